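test_that("concentration ratios reproduce the reference values at 2 decimals", {
  expect_equal(concentration_ratio(39, 31), 1.26)
  expect_equal(concentration_ratio(240, 200), 1.20)
  expect_equal(concentration_ratio(200, 200), 1.00)
  expect_equal(concentration_ratio(42, 31), 1.35)
  expect_error(concentration_ratio(39, 0), class = "glyco_domain_error")
  expect_error(concentration_ratio(-1, 31), class = "glyco_domain_error")
})

test_that("slope-intercept extrapolation reproduces the worked examples", {
  expect_equal(rate_at_halflife(1.26, 1.20, 1), 1.12)  # TGR
  expect_equal(rate_at_halflife(1.26, 1.20, 3), 1.13)  # LGR
  expect_equal(rate_at_halflife(1.00, 1.00, 1), 1.00)  # flat line
  expect_equal(rate_at_halflife(1.35, 1.31, 1), 1.26)
})

test_that("extrapolation equals the closed form on random ratio pairs", {
  set.seed(11)
  n <- 1e4
  ra <- runif(n, 0.8, 2.0)
  rf <- runif(n, 0.8, 2.0)
  for (h in c(1, 3)) {
    got <- rate_at_halflife(ra, rf, h, digits = NULL)
    expect_lt(max(abs(got - oracle_rate(ra, rf, h))), 1e-12)
  }
})

test_that("unrounded rates are a weighted combination of the two ratios", {
  # TGR = w*rF + (1-w)*rA with w = (28.7 - h)/12.2; coefficients sum to 1
  set.seed(12)
  ra <- runif(50, 0.9, 1.6)
  rf <- runif(50, 0.9, 1.6)
  tgr <- rate_at_halflife(ra, rf, 1, digits = NULL)
  lgr <- rate_at_halflife(ra, rf, 3, digits = NULL)
  expect_equal(tgr, 2.2705 * rf - 1.2705 * ra, tolerance = 1e-4)
  expect_equal(lgr, 2.1066 * rf - 1.1066 * ra, tolerance = 1e-4)
  # LGR - TGR = 2m exactly, so TGR <= LGR iff rA >= rF
  m <- (ra - rf) / 12.2
  expect_equal(lgr - tgr, 2 * m, tolerance = 1e-12)
  expect_equal(tgr <= lgr, ra >= rf)
})

test_that("rate is monotone: increasing in rF, decreasing in rA", {
  base <- rate_at_halflife(1.2, 1.2, 1, digits = NULL)
  expect_gt(rate_at_halflife(1.2, 1.25, 1, digits = NULL), base)
  expect_lt(rate_at_halflife(1.25, 1.2, 1, digits = NULL), base)
})

test_that("degenerate anchor geometry is rejected", {
  expect_error(glyco_constants(halflife_a1c = 16.5),
               class = "glyco_config_error")
})

test_that("glycation_metrics populates every metric at table precision", {
  m <- glycation_metrics(panel())  # A1c 39 mmol/mol, fruct 240, cTnI 3.2, LDL 125
  expect_equal(m$ratio_a1c, 1.26)
  expect_equal(m$ratio_fructosamine, 1.20)
  expect_equal(m$tgr, 1.12)
  expect_equal(m$lgr, 1.13)
  expect_equal(m$tgi, 3.6)   # 1.12 * 3.2 = 3.584 -> 3.6

  m2 <- glycation_metrics(panel(a1c = 42, fructosamine = 262,
                                ctni = 3.4, ldl = 130))
  expect_equal(m2$tgr, 1.26)
  expect_equal(m2$lgr, 1.27)
  expect_equal(m2$lgi, 165)  # 1.27 * 130 = 165.1 -> 165

  # index rounding identities hold for any row
  expect_equal(m2$tgi, round_half_up(m2$tgr * m2$ctni, 1))
  expect_equal(m2$lgi, round_half_up(m2$lgr * m2$ldl))
})

test_that("a panel at the optimal references yields unit rates and raw indices", {
  m <- glycation_metrics(optimal_panel())
  expect_equal(m$tgr, 1.0)
  expect_equal(m$lgr, 1.0)
  expect_equal(m$tgi, 1.6)
  expect_equal(m$lgi, 60)
  expect_false(m$negative_slope)
})

test_that("percent and mmol/mol A1c inputs give identical metrics", {
  pct <- glycation_metrics(panel(a1c = 5.7, a1c_units = "percent"))
  mml <- glycation_metrics(panel(a1c = 39, a1c_units = "mmol_mol"))
  cols <- c("a1c_ifcc", "ratio_a1c", "tgr", "lgr", "tgi", "lgi")
  expect_equal(pct[cols], mml[cols])
})

test_that("fructosamine-dominant panels are flagged, not refused", {
  m <- glycation_metrics(panel(a1c = 33, fructosamine = 260))
  expect_true(m$negative_slope)
  expect_gt(m$tgr, m$ratio_fructosamine)  # extrapolation exceeds both anchors
})

test_that("glycation gap triggers only above the threshold", {
  near <- glycation_gap(glycation_metrics(panel()))          # |1.26-1.20| = 0.06
  expect_false(near$gap_triggered)
  flat <- glycation_gap(glycation_metrics(optimal_panel()))  # gap exactly 0
  expect_equal(flat$gap, 0)
  expect_false(flat$gap_triggered)
  wide <- glycation_gap(glycation_metrics(panel(a1c = 43.4, fructosamine = 230)))
  expect_equal(wide$gap, 1.40 - 1.15)
  expect_true(wide$gap_triggered)
  expect_match(wide$gap_note, "A1c-dominant")
})

test_that("invalid panels are rejected with informative errors", {
  expect_error(glycation_metrics(panel(ctni = -1)), class = "glyco_domain_error")
  expect_error(glycation_metrics(panel(a1c_units = "mg")),
               class = "glyco_validation_error")
  expect_error(glycation_metrics(panel(sex = "unknown")),
               class = "glyco_validation_error")
  expect_error(glycation_metrics(dplyr::select(panel(), -ldl)),
               class = "glyco_validation_error")
})
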