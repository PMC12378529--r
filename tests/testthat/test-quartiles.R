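test_that("default quartile table reproduces the published bands verbatim", {
  qt <- quartile_table()
  cell <- function(metric, sex, q) {
    row <- qt[qt$metric == metric & qt$sex == sex & qt$quartile == q, ]
    c(row$lower, row$upper)
  }
  expect_equal(cell("ctni", "female", 1), c(1.6, 2.4))
  expect_equal(cell("ctni", "female", 2), c(2.5, 3.3))
  expect_equal(cell("ctni", "female", 3), c(3.4, 4.5))
  expect_equal(cell("ctni", "female", 4), c(4.6, Inf))
  expect_equal(cell("ctni", "male", 3), c(3.4, 5.0))
  expect_equal(cell("ctni", "male", 4), c(5.1, Inf))
  expect_equal(cell("tgr", "any", 1), c(1.00, 1.15))
  expect_equal(cell("tgr", "any", 2), c(1.16, 1.31))
  expect_equal(cell("tgr", "any", 3), c(1.32, 1.50))
  expect_equal(cell("tgr", "any", 4), c(1.51, Inf))
  expect_equal(cell("tgi", "female", 1), c(1.6, 2.8))
  expect_equal(cell("tgi", "female", 2), c(2.9, 4.3))
  expect_equal(cell("tgi", "female", 3), c(4.4, 6.75))
  expect_equal(cell("tgi", "male", 3), c(4.4, 7.5))
  expect_equal(cell("ldl", "any", 1), c(60, 90))
  expect_equal(cell("ldl", "any", 2), c(91, 121))
  expect_equal(cell("ldl", "any", 3), c(122, 152))
  expect_equal(cell("ldl", "any", 4), c(153, 180))
  expect_equal(qt[qt$metric == "lgr", c("lower", "upper")],
               qt[qt$metric == "tgr", c("lower", "upper")])
  expect_equal(cell("lgi", "any", 1), c(60, 104))
  expect_equal(cell("lgi", "any", 2), c(105, 160))
  expect_equal(cell("lgi", "any", 3), c(161, 228))
  expect_equal(cell("lgi", "any", 4), c(229, 270))
})

test_that("classification matches the published band assignments", {
  expect_equal(classify_value("tgr", 1.20, "female"), "2")
  expect_equal(classify_value("tgi", 7.0, "male"), "3")
  expect_equal(classify_value("tgi", 7.0, "female"), "4")
  expect_equal(classify_value("lgi", 60, "male"), "1")
  expect_equal(classify_value("ctni", 4.8, "female"), "4")
  expect_equal(classify_value("ctni", 4.8, "male"), "3")
})

test_that("values outside the table domain get range markers, unknown metrics error", {
  expect_equal(classify_value("ldl", 185, "male"), "above-range")
  expect_equal(classify_value("ldl", 50, "male"), "below-range")
  expect_equal(classify_value("ctni", 1.0, "female"), "below-range")
  expect_equal(classify_value("tgr", 9.9, "male"), "4")  # open top band
  expect_error(classify_value("hdl", 50, "male"), class = "glyco_config_error")
})

test_that("every in-domain value maps to exactly one quartile (gaps fall low)", {
  qt <- quartile_table()
  for (metric in unique(qt$metric)) {
    for (sx in c("female", "male")) {
      bands <- qt[qt$metric == metric & qt$sex %in% c("any", sx), ]
      top <- if (all(is.finite(bands$upper))) max(bands$upper)
             else max(bands$lower) + 1
      grid <- seq(min(bands$lower), top, length.out = 401)
      got <- classify_value(metric, grid, sx)
      expect_true(all(got %in% as.character(1:4)),
                  info = paste(metric, sx))
      expect_true(all(diff(as.integer(got)) >= 0), info = paste(metric, sx))
    }
  }
  # gap values are assigned to the lower band
  expect_equal(classify_value("tgr", 1.155, "female"), "1")
  expect_equal(classify_value("ldl", 90.5, "female"), "1")
})

test_that("raising the male troponin ceiling moves only male cTnI/TGI top edges", {
  qt5 <- quartile_table()
  qt7 <- quartile_table(glyco_limits(ctni_max_male = 7))
  changed <- dplyr::anti_join(qt7, qt5,
                              by = c("metric", "sex", "quartile", "lower", "upper"))
  expect_true(all(changed$sex == "male"))
  expect_true(all(changed$metric %in% c("ctni", "tgi")))
  expect_true(all(changed$quartile %in% 3:4))
  expect_equal(qt7$upper[qt7$metric == "tgi" & qt7$sex == "male" &
                           qt7$quartile == 3], 10.5)  # 1.5 * 7
  # male screening ceiling moves with it; female unchanged
  p <- panel(sex = "male", ctni = 6.0)
  expect_false(screen_exclusions(p)$eligible)
  expect_true(screen_exclusions(p, glyco_limits(ctni_max_male = 7))$eligible)
})

test_that("exclusion screening flags each analyte strictly above its limit", {
  expect_match(screen_exclusions(panel(a1c = 47))$screen_reasons,
               "diabetes mellitus")
  expect_false(screen_exclusions(panel(sex = "female", ctni = 4.6))$eligible)
  expect_true(screen_exclusions(panel(sex = "male", ctni = 5.0))$eligible)
  expect_true(screen_exclusions(panel(a1c = 46))$eligible)  # strict inequality
  expect_match(screen_exclusions(panel(ldl = 181))$screen_reasons,
               "hyperlipidemia")
  # eligibility is the conjunction of the per-analyte flags; panel untouched
  s <- screen_exclusions(panel(a1c = 47, ldl = 181, ctni = 9))
  expect_false(any(s$a1c_ok, s$ctni_ok, s$ldl_ok, s$eligible))
  expect_equal(s$ldl, 181)
  # percent-unit A1c screens on the converted IFCC value
  expect_false(screen_exclusions(panel(a1c = 6.5, a1c_units = "percent"))$eligible)
})

test_that("classify_quartiles bands a whole metrics table at once", {
  out <- classify_quartiles(glycation_metrics(example_panels()))
  expect_equal(out$tgr_quartile, c("1", "1", "1", "2"))
  expect_equal(out$lgi_quartile, c("2", "2", "2", "3"))
})
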