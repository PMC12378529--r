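#' Concentration ratio against an optimal reference
#'
#' An individual's relative glycation exposure is the analyte concentration
#' divided by its optimal reference (A1c 31 mmol/mol, fructosamine
#' 200 umol/L), rounded to 2 decimals. The 2-decimal rounding is the working
#' precision of the whole model and is load-bearing: downstream rates are
#' computed from the rounded ratios, exactly as the reference tables print
#' them. A1c ratios must be formed on the IFCC (mmol/mol) scale.
#'
#' @param observed Observed analyte concentration.
#' @param optimal Optimal reference for the same analyte, same unit.
#' @return Dimensionless ratio, rounded to 2 decimals.
#' @examples
#' concentration_ratio(39, 31)   # 1.26
#' concentration_ratio(240, 200) # 1.20
#' @export
concentration_ratio <- function(observed, optimal) {
  check_positive(observed, "observed")
  check_positive(optimal, "optimal")
  round_half_up(observed / optimal, 2)
}

# slope m and intercept b of the line through (h_a1c, rA) and (h_fru, rF)
slope_intercept <- function(ratio_a1c, ratio_fructosamine, constants) {
  dx <- constants$halflife_a1c - constants$halflife_fructosamine
  if (any(abs(dx) < .Machine$double.eps)) {
    abort("A1c and fructosamine half-lives coincide: extrapolation line is degenerate.",
          class = "glyco_domain_error")
  }
  m <- (ratio_a1c - ratio_fructosamine) / dx
  b <- ratio_a1c - m * constants$halflife_a1c
  list(slope = m, intercept = b)
}

#' Extrapolate the glycation rate to a target half-life
#'
#' Fits the line through the two anchor points (A1c half-life, A1c ratio) and
#' (fructosamine half-life, fructosamine ratio) and evaluates it at the
#' target substrate's half-life: `Y = m*X + b` with
#' `m = (Y2 - Y1)/(X2 - X1)` and `b = Y1 - m*X1`. Evaluating at 1 day gives
#' the troponin glycation rate (TGR), at 3 days the LDL glycation rate (LGR).
#' Both target half-lives lie below both anchors, so the rate increases in
#' the fructosamine ratio and decreases in the A1c ratio.
#'
#' @param ratio_a1c A1c concentration ratio (dimensionless, IFCC scale).
#' @param ratio_fructosamine Fructosamine concentration ratio.
#' @param target_halflife Half-life (days) of the substrate to extrapolate to.
#' @param constants A [glyco_constants()] object supplying the anchor
#'   half-lives.
#' @param digits Decimals for the returned rate (default 2, the model's
#'   printed precision); `NULL` leaves the rate unrounded.
#' @return Dimensionless glycation rate.
#' @examples
#' rate_at_halflife(1.26, 1.20, 1) # TGR 1.12
#' rate_at_halflife(1.26, 1.20, 3) # LGR 1.13
#' @export
rate_at_halflife <- function(ratio_a1c, ratio_fructosamine, target_halflife,
                             constants = glyco_constants(), digits = 2) {
  check_positive(ratio_a1c, "ratio_a1c")
  check_positive(ratio_fructosamine, "ratio_fructosamine")
  check_positive(target_halflife, "target_halflife")
  fit <- slope_intercept(ratio_a1c, ratio_fructosamine, constants)
  y <- fit$slope * target_halflife + fit$intercept
  if (is.null(digits)) y else round_half_up(y, digits)
}

#' Compute glycation metrics for biomarker panels
#'
#' The core pipeline step: takes a panel table (see [validate_panels()] for
#' the expected columns) and appends, per row, the A1c on the IFCC scale, the
#' two concentration ratios, the slope and intercept of the extrapolation
#' line, the troponin and LDL glycation rates (TGR, LGR) and the glycation
#' indices (TGI = TGR x cTnI, rounded to 1 decimal; LGI = LGR x LDL, rounded
#' to the nearest integer). Rows where the fructosamine ratio exceeds the A1c
#' ratio have a negative-slope line whose extrapolation exceeds both anchors;
#' these are computed normally but flagged in `negative_slope` (see
#' [glycation_gap()] for the related consistency check).
#'
#' @param panels A data frame of biomarker panels.
#' @param constants A [glyco_constants()] object.
#' @return The input tibble with columns `a1c_ifcc`, `a1c_percent`,
#'   `ratio_a1c`, `ratio_fructosamine`, `slope`, `intercept`, `tgr`, `lgr`,
#'   `tgi`, `lgi`, `negative_slope` appended.
#' @examples
#' library(tibble)
#' p <- tibble(date = 2024, sex = "female", a1c = 5.7, a1c_units = "percent",
#'             fructosamine = 240, ctni = 3.2, ldl = 125)
#' glycation_metrics(p)[, c("tgr", "lgr", "tgi", "lgi")]
#' @export
glycation_metrics <- function(panels, constants = glyco_constants()) {
  panels <- validate_panels(panels)
  out <- dplyr::mutate(
    panels,
    a1c_ifcc = a1c_as_ifcc(.data$a1c, .data$a1c_units),
    a1c_percent = ifelse(.data$a1c_units == "percent",
                         .data$a1c, a1c_ifcc_to_percent(.data$a1c_ifcc)),
    ratio_a1c = concentration_ratio(.data$a1c_ifcc, constants$optimal_a1c),
    ratio_fructosamine = concentration_ratio(.data$fructosamine,
                                             constants$optimal_fructosamine)
  )
  fit <- slope_intercept(out$ratio_a1c, out$ratio_fructosamine, constants)
  dplyr::mutate(
    out,
    slope = fit$slope,
    intercept = fit$intercept,
    tgr = round_half_up(fit$slope * constants$halflife_ctni + fit$intercept, 2),
    lgr = round_half_up(fit$slope * constants$halflife_ldl + fit$intercept, 2),
    tgi = round_half_up(.data$tgr * .data$ctni, 1),
    lgi = round_half_up(.data$lgr * .data$ldl),
    negative_slope = .data$ratio_fructosamine > .data$ratio_a1c
  )
}

#' Glycation gap between the two glycemic analytes
#'
#' A1c and fructosamine imply the same underlying glycemia in a stable
#' individual, so their concentration ratios should agree. A large
#' discrepancy (the "glycation gap") signals unstable glucose — rapid weight
#' change, recent medication change — or assay interference, and makes the
#' extrapolated rates unreliable. The default threshold of 0.15 on
#' `|ratio_a1c - ratio_fructosamine|` is a configurable working value, not an
#' established clinical cut-off.
#'
#' @param metrics A tibble from [glycation_metrics()] (needs `ratio_a1c` and
#'   `ratio_fructosamine`).
#' @param threshold Absolute gap above which the flag triggers.
#' @return The input with columns `gap`, `gap_triggered` and `gap_note`
#'   appended.
#' @export
glycation_gap <- function(metrics, threshold = 0.15) {
  check_positive(threshold, "threshold")
  stopifnot(all(c("ratio_a1c", "ratio_fructosamine") %in% names(metrics)))
  dplyr::mutate(
    as_tibble(metrics),
    gap = .data$ratio_a1c - .data$ratio_fructosamine,
    gap_triggered = abs(.data$gap) > threshold,
    gap_note = dplyr::case_when(
      !.data$gap_triggered ~ NA_character_,
      .data$gap > 0 ~ "A1c-dominant glycation gap: glucose instability or assay interference suspected",
      TRUE ~ "fructosamine-dominant glycation gap: glucose instability or assay interference suspected"
    )
  )
}
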