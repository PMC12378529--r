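#' Build an annual glycation series
#'
#' Orders a set of dated panels for one individual chronologically, computes
#' the glycation metrics for every draw and returns the sequential report
#' table (one row per year: raw biomarkers, A1c on both scales, TGR, TGI,
#' LGR, LGI). Duplicate years are rejected — the model assumes one panel per
#' annual examination — and gaps of more than one year between consecutive
#' draws raise a warning, since infrequent or delayed monitoring degrades the
#' sequential analysis.
#'
#' @param panels A data frame of biomarker panels (see [validate_panels()]).
#' @param constants A [glyco_constants()] object.
#' @param id Optional individual identifier stored on the series.
#' @return A tibble of class `glyco_series`, sorted by year, with a `year`
#'   column and all [glycation_metrics()] columns.
#' @examples
#' glyco_series(example_panels())
#' @export
glyco_series <- function(panels, constants = glyco_constants(), id = NULL) {
  panels <- validate_panels(panels)
  metrics <- glycation_metrics(panels, constants)
  metrics$year <- panel_year(metrics$date)
  metrics <- dplyr::arrange(metrics, .data$year)
  dup <- unique(metrics$year[duplicated(metrics$year)])
  if (length(dup)) {
    abort(paste0("duplicate year(s) in series: ", paste(dup, collapse = ", "),
                 "; supply one panel per annual draw."),
          class = "glyco_validation_error")
  }
  if (nrow(metrics) > 1 && any(diff(metrics$year) > 1)) {
    warn("gap of more than one year between draws: infrequent or delayed monitoring can lead to inaccuracies.")
  }
  metrics <- dplyr::relocate(metrics, "year")
  structure(metrics, class = c("glyco_series", class(metrics)),
            constants = constants, id = id)
}

#' Forecast the next annual panel by per-column least squares
#'
#' Each raw biomarker column (A1c %, fructosamine, cTnI, LDL) is fitted by
#' ordinary least squares against a 0-based integer year index (calendar-day
#' spacing is ignored: the model assumes an annual cadence) and evaluated one
#' year ahead. Forecasts are rounded to each column's reporting precision
#' (A1c 0.1%, fructosamine 1 umol/L, cTnI 0.1 ng/L, LDL 1 mg/dL) *before*
#' the glycation metrics of the predicted row are recomputed from them, so
#' the forecast row obeys exactly the same arithmetic as an observed row.
#' The horizon is fixed at one year: individual biomarker variability makes
#' longer extrapolation unreliable, and the function refuses it.
#'
#' @param series A `glyco_series` from [glyco_series()], with at least two
#'   observations.
#' @param mode `"recompute"` (default) derives the predicted TGR/LGR/TGI/LGI
#'   from the forecast biomarkers; `"column_ols"` instead regresses the
#'   metric columns themselves and reports their one-year-ahead values.
#' @return An object of class `glyco_forecast`: a one-row tibble in the
#'   series layout with `predicted = TRUE`, carrying the per-column [lm]
#'   fits in its `fits` attribute (see [tidy.glyco_forecast()]).
#' @examples
#' s <- glyco_series(example_panels())
#' forecast_next(s)[, c("year", "a1c_percent", "fructosamine", "ctni", "ldl")]
#' @export
forecast_next <- function(series, mode = c("recompute", "column_ols")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "glyco_series"))
  if (nrow(series) < 2) {
    abort("at least two observations are required to forecast the next year.",
          class = "glyco_validation_error")
  }
  constants <- attr(series, "constants") %||% glyco_constants()
  idx <- series$year - series$year[[1]]
  ahead <- max(idx) + 1L
  ols_pred <- function(y) {
    fit <- lm(y ~ idx)
    list(fit = fit, pred = unname(coef(fit)[[1]] + coef(fit)[[2]] * ahead))
  }
  cols <- list(a1c_percent = 1, fructosamine = 0, ctni = 1, ldl = 0)
  fits <- purrr::imap(cols, function(digits, col) ols_pred(series[[col]]))
  pred <- purrr::imap_dbl(fits, function(f, col) round_half_up(f$pred, cols[[col]]))

  row <- tibble(
    date = max(series$year) + 1L,
    sex = series$sex[[1]],
    a1c = pred[["a1c_percent"]],
    a1c_units = "percent",
    fructosamine = pred[["fructosamine"]],
    ctni = pred[["ctni"]],
    ldl = pred[["ldl"]]
  )
  out <- glycation_metrics(row, constants)
  out$year <- max(series$year) + 1L
  if (mode == "column_ols") {
    # regress the metric columns directly instead of recomputing
    mfits <- purrr::map(c(tgr = "tgr", lgr = "lgr", tgi = "tgi", lgi = "lgi"),
                        function(col) ols_pred(series[[col]]))
    out$tgr <- round_half_up(mfits$tgr$pred, 2)
    out$lgr <- round_half_up(mfits$lgr$pred, 2)
    out$tgi <- round_half_up(mfits$tgi$pred, 1)
    out$lgi <- round_half_up(mfits$lgi$pred)
    fits <- c(fits, mfits)
  }
  out$predicted <- TRUE
  out <- dplyr::relocate(out, "year")
  structure(out, class = c("glyco_forecast", class(out)),
            fits = purrr::map(fits, "fit"), mode = mode)
}

#' @describeIn forecast_next Broom-style coefficient table of the per-column
#'   forecast regressions: one row per analyte and term.
#' @param x A `glyco_forecast` object.
#' @param ... Unused.
#' @export
tidy.glyco_forecast <- function(x, ...) {
  purrr::imap_dfr(attr(x, "fits"), function(fit, col) {
    s <- summary(fit)$coefficients
    tibble(column = col,
           term = c("intercept", "per_year"),
           estimate = unname(s[, 1]),
           std.error = unname(s[, 2]))
  })
}

#' @describeIn forecast_next One-row-per-analyte fit summary (R squared,
#'   residual sigma, number of observations).
#' @export
glance.glyco_forecast <- function(x, ...) {
  purrr::imap_dfr(attr(x, "fits"), function(fit, col) {
    s <- summary(fit)
    tibble(column = col, r.squared = s$r.squared, sigma = s$sigma,
           nobs = length(fit$residuals))
  })
}

#' Annotate consecutive-year biomarker/metric divergences
#'
#' Inspects each consecutive pair of years and annotates whether troponin I
#' and TGR moved together. A parallel increase suggests glycation as the
#' driver of the troponin change; troponin rising while the glycation rate
#' is flat or falling points at a non-glycation factor (e.g. hypertension);
#' troponin and LDL falling together is consistent with an LDL-lowering
#' intervention such as a statin, which reduces the glycation substrate
#' without lowering glucose.
#'
#' @param series A `glyco_series`.
#' @param tol Minimum movement (in each quantity's own units) counted as a
#'   change; smaller moves are treated as flat. Default 0 (any printed
#'   change counts).
#' @return A tibble with one row per consecutive pair: `from`, `to`, the
#'   deltas, and `note` (`NA` when nothing is flagged).
#' @export
divergence_notes <- function(series, tol = 0) {
  stopifnot(inherits(series, "glyco_series"))
  if (nrow(series) < 2) {
    abort("at least two observations are required to annotate changes.",
          class = "glyco_validation_error")
  }
  n <- nrow(series)
  d_ctni <- diff(series$ctni)
  d_tgr <- diff(series$tgr)
  d_ldl <- diff(series$ldl)
  dir <- function(d) ifelse(d > tol, 1L, ifelse(d < -tol, -1L, 0L))
  tibble(
    from = series$year[-n],
    to = series$year[-1],
    delta_ctni = d_ctni,
    delta_tgr = d_tgr,
    delta_ldl = d_ldl,
    note = dplyr::case_when(
      dir(d_ctni) > 0 & dir(d_tgr) > 0 ~ "parallel increase: glycation-consistent troponin rise",
      dir(d_ctni) > 0 & dir(d_tgr) <= 0 ~ "non-glycation factor suspected (troponin rose without a proportional TGR rise)",
      dir(d_ctni) < 0 & dir(d_ldl) < 0 ~ "consistent with LDL-lowering intervention",
      TRUE ~ NA_character_
    )
  )
}

#' Sequential annual report with forecast row
#'
#' Convenience wrapper producing the full sequential report: the observed
#' series plus (when at least two observations are available) the predicted
#' next-year row, marked by the logical `predicted` column.
#'
#' @inheritParams glyco_series
#' @inheritParams forecast_next
#' @return A tibble in the report layout: `year`, `a1c_percent`, `a1c_ifcc`,
#'   `fructosamine`, `ctni`, `tgr`, `tgi`, `ldl`, `lgr`, `lgi`, `predicted`.
#' @examples
#' track_report(example_panels())
#' @export
track_report <- function(panels, constants = glyco_constants(),
                         mode = c("recompute", "column_ols")) {
  series <- glyco_series(panels, constants)
  obs <- dplyr::mutate(as_tibble(series), predicted = FALSE)
  rows <- if (nrow(series) >= 2) {
    dplyr::bind_rows(obs, as_tibble(forecast_next(series, mode)))
  } else {
    warn("single observation: no forecast row produced.")
    obs
  }
  dplyr::select(rows, "year", "sex", "a1c_percent", "a1c_ifcc",
                "fructosamine", "ctni", "tgr", "tgi",
                "ldl", "lgr", "lgi", "predicted")
}
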