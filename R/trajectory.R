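#' Trajectory specification for multi-decade simulation
#'
#' Describes a glycation-index trajectory over a span of years by its rate
#' and concentration endpoints. The trajectory is linear *in index space*
#' between the baseline index and the endpoint index, where the endpoint is
#' the rate endpoint times the concentration endpoint rounded to the index's
#' display precision (1 decimal for TGI, integer for LGI). An alternative
#' `"component-linear"` mode interpolates rate and concentration separately
#' and multiplies (a mildly convex index path); it is retained for
#' sensitivity analysis but the index-linear path is the one whose burden
#' matches the model's published trajectory comparisons.
#'
#' @param index `"tgi"` or `"lgi"`.
#' @param rate_start,rate_end Glycation rate (TGR or LGR) at the start and
#'   end of the span; `rate_start` at or above the optimum 1.0.
#' @param conc_start,conc_end Concentration (cTnI ng/L or LDL mg/dL) at the
#'   start and end of the span.
#' @param span Span in years (default 30).
#' @param label Free-text label (`"normal"`, `"prediabetic"`, or custom).
#' @return A `glyco_trajectory_spec` (named list) with the derived
#'   `baseline` and `endpoint` index values.
#' @examples
#' trajectory_spec("tgi", 1.0, 1.11, 1.6, 2.6)
#' @export
trajectory_spec <- function(index = c("tgi", "lgi"),
                            rate_start, rate_end, conc_start, conc_end,
                            span = 30, label = "custom") {
  index <- match.arg(index)
  check_positive(span, "span")
  for (v in c("rate_start", "rate_end", "conc_start", "conc_end")) {
    check_positive(get(v), v)
  }
  if (rate_start < 1) {
    abort("`rate_start` must be at least 1.0 (the optimal glycation rate).",
          class = "glyco_domain_error")
  }
  digits <- if (index == "tgi") 1 else 0
  structure(list(
    index = index, label = label, span = span,
    rate_start = rate_start, rate_end = rate_end,
    conc_start = conc_start, conc_end = conc_end,
    baseline = round_half_up(rate_start * conc_start, digits),
    endpoint = round_half_up(rate_end * conc_end, digits)
  ), class = "glyco_trajectory_spec")
}

#' Published trajectory presets
#'
#' The two 30-year archetypes used in the model's trajectory comparison,
#' both starting at the optimal references (TGI 1.6, LGI 60, rates 1.0):
#' a normal individual (TGR/LGR to 1.11, cTnI to 2.6 ng/L, LDL to
#' 100 mg/dL) and one developing prediabetes (TGR to 1.24 / LGR to 1.25,
#' cTnI to 3.4 ng/L, LDL to 140 mg/dL).
#'
#' @param archetype `"normal"` or `"prediabetic"`.
#' @return A named list with `tgi` and `lgi` [trajectory_spec()]s.
#' @examples
#' trajectory_preset("prediabetic")$tgi$endpoint # 4.2
#' @export
trajectory_preset <- function(archetype = c("normal", "prediabetic")) {
  archetype <- match.arg(archetype)
  p <- switch(archetype,
    normal = list(tgr = 1.11, ctni = 2.6, lgr = 1.11, ldl = 100),
    prediabetic = list(tgr = 1.24, ctni = 3.4, lgr = 1.25, ldl = 140)
  )
  list(
    tgi = trajectory_spec("tgi", 1.0, p$tgr, 1.6, p$ctni,
                          span = 30, label = archetype),
    lgi = trajectory_spec("lgi", 1.0, p$lgr, 60, p$ldl,
                          span = 30, label = archetype)
  )
}

#' Sample an index trajectory on a uniform time grid
#'
#' @param spec A [trajectory_spec()].
#' @param n_points Number of grid points covering the span (at least 2).
#' @param mode `"index-linear"` (default) interpolates the index itself
#'   between baseline and rounded endpoint; `"component-linear"`
#'   interpolates rate and concentration separately and multiplies.
#' @return A tibble with columns `time` (years from start), `index`, plus
#'   the spec's `label` and index type.
#' @examples
#' index_trajectory(trajectory_preset("normal")$tgi, n_points = 5)
#' @export
index_trajectory <- function(spec, n_points = 61,
                             mode = c("index-linear", "component-linear")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "glyco_trajectory_spec"))
  if (n_points < 2) {
    abort("`n_points` must be at least 2.", class = "glyco_domain_error")
  }
  u <- seq(0, 1, length.out = n_points)
  idx <- if (mode == "index-linear") {
    spec$baseline + u * (spec$endpoint - spec$baseline)
  } else {
    rate <- spec$rate_start + u * (spec$rate_end - spec$rate_start)
    conc <- spec$conc_start + u * (spec$conc_end - spec$conc_start)
    rate * conc
  }
  tibble(time = u * spec$span, index = idx,
         index_type = spec$index, label = spec$label)
}

#' Cumulative excess glycation burden (AUC above baseline)
#'
#' Integrates the part of an index trajectory that lies above its baseline
#' value by the trapezoid rule, giving the model's proxy for cumulative
#' excess tissue glycation over the span (index-units x years). For a linear
#' trajectory this equals `span * (endpoint - baseline) / 2` exactly,
#' independent of grid density.
#'
#' @param trajectory A tibble from [index_trajectory()] (columns `time`,
#'   `index`), sampled on a uniform grid covering the span.
#' @param baseline Baseline index value subtracted before integration.
#' @return An object of class `glyco_burden`: a list with `auc`, `baseline`,
#'   `endpoint`, `span`, `index_type` and `label`.
#' @examples
#' tr <- index_trajectory(trajectory_preset("normal")$tgi)
#' excess_burden(tr, baseline = 1.6)$auc # 19.5
#' @export
excess_burden <- function(trajectory, baseline) {
  if (!is.data.frame(trajectory) || nrow(trajectory) == 0) {
    abort("`trajectory` must be a non-empty data frame with `time` and `index`.",
          class = "glyco_domain_error")
  }
  stopifnot(all(c("time", "index") %in% names(trajectory)))
  excess <- pmax(trajectory$index - baseline, 0)
  t <- trajectory$time
  auc <- sum(diff(t) * (utils::head(excess, -1) + utils::tail(excess, -1)) / 2)
  structure(list(
    auc = auc,
    baseline = baseline,
    endpoint = trajectory$index[[nrow(trajectory)]],
    span = max(t) - min(t),
    index_type = if ("index_type" %in% names(trajectory))
      trajectory$index_type[[1]] else NA_character_,
    label = if ("label" %in% names(trajectory))
      trajectory$label[[1]] else NA_character_
  ), class = "glyco_burden")
}

#' @export
print.glyco_burden <- function(x, ...) {
  cat(sprintf("Excess glycation burden (%s, %s): AUC %.4g index-years over %g y (baseline %g, endpoint %g)\n",
              toupper(x$index_type %||% "?"), x$label %||% "unlabelled",
              x$auc, x$span, x$baseline, x$endpoint))
  invisible(x)
}

#' Compare two excess burdens
#'
#' @param a,b `glyco_burden` objects over the same span and index type.
#' @return A list with `ratio` (`a$auc / b$auc`, `NA` when `b` is zero) and
#'   a `narrative` rendering the fold change at 1 decimal.
#' @examples
#' pre <- excess_burden(index_trajectory(trajectory_preset("prediabetic")$tgi), 1.6)
#' nor <- excess_burden(index_trajectory(trajectory_preset("normal")$tgi), 1.6)
#' compare_burden(pre, nor)$narrative
#' @export
compare_burden <- function(a, b) {
  stopifnot(inherits(a, "glyco_burden"), inherits(b, "glyco_burden"))
  if (!isTRUE(all.equal(a$span, b$span)) ||
      !identical(a$index_type, b$index_type)) {
    abort("burdens must share the same span and index type to be compared.",
          class = "glyco_domain_error")
  }
  if (b$auc == 0) {
    return(list(ratio = NA_real_,
                narrative = "undefined ratio: reference burden is zero"))
  }
  ratio <- a$auc / b$auc
  list(ratio = ratio,
       narrative = sprintf("%.1f-fold excess %s burden (%s vs %s)",
                           round_half_up(ratio, 1), toupper(a$index_type %||% "index"),
                           a$label %||% "a", b$label %||% "b"))
}

#' Burden summary for the published archetype comparison
#'
#' Runs both presets through [index_trajectory()] and [excess_burden()] and
#' tabulates endpoint, AUC and the prediabetic:normal burden ratio for each
#' index.
#'
#' @param n_points Grid points per trajectory.
#' @param mode Passed to [index_trajectory()].
#' @return A tibble: `label`, `index_type`, `baseline`, `endpoint`, `auc`,
#'   `ratio_vs_normal`.
#' @examples
#' burden_summary()
#' @export
burden_summary <- function(n_points = 61, mode = "index-linear") {
  rows <- purrr::map_dfr(c("normal", "prediabetic"), function(arch) {
    ps <- trajectory_preset(arch)
    purrr::map_dfr(ps, function(spec) {
      b <- excess_burden(index_trajectory(spec, n_points, mode), spec$baseline)
      tibble(label = arch, index_type = spec$index,
             baseline = spec$baseline, endpoint = spec$endpoint, auc = b$auc)
    })
  })
  dplyr::mutate(
    dplyr::group_by(rows, .data$index_type),
    ratio_vs_normal = .data$auc / .data$auc[.data$label == "normal"]
  ) |> dplyr::ungroup()
}
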