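#' Quartile bands for biomarkers and glycation metrics
#'
#' Fixed reference bands (not population quantiles) for troponin I, TGR, TGI,
#' LDL, LGR and LGI. Bands are closed on their printed endpoints; the small
#' gaps left by the printed measurement precision (e.g. TGR 1.15 | 1.16) are
#' bridged by assigning any in-gap value to the lower band, so classification
#' is total over each metric's domain. Troponin bands are sex-specific in the
#' upper quartiles: the female/male band-3 ceilings are the exclusionary
#' troponin limits and the TGI ceilings are `rate_max` times those limits, so
#' raising the male troponin ceiling (5-7 ng/L is defensible) moves only the
#' male band-3/4 edges.
#'
#' @param limits A [glyco_limits()] object (supplies the sex-specific
#'   troponin ceilings and the LDL ceiling).
#' @param constants A [glyco_constants()] object (supplies the troponin LOD
#'   and LDL floor).
#' @param rate_max Maximal in-range glycation rate (default 1.5).
#' @return A tibble with columns `metric`, `sex` (`"female"`, `"male"` or
#'   `"any"`), `quartile`, `lower`, `upper` (`Inf` for open top bands).
#' @examples
#' quartile_table()
#' @export
quartile_table <- function(limits = glyco_limits(),
                           constants = glyco_constants(),
                           rate_max = 1.5) {
  band <- function(metric, sex, lower, upper) {
    tibble(metric = metric, sex = sex, quartile = seq_along(lower),
           lower = lower, upper = upper)
  }
  rate_bands <- function(metric) {
    band(metric, "any", c(1.0, 1.16, 1.32, 1.50 + 0.01),
         c(1.15, 1.31, rate_max, Inf))
  }
  ctni_bands <- function(sex, ceiling) {
    band("ctni", sex, c(constants$ctni_lod, 2.5, 3.4, ceiling + 0.1),
         c(2.4, 3.3, ceiling, Inf))
  }
  tgi_bands <- function(sex, ceiling) {
    top <- round_half_up(rate_max * ceiling, 2)
    band("tgi", sex, c(round_half_up(constants$ctni_lod, 1), 2.9, 4.4, top + 0.01),
         c(2.8, 4.3, top, Inf))
  }
  dplyr::bind_rows(
    ctni_bands("female", limits$ctni_max_female),
    ctni_bands("male", limits$ctni_max_male),
    rate_bands("tgr"),
    tgi_bands("female", limits$ctni_max_female),
    tgi_bands("male", limits$ctni_max_male),
    band("ldl", "any", c(constants$ldl_floor, 91, 122, 153),
         c(90, 121, 152, limits$ldl_max)),
    rate_bands("lgr"),
    band("lgi", "any", c(round_half_up(constants$ldl_floor), 105, 161, 229),
         c(104, 160, 228, round_half_up(rate_max * limits$ldl_max)))
  )
}

#' Assign a value to its quartile band
#'
#' @param metric One of `"ctni"`, `"tgr"`, `"tgi"`, `"ldl"`, `"lgr"`,
#'   `"lgi"`.
#' @param value Numeric value(s) to band.
#' @param sex `"female"` or `"male"`; required for the sex-specific troponin
#'   bands, ignored for the others.
#' @param table A [quartile_table()].
#' @return Character vector: `"1"`-`"4"`, or `"below-range"`/`"above-range"`
#'   for values outside the table's overall domain.
#' @examples
#' classify_value("tgr", 1.20, "female") # "2"
#' classify_value("tgi", 7.0, "male")    # "3"
#' classify_value("tgi", 7.0, "female")  # "4"
#' @export
classify_value <- function(metric, value, sex, table = quartile_table()) {
  if (!metric %in% unique(table$metric)) {
    abort(sprintf("unknown metric \"%s\"; table defines: %s", metric,
                  paste(unique(table$metric), collapse = ", ")),
          class = "glyco_config_error")
  }
  check_sex(sex)
  n <- max(length(value), length(sex))
  value <- rep_len(value, n)
  sex <- rep_len(sex, n)
  vapply(seq_len(n), function(i) {
    bands <- table[table$metric == metric &
                     table$sex %in% c("any", sex[[i]]), , drop = FALSE]
    bands <- bands[order(bands$quartile), , drop = FALSE]
    v <- value[[i]]
    if (is.na(v)) return(NA_character_)
    if (v < min(bands$lower)) return("below-range")
    if (v > max(bands$upper)) return("above-range")
    # closed bands; in-gap values fall to the lower band
    as.character(max(bands$quartile[v >= bands$lower]))
  }, character(1))
}

#' Band every metric of a glycation-metrics table
#'
#' @param metrics A tibble from [glycation_metrics()].
#' @param table A [quartile_table()].
#' @return The input with character columns `ctni_quartile`, `tgr_quartile`,
#'   `tgi_quartile`, `ldl_quartile`, `lgr_quartile`, `lgi_quartile` appended.
#' @export
classify_quartiles <- function(metrics, table = quartile_table()) {
  metrics <- as_tibble(metrics)
  for (m in c("ctni", "tgr", "tgi", "ldl", "lgr", "lgi")) {
    stopifnot(m %in% names(metrics))
    metrics[[paste0(m, "_quartile")]] <-
      classify_value(m, metrics[[m]], metrics$sex, table)
  }
  metrics
}

#' Screen panels against the exclusionary limits
#'
#' Flags analytes strictly above their exclusionary ceiling: A1c above
#' 46 mmol/mol suggests diabetes mellitus, LDL above 180 mg/dL severe
#' hyperlipidemia, troponin I above the sex-specific ceiling cardiac ischemia
#' or injury. A panel at the limit passes (the inequality is strict).
#' Screening never errors and never mutates the panel values; eligibility is
#' the conjunction of the per-analyte flags.
#'
#' @param panels A data frame of biomarker panels (see [validate_panels()]).
#' @param limits A [glyco_limits()] object.
#' @return The input with logical columns `a1c_ok`, `ctni_ok`, `ldl_ok`,
#'   `eligible` and a character `screen_reasons` column (`NA` when eligible).
#' @examples
#' library(tibble)
#' p <- tibble(date = 2024, sex = "female", a1c = 47, a1c_units = "mmol_mol",
#'             fructosamine = 280, ctni = 3.0, ldl = 120)
#' screen_exclusions(p)$screen_reasons
#' @export
screen_exclusions <- function(panels, limits = glyco_limits()) {
  panels <- validate_panels(panels)
  a1c_ifcc <- a1c_as_ifcc(panels$a1c, panels$a1c_units)
  ctni_max <- ifelse(panels$sex == "female",
                     limits$ctni_max_female, limits$ctni_max_male)
  out <- dplyr::mutate(
    panels,
    a1c_ok = a1c_ifcc <= limits$a1c_max,
    ctni_ok = .data$ctni <= ctni_max,
    ldl_ok = .data$ldl <= limits$ldl_max,
    eligible = .data$a1c_ok & .data$ctni_ok & .data$ldl_ok
  )
  reasons <- purrr::pmap_chr(
    list(out$a1c_ok, out$ctni_ok, out$ldl_ok),
    function(a, t, l) {
      r <- c(
        if (!a) sprintf("A1c > %g mmol/mol suggests diabetes mellitus", limits$a1c_max),
        if (!t) "troponin I above sex-specific limit suggests cardiac ischemia or injury",
        if (!l) sprintf("LDL > %g mg/dL suggests severe hyperlipidemia", limits$ldl_max)
      )
      if (length(r)) paste(r, collapse = "; ") else NA_character_
    }
  )
  dplyr::mutate(out, screen_reasons = reasons)
}
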