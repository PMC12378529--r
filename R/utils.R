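#' Round half away from zero
#'
#' Commercial ("schoolbook") rounding: halves round up in magnitude, so
#' `round_half_up(142.5) == 143`, unlike base [round()] which rounds half to
#' even. All display rounding in the package goes through this function
#' because the reference tables are printed with half-up rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(142.5)     # 143, not 142
#' round_half_up(3.584, 1)  # 3.6
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  # nudge by sqrt(eps) so values stored just under .5 (e.g. 1.335) round up
  trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p * sign(x)
}

# shared input checks -------------------------------------------------------

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and strictly positive.", name),
          class = "glyco_domain_error")
  }
  invisible(x)
}

check_sex <- function(sex) {
  if (!all(sex %in% c("female", "male"))) {
    abort("`sex` must be \"female\" or \"male\" (required for troponin limits).",
          class = "glyco_validation_error")
  }
  invisible(sex)
}

#' Validate a tibble of biomarker panels
#'
#' A panel table has one row per laboratory draw with columns `date` (a
#' [Date], or an integer year), `sex` (`"female"`/`"male"`), `a1c`,
#' `a1c_units` (`"percent"` NGSP or `"mmol_mol"` IFCC), `fructosamine`
#' (umol/L), `ctni` (ng/L) and `ldl` (mg/dL). All analyte values must be
#' strictly positive and the A1c unit system is always explicit, never
#' inferred from magnitude.
#'
#' @param panels A data frame of biomarker panels.
#' @return The validated panels as a tibble (invisibly usable in pipes).
#' @export
validate_panels <- function(panels) {
  panels <- as_tibble(panels)
  needed <- c("date", "sex", "a1c", "a1c_units", "fructosamine", "ctni", "ldl")
  missing <- setdiff(needed, names(panels))
  if (length(missing)) {
    abort(paste0("panel table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "glyco_validation_error")
  }
  if (!all(panels$a1c_units %in% c("percent", "mmol_mol"))) {
    abort("`a1c_units` must be \"percent\" or \"mmol_mol\" for every row.",
          class = "glyco_validation_error")
  }
  check_sex(panels$sex)
  for (col in c("a1c", "fructosamine", "ctni", "ldl")) {
    check_positive(panels[[col]], col)
  }
  panels
}

panel_year <- function(date) {
  if (inherits(date, "Date")) as.integer(format(date, "%Y")) else as.integer(date)
}
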