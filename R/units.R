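#' Convert A1c between NGSP percent and IFCC mmol/mol
#'
#' The NGSP/IFCC master equation `IFCC = 10.93 * NGSP - 23.50` maps percent
#' A1c to mmol/mol; laboratories report IFCC as an integer, so the forward
#' conversion rounds to the nearest mmol/mol (half-up). The inverse round-trips
#' within one quantization unit (about 0.05 percentage points).
#'
#' @param a1c_percent A1c in % (NGSP). Must exceed 2.15% so the IFCC value is
#'   positive.
#' @param a1c_ifcc A1c in mmol/mol (IFCC), strictly positive.
#' @return `a1c_percent_to_ifcc()`: integer-valued mmol/mol;
#'   `a1c_ifcc_to_percent()`: percent, rounded to 1 decimal.
#' @examples
#' a1c_percent_to_ifcc(5.0) # 31
#' a1c_percent_to_ifcc(5.7) # 39
#' a1c_ifcc_to_percent(42)  # 6.0
#' @export
a1c_percent_to_ifcc <- function(a1c_percent) {
  check_positive(a1c_percent, "a1c_percent")
  if (any(a1c_percent <= 23.5 / 10.93)) {
    abort("`a1c_percent` must exceed 2.15% (IFCC value would be non-positive).",
          class = "glyco_domain_error")
  }
  round_half_up(10.93 * a1c_percent - 23.5)
}

#' @rdname a1c_percent_to_ifcc
#' @export
a1c_ifcc_to_percent <- function(a1c_ifcc) {
  check_positive(a1c_ifcc, "a1c_ifcc")
  round_half_up((a1c_ifcc + 23.5) / 10.93, 1)
}

# A1c ratios are always taken on the IFCC scale; percent inputs convert first.
a1c_as_ifcc <- function(a1c, a1c_units) {
  ifelse(a1c_units == "percent", a1c_percent_to_ifcc(a1c), a1c)
}
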