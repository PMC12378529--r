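#' Worked-example biomarker panels
#'
#' The four-year annual panel series used throughout the documentation and
#' tests: a simulated individual progressing from normal to prediabetic
#' glycemia (A1c 5.5% to 6.0%) with rising fructosamine, troponin I and LDL.
#' Running it through [track_report()] reproduces the model's reference
#' sequential report, including the predicted next-year row.
#'
#' @return A tibble of four biomarker panels (2022-2025).
#' @examples
#' example_panels()
#' @export
example_panels <- function() {
  tibble(
    date = 2022:2025,
    sex = "male",
    a1c = c(5.5, 5.5, 5.7, 6.0),
    a1c_units = "percent",
    fructosamine = c(230, 230, 240, 262),
    ctni = c(2.6, 3.0, 3.2, 3.4),
    ldl = c(110, 120, 125, 130)
  )
}
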