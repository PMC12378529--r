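#' Reference constants of the glycation model
#'
#' Half-lives and optimal references used by the slope-intercept
#' extrapolation. The defaults are the model's published constants: half-lives
#' of 28.7 d (A1c), 16.5 d (fructosamine), 3 d (LDL) and 1 d (troponin I);
#' optimal A1c 31 mmol/mol (5.0%) and fructosamine 200 umol/L; troponin I
#' assay limit of detection 1.6 ng/L and LDL physiological floor 60 mg/dL.
#' All are configurable (e.g. a cTnI half-life between 2-4 h and 3.2 d is
#' defensible depending on ischemic state), but the extrapolation geometry
#' requires `halflife_a1c > halflife_fructosamine > halflife_ldl >
#' halflife_ctni`.
#'
#' @param halflife_a1c,halflife_fructosamine,halflife_ldl,halflife_ctni
#'   Substrate half-lives in days.
#' @param optimal_a1c Optimal A1c in mmol/mol (IFCC).
#' @param optimal_fructosamine Optimal fructosamine in umol/L.
#' @param ctni_lod Troponin I assay limit of detection, ng/L.
#' @param ldl_floor Lower physiological LDL reference, mg/dL.
#' @return An object of class `glyco_constants` (a named list).
#' @examples
#' glyco_constants()
#' glyco_constants(halflife_ctni = 2) # alternative troponin half-life
#' @export
glyco_constants <- function(halflife_a1c = 28.7,
                            halflife_fructosamine = 16.5,
                            halflife_ldl = 3,
                            halflife_ctni = 1,
                            optimal_a1c = 31,
                            optimal_fructosamine = 200,
                            ctni_lod = 1.6,
                            ldl_floor = 60) {
  const <- list(
    halflife_a1c = halflife_a1c,
    halflife_fructosamine = halflife_fructosamine,
    halflife_ldl = halflife_ldl,
    halflife_ctni = halflife_ctni,
    optimal_a1c = optimal_a1c,
    optimal_fructosamine = optimal_fructosamine,
    ctni_lod = ctni_lod,
    ldl_floor = ldl_floor
  )
  for (nm in names(const)) check_positive(const[[nm]], nm)
  hl <- c(const$halflife_a1c, const$halflife_fructosamine,
          const$halflife_ldl, const$halflife_ctni)
  if (any(diff(hl) >= 0)) {
    abort(paste("half-lives must satisfy a1c > fructosamine > ldl > ctni;",
                "the extrapolation is anchored at the two longest-lived",
                "substrates and evaluated below them."),
          class = "glyco_config_error")
  }
  structure(const, class = "glyco_constants")
}

#' @export
print.glyco_constants <- function(x, ...) {
  cat("Glycation model constants\n")
  cat(sprintf("  half-lives (d): A1c %.1f | fructosamine %.1f | LDL %.1f | cTnI %.1f\n",
              x$halflife_a1c, x$halflife_fructosamine, x$halflife_ldl, x$halflife_ctni))
  cat(sprintf("  optima: A1c %g mmol/mol, fructosamine %g umol/L\n",
              x$optimal_a1c, x$optimal_fructosamine))
  cat(sprintf("  cTnI LOD %g ng/L, LDL floor %g mg/dL\n", x$ctni_lod, x$ldl_floor))
  invisible(x)
}

#' Exclusionary screening limits
#'
#' Analyte ceilings beyond which the glycation model defers to diagnostic
#' work-up rather than monitoring: A1c above 46 mmol/mol (>6.4%) suggests
#' diabetes mellitus, LDL above 180 mg/dL severe hyperlipidemia, and troponin
#' I above 4.5 ng/L (women) or 5.0 ng/L (men) cardiac ischemia or injury.
#' The male troponin ceiling may be raised (values of 5-7 ng/L are supported
#' by ROC analyses); 5 ng/L is the default for sensitivity.
#'
#' @param a1c_max Maximum A1c in mmol/mol.
#' @param ldl_max Maximum LDL in mg/dL.
#' @param ctni_max_female,ctni_max_male Maximum troponin I in ng/L by sex.
#' @return An object of class `glyco_limits` (a named list).
#' @export
glyco_limits <- function(a1c_max = 46,
                         ldl_max = 180,
                         ctni_max_female = 4.5,
                         ctni_max_male = 5.0) {
  lim <- list(a1c_max = a1c_max, ldl_max = ldl_max,
              ctni_max_female = ctni_max_female, ctni_max_male = ctni_max_male)
  for (nm in names(lim)) check_positive(lim[[nm]], nm)
  if (ctni_max_male < ctni_max_female) {
    abort("`ctni_max_male` must be >= `ctni_max_female`.",
          class = "glyco_config_error")
  }
  structure(lim, class = "glyco_limits")
}

#' Calculated ranges of the glycation indices
#'
#' Derives the attainable range of each metric from the model constants and
#' exclusion limits: the lowest TGI is the optimal rate (1.0) times the
#' troponin assay LOD; the highest is the maximal admissible rate
#' (`rate_max`, 1.5 at the screening ceilings) times the sex-specific
#' troponin ceiling; LGI analogously against the LDL floor and ceiling.
#'
#' @param constants A [glyco_constants()] object.
#' @param limits A [glyco_limits()] object.
#' @param rate_max Maximal glycation rate attainable inside the screening
#'   limits (dimensionless, default 1.5).
#' @return A tibble with one row per metric/sex combination:
#'   `metric`, `sex`, `lower`, `upper`.
#' @examples
#' glyco_ranges()
#' @export
glyco_ranges <- function(constants = glyco_constants(),
                         limits = glyco_limits(),
                         rate_max = 1.5) {
  check_positive(rate_max, "rate_max")
  tibble(
    metric = c("tgr", "lgr", "tgi", "tgi", "lgi"),
    sex    = c("any", "any", "female", "male", "any"),
    lower  = c(1, 1,
               round_half_up(1 * constants$ctni_lod, 1),
               round_half_up(1 * constants$ctni_lod, 1),
               round_half_up(1 * constants$ldl_floor)),
    upper  = c(rate_max, rate_max,
               round_half_up(rate_max * limits$ctni_max_female, 2),
               round_half_up(rate_max * limits$ctni_max_male, 2),
               round_half_up(rate_max * limits$ldl_max))
  )
}
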