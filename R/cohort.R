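#' Synthetic cohort specification
#'
#' Describes a seeded synthetic cohort for end-to-end testing of the
#' pipeline: each individual follows one of the two trajectory archetypes,
#' with the underlying biomarkers interpolating linearly between the
#' archetype's start and end values and independent Gaussian noise added per
#' analyte per draw. The glycemic analytes drift proportionally (the A1c and
#' fructosamine ratios share one path), so in the noise-free limit the
#' troponin glycation rate equals the archetype's rate path exactly and the
#' preset endpoints are recovered. A1c is generated on the continuous IFCC
#' scale; its noise SD is specified in percent points and converted via the
#' NGSP/IFCC master-equation slope (10.93).
#'
#' The noise defaults (0.1% A1c, 5 umol/L fructosamine, 0.2 ng/L cTnI,
#' 5 mg/dL LDL) are synthetic-fixture values of realistic assay magnitude,
#' not published constants.
#'
#' @param n Number of individuals.
#' @param weights Named archetype mixture weights (`normal`, `prediabetic`);
#'   must sum to 1.
#' @param noise_sd Named per-analyte Gaussian SDs: `a1c` (percent points),
#'   `fructosamine` (umol/L), `ctni` (ng/L), `ldl` (mg/dL). All must be
#'   non-negative.
#' @param span Years covered (default 30).
#' @param interval Sampling interval in years (default 1).
#' @param start_year Calendar year of the first draw.
#' @param seed Integer seed; a fixed seed gives bit-identical cohorts.
#' @return A `glyco_cohort_spec` (named list).
#' @export
cohort_spec <- function(n = 10,
                        weights = c(normal = 0.5, prediabetic = 0.5),
                        noise_sd = c(a1c = 0.1, fructosamine = 5,
                                     ctni = 0.2, ldl = 5),
                        span = 30, interval = 1, start_year = 2000L,
                        seed = 1L) {
  stopifnot(n >= 1, span > 0, interval > 0)
  if (!setequal(names(weights), c("normal", "prediabetic")) ||
      abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    abort("`weights` must be non-negative, named normal/prediabetic and sum to 1.",
          class = "glyco_config_error")
  }
  if (!all(c("a1c", "fructosamine", "ctni", "ldl") %in% names(noise_sd)) ||
      any(noise_sd < 0)) {
    abort("`noise_sd` must name a1c, fructosamine, ctni and ldl, all >= 0.",
          class = "glyco_config_error")
  }
  structure(list(n = as.integer(n), weights = weights, noise_sd = noise_sd,
                 span = span, interval = interval,
                 start_year = as.integer(start_year),
                 seed = as.integer(seed)),
            class = "glyco_cohort_spec")
}

#' Simulate a synthetic cohort of annual panel series
#'
#' @param spec A [cohort_spec()].
#' @param constants A [glyco_constants()] object; the archetype start values
#'   are its optimal references (A1c 31 mmol/mol, fructosamine 200 umol/L,
#'   cTnI at the LOD, LDL at the floor).
#' @return A tibble of panels with `id` and `archetype` columns prepended,
#'   one row per individual per draw, ready for [glycation_metrics()] or
#'   [glyco_series()] (per individual).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 4, seed = 42))
#' dplyr::count(cohort, id, archetype)
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            constants = glyco_constants()) {
  stopifnot(inherits(spec, "glyco_cohort_spec"))
  withr::with_seed(spec$seed, simulate_cohort_impl(spec, constants))
}

simulate_cohort_impl <- function(spec, constants) {
  ends <- list(
    normal = list(rate = 1.11, ctni = 2.6, ldl = 100),
    prediabetic = list(rate = 1.24, ctni = 3.4, ldl = 140)
  )
  archetypes <- sample(names(spec$weights), spec$n, replace = TRUE,
                       prob = spec$weights)
  sexes <- sample(c("female", "male"), spec$n, replace = TRUE)
  times <- seq(0, spec$span, by = spec$interval)
  u <- times / spec$span
  sd <- spec$noise_sd
  floorval <- 1e-3  # analytes are strictly positive; noise never clips in practice

  purrr::map_dfr(seq_len(spec$n), function(i) {
    e <- ends[[archetypes[[i]]]]
    rate <- 1 + u * (e$rate - 1)
    k <- length(times)
    tibble(
      id = sprintf("ind%03d", i),
      archetype = archetypes[[i]],
      date = spec$start_year + as.integer(round(times)),
      sex = sexes[[i]],
      a1c = pmax(constants$optimal_a1c * rate +
                   rnorm(k, 0, sd[["a1c"]] * 10.93), floorval),
      a1c_units = "mmol_mol",
      fructosamine = pmax(constants$optimal_fructosamine * rate +
                            rnorm(k, 0, sd[["fructosamine"]]), floorval),
      ctni = pmax(constants$ctni_lod + u * (e$ctni - constants$ctni_lod) +
                    rnorm(k, 0, sd[["ctni"]]), floorval),
      ldl = pmax(constants$ldl_floor + u * (e$ldl - constants$ldl_floor) +
                   rnorm(k, 0, sd[["ldl"]]), floorval)
    )
  })
}

#' Per-individual excess burden of a simulated cohort
#'
#' Runs every individual of a simulated cohort through the metrics pipeline
#' and integrates the excess of each glycation index above its optimal
#' baseline over the sampled span.
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @param constants A [glyco_constants()] object.
#' @return A tibble: `id`, `archetype`, `tgi_burden`, `lgi_burden`.
#' @export
cohort_burden <- function(cohort, constants = glyco_constants()) {
  base_tgi <- round_half_up(constants$ctni_lod, 1)
  base_lgi <- round_half_up(constants$ldl_floor)
  metrics <- glycation_metrics(cohort, constants)
  metrics$year <- panel_year(metrics$date)
  one_burden <- function(year, index, baseline) {
    excess_burden(tibble(time = year - min(year), index = index), baseline)$auc
  }
  dplyr::summarise(
    dplyr::group_by(metrics, .data$id, .data$archetype),
    tgi_burden = one_burden(.data$year, .data$tgi, base_tgi),
    lgi_burden = one_burden(.data$year, .data$lgi, base_lgi),
    .groups = "drop"
  )
}
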