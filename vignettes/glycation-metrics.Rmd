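---
title: "Glycation metrics from circulating biomarkers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycation metrics from circulating biomarkers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotrack)
library(dplyr)
```

## The model

Glycation — the non-enzymatic, irreversible attachment of glucose to
proteins — proceeds at a rate set by pH, temperature, glucose exposure and
the physical characteristics of the substrate, chiefly its half-life. In a
healthy adult pH and temperature are effectively constant, so two substrates
bathed in the same blood differ in accumulated glycation mainly through
their half-lives. That observation motivates a proxy: the glycation burden
of cardiac troponin I and of LDL, which cannot be assayed directly in situ,
is extrapolated from two glycated analytes that *are* routinely measured —
hemoglobin A1c (half-life 28.7 d) and fructosamine (16.5 d).

For one laboratory draw the pipeline is:

1. **Unit normalisation.** A1c is accepted in % (NGSP) or mmol/mol (IFCC),
   tagged explicitly — never inferred from magnitude. Percent converts by
   the master equation IFCC = 10.93 × NGSP − 23.50, rounded to the integer
   mmol/mol that laboratories report. All ratios are formed on the IFCC
   scale: the reference worked example (A1c 39 mmol/mol vs optimum 31)
   gives 39/31 = 1.26, which only the mmol/mol reading reproduces.
2. **Concentration ratios.** rA = A1c / 31 mmol/mol and
   rF = fructosamine / 200 µmol/L, each rounded to 2 decimals. The optima
   are the glycemic levels associated with minimal cardiac risk; at them the
   relative glycation rate is defined as 1.0.
3. **Slope-intercept extrapolation.** The line through
   (28.7 d, rA) and (16.5 d, rF) — half-life on the x-axis, relative
   glycation on the y-axis — is evaluated at the target substrate's
   half-life: 1 d for troponin I (TGR) and 3 d for LDL (LGR), rounded to
   2 decimals. Equivalently, before rounding,
   rate(h) = rF + (rA − rF)(h − 16.5)/12.2, a weighted combination of the
   two ratios whose weights sum to one.
4. **Indices.** TGI = TGR × cTnI (ng/L, 1 decimal) and LGI = LGR × LDL
   (mg/dL, integer) estimate the *total* glycated troponin and LDL in
   circulation.

Assumptions inherited from the model: linear early-phase kinetics (the full
reaction is likely nonlinear; linearity is the stated first-order
approximation), constant physiological pH and temperature, steady state
between myocardial and circulating troponin, and genetically fixed substrate
structure over a lifetime. None of these are verified by this package; it
implements the arithmetic.

## Rounding protocol

Rounding is part of the model's definition, not cosmetic. Ratios are rounded
to 2 decimals *before* the slope-intercept step; rates to 2 decimals;
TGI to 1 decimal; LGI to the nearest integer. All rounding is half-up
(`round_half_up()`), not banker's rounding — the reference report contains a
142.5 → 143 cell that half-even would break. With unrounded ratios the later
report rows do not reproduce (e.g. ratios 1.35/1.31 must give TGR 1.26; the
unrounded pair gives 1.25), which is why the 2-decimal intermediate is
load-bearing.

The reference sequential report contains two cells this protocol cannot
reproduce: its early rows print TGR = LGR = 1.1 where the procedure gives
1.10/1.11 (a 1-decimal print), and one year prints LGR 1.14 / LGI 143 where
the same biomarkers that elsewhere yield LGR 1.13 give LGI 141. The package
computes the protocol value; the discrepancy is documented rather than
special-cased, and one acceptance expectation intentionally records the
mismatch.

```{r}
glycation_metrics(example_panels()) |>
  select(date, ratio_a1c, ratio_fructosamine, tgr, tgi, lgr, lgi)
```

## Classification and screening

`quartile_table()` holds fixed reference bands (not population quantiles)
for cTnI, TGR, TGI, LDL, LGR and LGI. Bands are closed on their printed
endpoints; values falling in the precision gaps between bands (e.g. TGR
1.155 between 1.15 and 1.16) are assigned to the lower band, making
classification total without inventing unprinted edges. Troponin bands are
sex-specific in the upper quartiles because the exclusionary troponin limits
are (4.5 ng/L women, 5.0 ng/L men); the TGI ceilings are 1.5 × those
limits, so raising the male limit (5–7 ng/L is defensible) moves only the
male band-3/4 edges. The LGI band floor follows the published quartile table
(60, the optimal rate times the LDL floor) rather than the alternative
printed range minimum of 80, which contradicts its own derivation.

`screen_exclusions()` flags analytes *strictly* above their ceilings (A1c
46 mmol/mol, LDL 180 mg/dL, sex-specific troponin); a value at the limit
passes. Screening marks panels as outside the model's monitoring domain — it
is not a diagnosis, and the package makes no treatment recommendation.

## Sequential tracking and forecasting

`glyco_series()` orders one panel per year (duplicate years are errors; gaps
longer than a year warn, since the model is explicitly a *sequential*
monitoring device). `forecast_next()` fits each raw biomarker column by
ordinary least squares on a 0-based year index and evaluates one year ahead
— a one-year horizon only, because individual biomarker variability makes
longer extrapolation unreliable. Forecasts are rounded to each column's
reporting precision (0.1 % A1c, 1 µmol/L, 0.1 ng/L, 1 mg/dL) *before* the
predicted row's metrics are recomputed from them, so a predicted row obeys
exactly the same arithmetic as an observed one. The reference forecast row
prints LDL 137 where the regression lands exactly on 137.5; this package's
half-up protocol yields 138, within the half-unit ambiguity of that cell.

The predicted TGR/LGR cells of the reference report are reproducible neither
by recomputing from forecast biomarkers (≈1.28) nor by regressing the metric
columns (1.27/1.29); the default mode recomputes, for internal consistency,
and `mode = "column_ols"` exposes the alternative. `divergence_notes()`
annotates consecutive-year patterns (troponin rising with TGR = glycation-
consistent; troponin rising with flat TGR = non-glycation factor such as
hypertension; troponin and LDL falling together = consistent with an
LDL-lowering intervention). `glycation_gap()` flags |rA − rF| above a
threshold as a glucose-stability/assay warning; the default 0.15 is a
configurable working value — no authoritative cut-off exists.

## Trajectories and cumulative burden

`trajectory_preset()` encodes the two published 30-year archetypes, both
starting at the optimal references (TGI 1.6, LGI 60): *normal* (TGR/LGR →
1.11, cTnI → 2.6 ng/L, LDL → 100 mg/dL) and *prediabetic* (TGR → 1.24,
LGR → 1.25, cTnI → 3.4 ng/L, LDL → 140 mg/dL). The endpoint index is the
rate endpoint times the concentration endpoint, rounded to the index's
display precision *before* integration, and the trajectory is linear in
index space. Both choices are fixed by exact reproduction of the published
burden figures: the excess-area reading gives 19.5/39 (TGI) and 765/1725
(LGI) where a raw-index AUC gives 67.3/123, and interpolating rate and
concentration separately (a convex index path, available as
`mode = "component-linear"`) gives 18.74, not 19.5.

`excess_burden()` integrates max(index − baseline, 0) by the trapezoid rule
over a uniform grid; for linear trajectories this equals
span × (endpoint − baseline)/2 to machine precision at any grid density ≥ 2,
which the tests verify against both the closed form and an independent
integration routine.

```{r}
burden_summary()
```

## Synthetic cohorts

`simulate_cohort()` exists so every pipeline stage is testable without
patient data. Each simulated individual follows one archetype; the
underlying biomarkers interpolate linearly between the archetype start and
end values with independent Gaussian noise per analyte per draw (defaults
0.1 % A1c, 5 µmol/L fructosamine, 0.2 ng/L cTnI, 5 mg/dL LDL — fixture
values of realistic assay magnitude, not published constants). Two
generator-design points:

* The two glycemic analytes share one relative drift path (rA = rF), so the
  extrapolation line is flat and the noise-free year-30 TGR equals the
  archetype's rate endpoint exactly — the property the recovery tests pin.
* A1c is generated on the *continuous* IFCC scale (noise SD converted from
  percent by the master-equation slope 10.93); generating in percent and
  converting would quantise to integer mmol/mol and break exact recovery.

The generator emulates smooth annual drift with assay noise. It does not
emulate intercurrent illness, medication changes, smoking effects on
troponin, anemia, or assay platform changes — all confounders the model
defers to clinical judgement — so passing tests demonstrate arithmetic
correctness of the pipeline, not clinical validity on real cohorts.
Default problem sizes (tens of individuals, 31 annual draws) keep the whole
suite deterministic and fast while leaving Monte-Carlo error on the
two-fold burden ratio within ±15 %.

## Numerical and degenerate-input choices

* Half-up rounding everywhere, via a `sqrt(eps)` nudge so values stored just
  under x.5 by floating point (1.335) still round up.
* Coincident anchor half-lives are a configuration error (degenerate line);
  the constructor enforces the half-life ordering A1c > fructosamine > LDL
  > cTnI.
* Fructosamine-dominant panels (rF > rA, negative slope) are computed
  normally — the extrapolation then exceeds both anchors — and flagged via
  `negative_slope` and the glycation gap rather than refused.
* Zero-length trajectories, sub-2-point grids, non-positive analytes and
  mismatched burden comparisons raise classed errors
  (`glyco_domain_error`, `glyco_validation_error`, `glyco_config_error`);
  the CLI maps these to exit codes 2/2/3.
* Burden ratios with a zero denominator return `NA` with an explicit
  narrative rather than `Inf`.

## Limitations

The package is a faithful implementation of a theoretical model: no clinical
trial or original human data stands behind the constants, the quartile
bands, or the trajectories, and the model's own authors frame it as a
monitoring adjunct, not a diagnostic. Known internal inconsistencies of the
published tables (the 1.14/143 report cells, the LGI range minimum, the
predicted-row rate cells) are documented above and in the test suite rather
than silently reconciled.
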