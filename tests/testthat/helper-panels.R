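# fixture builders shared across the suite ----------------------------------

# single panel with overridable fields; defaults are the worked-example draw
panel <- function(date = 2024, sex = "female", a1c = 39,
                  a1c_units = "mmol_mol", fructosamine = 240,
                  ctni = 3.2, ldl = 125) {
  tibble::tibble(date = date, sex = sex, a1c = a1c, a1c_units = a1c_units,
                 fructosamine = fructosamine, ctni = ctni, ldl = ldl)
}

# panel pinned exactly at the optimal references
optimal_panel <- function(...) {
  panel(a1c = 31, fructosamine = 200, ctni = 1.6, ldl = 60, ...)
}

# independent closed-form oracle for the two-point extrapolation:
# Y(h) = rF + (rA - rF) * (h - h_F) / (h_A - h_F), unrounded
oracle_rate <- function(ra, rf, h, h_a = 28.7, h_f = 16.5) {
  rf + (ra - rf) * (h - h_f) / (h_a - h_f)
}

# independent normal-equations OLS oracle
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}
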