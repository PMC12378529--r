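#' Read biomarker panels from CSV
#'
#' Reads a laboratory panel CSV with header
#' `date,sex,a1c,a1c_units,fructosamine,ctni,ldl` (comma-separated, UTF-8,
#' ISO dates or plain years). Malformed rows are reported with their line
#' number and dropped so a single bad draw does not abort a batch; if every
#' row is invalid the read errors.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of panels. Rows dropped as malformed are
#'   listed in the `dropped` attribute (row numbers + reasons).
#' @export
read_panel_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("date", "sex", "a1c", "a1c_units", "fructosamine", "ctni", "ldl")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort(paste0("CSV is missing column(s): ", paste(missing, collapse = ", ")),
          class = "glyco_validation_error")
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  parsed <- dplyr::mutate(
    raw,
    .line = dplyr::row_number() + 1L,  # header is line 1
    a1c = num(.data$a1c), fructosamine = num(.data$fructosamine),
    ctni = num(.data$ctni), ldl = num(.data$ldl)
  )
  bad_reason <- purrr::pmap_chr(
    parsed[, c("sex", "a1c", "a1c_units", "fructosamine", "ctni", "ldl")],
    function(sex, a1c, a1c_units, fructosamine, ctni, ldl) {
      r <- c(
        if (!sex %in% c("female", "male")) "sex must be female/male (no default)",
        if (!a1c_units %in% c("percent", "mmol_mol")) "a1c_units must be percent/mmol_mol",
        if (anyNA(c(a1c, fructosamine, ctni, ldl)) ||
              any(c(a1c, fructosamine, ctni, ldl) <= 0, na.rm = TRUE))
          "analytes must be positive numbers"
      )
      if (length(r)) paste(r, collapse = "; ") else NA_character_
    }
  )
  bad <- which(!is.na(bad_reason))
  for (i in bad) {
    warn(sprintf("line %d: %s (row skipped)", parsed$.line[[i]], bad_reason[[i]]))
  }
  good <- parsed[setdiff(seq_len(nrow(parsed)), bad), , drop = FALSE]
  if (nrow(good) == 0) {
    abort("no valid rows in panel CSV.", class = "glyco_validation_error")
  }
  date <- as.Date(good$date, format = "%Y-%m-%d")  # NA for bare years
  good$date <- if (anyNA(date)) as.integer(good$date) else date
  out <- validate_panels(dplyr::select(good, -".line"))
  attr(out, "dropped") <- tibble(line = parsed$.line[bad],
                                 reason = bad_reason[bad])
  out
}

#' Write a sequential report to CSV
#'
#' Writes a [track_report()] tibble in the reference report layout.
#'
#' @param report A tibble from [track_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  readr::write_csv(report, path, progress = FALSE)
  invisible(path)
}

# tool configuration --------------------------------------------------------

default_config <- function() {
  list(
    constants = unclass(glyco_constants()),
    limits = unclass(glyco_limits()),
    rate_max = 1.5,
    gap_threshold = 0.15,
    forecast_mode = "recompute",
    burden_mode = "index-linear"
  )
}

#' Read or write the tool configuration
#'
#' The tool configuration is a flat YAML key/value file holding overrides of
#' the model constants, exclusion limits, the glycation-gap threshold and the
#' forecast/burden modes. Unspecified keys fall back to the model defaults.
#' Keys for constants and limits are flat (e.g. `halflife_ctni: 2`,
#' `ctni_max_male: 6`).
#'
#' @param path Path to a YAML config file; for `read_config()`, `NULL`
#'   returns pure defaults.
#' @param config For `write_config()`, a config list as returned by
#'   `read_config()`.
#' @return `read_config()`: a `glyco_config` list with elements `constants`
#'   ([glyco_constants()]), `limits` ([glyco_limits()]), `rate_max`,
#'   `gap_threshold`, `forecast_mode`, `burden_mode`.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.list(user)) {
      abort("config file must be a flat key/value mapping.",
            class = "glyco_config_error")
    }
    for (key in names(user)) {
      if (key %in% names(cfg$constants)) {
        cfg$constants[[key]] <- user[[key]]
      } else if (key %in% names(cfg$limits)) {
        cfg$limits[[key]] <- user[[key]]
      } else if (key %in% c("rate_max", "gap_threshold",
                            "forecast_mode", "burden_mode")) {
        cfg[[key]] <- user[[key]]
      } else {
        abort(sprintf("unknown config key \"%s\".", key),
              class = "glyco_config_error")
      }
    }
  }
  cfg$constants <- do.call(glyco_constants, cfg$constants)
  cfg$limits <- do.call(glyco_limits, cfg$limits)
  if (!cfg$forecast_mode %in% c("recompute", "column_ols")) {
    abort("forecast_mode must be recompute or column_ols.",
          class = "glyco_config_error")
  }
  if (!cfg$burden_mode %in% c("index-linear", "component-linear")) {
    abort("burden_mode must be index-linear or component-linear.",
          class = "glyco_config_error")
  }
  structure(cfg, class = "glyco_config")
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "glyco_config"))
  flat <- c(unclass(config$constants), unclass(config$limits),
            config[c("rate_max", "gap_threshold", "forecast_mode", "burden_mode")])
  yaml::write_yaml(flat, path)
  invisible(path)
}

# log the full effective constant set so defaults vs overrides are auditable
echo_config <- function(config) {
  flat <- c(unclass(config$constants), unclass(config$limits),
            config[c("rate_max", "gap_threshold", "forecast_mode", "burden_mode")])
  inform(paste0("effective config: ",
                paste(names(flat), unlist(flat), sep = "=", collapse = " ")))
  invisible(config)
}
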