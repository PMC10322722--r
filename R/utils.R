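# Internal validators shared across modules.

assert_carbon_number <- function(n) {
  if (!is.numeric(n) || length(n) < 1 || any(is.na(n))) {
    abort("`n` must be a numeric vector of carbon-chain lengths.")
  }
  if (any(n < 1) || any(n != round(n))) {
    abort("`n` must contain positive integers (carbon-chain length >= 1).")
  }
  invisible(as.numeric(n))
}

assert_fraction <- function(f, name = "f") {
  if (!is.numeric(f) || any(is.na(f))) {
    abort(sprintf("`%s` must be numeric.", name))
  }
  if (any(f < 0) || any(f >= 1)) {
    abort(sprintf("`%s` must lie in [0, 1).", name))
  }
  invisible(as.numeric(f))
}

# A culture time series is a data frame with at least time_d, replicate,
# sulfide_mM; optional dic_mM, sulfate_mM, dilution (0/1). Times must be
# strictly increasing within a replicate and concentrations non-negative.
assert_culture_series <- function(series, require = "sulfide_mM") {
  if (!is.data.frame(series)) {
    abort("`series` must be a data frame of culture measurements.")
  }
  needed <- unique(c("time_d", "replicate", require))
  missing <- setdiff(needed, names(series))
  if (length(missing) > 0) {
    abort(paste0("`series` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad_order <- series |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(ok = all(diff(.data$time_d) > 0), .groups = "drop")
  if (!all(bad_order$ok)) {
    abort("`time_d` must be strictly increasing within each replicate.")
  }
  conc_cols <- intersect(c("sulfide_mM", "dic_mM", "sulfate_mM"), names(series))
  for (col in conc_cols) {
    if (any(series[[col]] < 0, na.rm = TRUE)) {
      abort(sprintf("Column `%s` contains negative concentrations.", col))
    }
  }
  invisible(series)
}
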