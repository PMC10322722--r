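#' Split a culture time series at dilution events
#'
#' Maintenance dilutions (1:3 with fresh medium once sulfide accumulates)
#' partition a sulfide trajectory into growth segments. A row whose
#' `dilution` flag is 1 records the first (post-dilution) measurement of a
#' new segment. `segment_series()` adds an integer `segment` column,
#' numbered from 1 within each replicate; all input rows and columns are
#' preserved, so dropping `segment` reproduces the input.
#'
#' A dilution flag on the first record of a replicate would open with an
#' empty leading segment; it is dropped with a warning and numbering still
#' starts at 1.
#'
#' @param series Culture time series data frame (`time_d`, `replicate`,
#'   `sulfide_mM`, optional `dilution`). A missing `dilution` column means a
#'   single segment per replicate.
#' @return The input tibble with an added integer `segment` column.
#' @examples
#' ts <- tibble::tibble(
#'   time_d = 0:5, replicate = "a",
#'   sulfide_mM = c(1, 4, 12, 4, 8, 14),
#'   dilution = c(0, 0, 0, 1, 0, 0)
#' )
#' segment_series(ts)
#' @export
segment_series <- function(series) {
  if (nrow(series) == 0) {
    out <- as_tibble(series)
    out$segment <- integer(0)
    return(out)
  }
  assert_culture_series(series)
  out <- as_tibble(series)
  if (!"dilution" %in% names(out)) out$dilution <- 0
  out <- out |>
    dplyr::group_by(.data$replicate) |>
    dplyr::arrange(.data$time_d, .by_group = TRUE) |>
    dplyr::mutate(segment = cumsum(.data$dilution) + 1L) |>
    dplyr::mutate(segment = {
      if (.data$dilution[1] == 1) {
        warn("dilution flag on the first record: leading empty segment dropped.")
        as.integer(.data$segment - 1L)
      } else {
        as.integer(.data$segment)
      }
    }) |>
    dplyr::ungroup()
  if (!"dilution" %in% names(series)) out$dilution <- NULL
  out
}

#' Fit an exponential activity model to a sulfide segment
#'
#' Sulfide accumulation during active growth follows
#' \eqn{y = n_0 e^{m t}}; the activity doubling time is \eqn{\ln(2)/m}.
#' The fit is ordinary least squares of \eqn{\ln(\mathrm{sulfide})} on time
#' (the log-linear reading of an exponential trend line), with time measured
#' from the start of the segment so that `n0` is the amplitude at segment
#' start.
#'
#' Points are filtered before fitting: sulfide must exceed `min_sulfide`
#' (assay background) and stay below `plateau_fraction` times the segment
#' maximum (to exclude the plateau where sulfide production stalls).
#'
#' @param segment A single-segment data frame with columns `time_d` and
#'   `sulfide_mM` (e.g. one group of [segment_series()] output).
#' @param min_sulfide Lower sulfide cutoff in mM (default 1).
#' @param plateau_fraction Upper cutoff as a fraction of the segment maximum
#'   (default 0.9).
#' @return An object of class `growth_fit`: a list with elements `m`
#'   (per day), `n0` (mM), `doubling_time` (days; `NA` with a warning when
#'   `m <= 0`), `r_squared`, `n_points`, `segment`, `replicate`, and the
#'   underlying `lm` fit. Use [glance()] for a one-row tibble and [tidy()]
#'   for coefficient-level detail.
#' @examples
#' seg <- tibble::tibble(time_d = seq(0, 30, 3), replicate = "a",
#'                       sulfide_mM = 0.5 * exp(0.1 * seq(0, 30, 3)))
#' fit <- fit_exponential(seg, min_sulfide = 0)
#' glance(fit)
#' @export
fit_exponential <- function(segment, min_sulfide = 1, plateau_fraction = 0.9) {
  if (!is.data.frame(segment) || !all(c("time_d", "sulfide_mM") %in% names(segment))) {
    abort("`segment` must contain `time_d` and `sulfide_mM` columns.")
  }
  seg_max <- max(segment$sulfide_mM)
  usable <- segment |>
    dplyr::filter(
      .data$sulfide_mM > min_sulfide,
      .data$sulfide_mM < plateau_fraction * seg_max
    )
  if (nrow(usable) < 3) {
    abort("insufficient points: fewer than 3 usable sulfide measurements after filtering.")
  }
  t0 <- min(segment$time_d)
  fit <- lm(log(sulfide_mM) ~ I(time_d - t0), data = usable)
  m <- unname(coef(fit)[2])
  doubling <- if (m > 0) log(2) / m else NA_real_
  if (m <= 0) {
    warn("non-positive specific rate: doubling time undefined.")
  }
  structure(
    list(
      m = m,
      n0 = exp(unname(coef(fit)[1])),
      doubling_time = doubling,
      # summary.lm warns on numerically perfect fits (noise-free input); the
      # R^2 itself is still well defined
      r_squared = suppressWarnings(summary(fit)$r.squared),
      n_points = nrow(usable),
      segment = if ("segment" %in% names(usable)) usable$segment[1] else NA_integer_,
      replicate = if ("replicate" %in% names(usable)) as.character(usable$replicate[1]) else NA_character_,
      fit = fit
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Exponential activity fit\n")
  cat(sprintf("  m = %.4g /d, n0 = %.4g mM, doubling time = %.4g d (R^2 = %.3f, n = %d)\n",
              x$m, x$n0, x$doubling_time, x$r_squared, x$n_points))
  invisible(x)
}

#' @describeIn fit_exponential One-row summary tibble of the fit.
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(
    replicate = x$replicate,
    segment = x$segment,
    m = x$m,
    n0 = x$n0,
    doubling_time = x$doubling_time,
    r_squared = x$r_squared,
    n_points = x$n_points
  )
}

#' @describeIn fit_exponential Coefficient-level tibble (`log_n0` and `m`)
#'   with standard errors from the log-linear regression.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = c("log_n0", "m"),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' Doubling times over the first growth segments of a culture
#'
#' Fits the exponential activity model to each of the first
#' `segments` growth segments (default the first two, the convention for
#' reporting activity doubling times) of every replicate and summarises.
#' Segments that cannot be fitted (too few usable points) are dropped with a
#' warning; if no segment can be fitted the function errors.
#'
#' @inheritParams fit_exponential
#' @param series Culture time series data frame; segmented internally via
#'   [segment_series()] if no `segment` column is present.
#' @param segments Integer vector of segment numbers to fit (default `1:2`).
#' @return A tibble with one row per fitted replicate x segment (columns as
#'   [glance()] of a `growth_fit`), with attribute `mean_doubling_time`, the
#'   arithmetic mean doubling time over all fitted segments (also accessible
#'   via `attr(x, "mean_doubling_time")`).
#' @export
doubling_time_summary <- function(series, min_sulfide = 1, plateau_fraction = 0.9,
                                  segments = 1:2) {
  seg <- if ("segment" %in% names(series)) as_tibble(series) else segment_series(series)
  pieces <- seg |>
    dplyr::filter(.data$segment %in% segments) |>
    dplyr::group_by(.data$replicate, .data$segment) |>
    dplyr::group_split()
  fits <- purrr::map(pieces, function(d) {
    tryCatch(
      glance(fit_exponential(d, min_sulfide = min_sulfide, plateau_fraction = plateau_fraction)),
      error = function(e) {
        warn(sprintf("replicate %s segment %s: %s",
                     as.character(d$replicate[1]), d$segment[1], conditionMessage(e)))
        NULL
      }
    )
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    abort("no segment could be fitted: all segments lack usable points.")
  }
  out <- dplyr::bind_rows(fits)
  attr(out, "mean_doubling_time") <- mean(out$doubling_time, na.rm = TRUE)
  out
}

#' Classify sustained activity across dilution segments
#'
#' Substrate-range and temperature incubations count as successful when
#' activity is sustained over repeated dilutions: at least
#' `required_segments` consecutive growth segments must each push sulfide
#' above `threshold` (the >10 mM dilution trigger used in substrate-range
#' tests). The classification is monotone in the threshold: success at a
#' given threshold implies success at any lower one.
#'
#' @inheritParams doubling_time_summary
#' @param threshold Sulfide concentration (mM) a segment must exceed
#'   (default 10).
#' @param required_segments Number of consecutive passing segments required
#'   (default 2).
#' @param label Optional substrate or temperature label stored in the output.
#' @return A tibble with one row per replicate: `label`, `replicate`,
#'   `segments_completed` (number of segments), `success`, and `peaks`, a
#'   list-column of per-segment peak sulfide (mM).
#' @examples
#' ts <- tibble::tibble(
#'   time_d = 0:5, replicate = "a",
#'   sulfide_mM = c(2, 12, 13, 4, 9, 11),
#'   dilution = c(0, 0, 0, 1, 0, 0)
#' )
#' classify_sustained_activity(ts, label = "C6")
#' @export
classify_sustained_activity <- function(series, threshold = 10, required_segments = 2,
                                        label = NA_character_) {
  seg <- if ("segment" %in% names(series)) as_tibble(series) else segment_series(series)
  seg |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(d, key) {
      peaks <- d |>
        dplyr::group_by(.data$segment) |>
        dplyr::summarise(peak = max(.data$sulfide_mM), .groups = "drop") |>
        dplyr::arrange(.data$segment)
      passing <- peaks$peak > threshold
      runs <- rle(passing)
      ok <- any(runs$values & runs$lengths >= required_segments)
      tibble(
        label = label,
        segments_completed = nrow(peaks),
        success = ok,
        peaks = list(setNames(peaks$peak, peaks$segment))
      )
    }) |>
    dplyr::ungroup()
}
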