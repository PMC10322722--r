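#' Plot culture concentration trajectories
#'
#' Sulfide (and, where present, DIC and sulfate) over time, one colour per
#' replicate, with dilution events marked by vertical dashed lines. Sulfide
#' is conventionally inspected on a log2 axis when reading off doubling
#' times; set `log2_sulfide = TRUE` for that view.
#'
#' @param series Culture time series tibble.
#' @param log2_sulfide Use a log2 y axis for the sulfide panel.
#' @return A ggplot object.
#' @export
plot_culture_series <- function(series, log2_sulfide = FALSE) {
  assert_culture_series(series)
  conc_cols <- intersect(c("sulfide_mM", "dic_mM", "sulfate_mM"), names(series))
  long <- series |>
    tidyr::pivot_longer(dplyr::all_of(conc_cols),
                        names_to = "analyte", values_to = "mM") |>
    dplyr::mutate(analyte = sub("_mM$", "", .data$analyte))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_d, .data$mM,
                                          colour = .data$replicate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "time (d)", y = "concentration (mM)") +
    ggplot2::theme_minimal()
  if ("dilution" %in% names(series) && any(series$dilution == 1)) {
    dil <- unique(series$time_d[series$dilution == 1])
    p <- p + ggplot2::geom_vline(xintercept = dil, linetype = "dashed",
                                 colour = "grey50")
  }
  if (log2_sulfide) {
    p <- p + ggplot2::scale_y_continuous(trans = "log2")
  }
  p
}

#' Plot an exponential activity fit
#'
#' The filtered sulfide points of a segment on a log2 axis with the fitted
#' exponential overlaid; the slope on this axis is the reciprocal doubling
#' time.
#'
#' @param fit A `growth_fit` from [fit_exponential()].
#' @return A ggplot object.
#' @export
plot_growth_fit <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  d <- fit$fit$model
  names(d) <- c("log_sulfide", "t")
  d$t <- as.numeric(d$t)
  d$sulfide_mM <- exp(d$log_sulfide)
  grid <- tibble(t = seq(min(d$t), max(d$t), length.out = 100))
  grid$sulfide_mM <- fit$n0 * exp(fit$m * grid$t)
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$sulfide_mM)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(
      x = "time since segment start (d)", y = "sulfide (mM, log2)",
      title = sprintf("doubling time %.1f d (R² = %.3f)",
                      fit$doubling_time, fit$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-gene expression with the organism mean line
#'
#' FPK values per gene on a log10 axis, faceted by sample, with each
#' organism's arithmetic-mean FPK drawn as a horizontal line — the standard
#' way to show which genes sit above average expression.
#'
#' @param norm Expression table with `fpk_*` columns (see [fpk()]).
#' @param highlight Optional gene ids to label.
#' @return A ggplot object.
#' @export
plot_expression <- function(norm, highlight = NULL) {
  fpk_cols <- grep("^fpk_", names(norm), value = TRUE)
  if (length(fpk_cols) == 0) abort("no `fpk_*` columns: run fpk() first.")
  norm2 <- as_tibble(norm)
  if (!"organism" %in% names(norm2)) norm2$organism <- "all"
  long <- norm2 |>
    dplyr::select("gene_id", "organism", dplyr::all_of(fpk_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(fpk_cols), names_to = "sample",
                        values_to = "fpk", names_prefix = "fpk_")
  means <- long |>
    dplyr::group_by(.data$organism, .data$sample) |>
    dplyr::summarise(mean_fpk = mean(.data$fpk), .groups = "drop")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$organism, .data$fpk)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.4, size = 0.8) +
    ggplot2::geom_errorbar(
      data = means,
      ggplot2::aes(y = NULL, ymin = .data$mean_fpk, ymax = .data$mean_fpk),
      width = 0.6, colour = "firebrick"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = NULL, y = "FPK (log10)") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    sub <- dplyr::filter(long, .data$gene_id %in% highlight)
    p <- p + ggplot2::geom_point(data = sub, colour = "steelblue", size = 2)
  }
  p
}

#' Plot probe evaluation mismatch profile
#'
#' Minimum mismatch count of the probe against every target and non-target
#' sequence; the dashed line at zero separates perfect hits from
#' discriminating mismatches.
#'
#' @param evaluation A `probe_evaluation` from [evaluate_probe()].
#' @return A ggplot object.
#' @export
plot_probe_evaluation <- function(evaluation) {
  stopifnot(inherits(evaluation, "probe_evaluation"))
  d <- evaluation$hits
  d$min_mismatches[is.infinite(d$min_mismatches)] <- NA_real_
  ggplot2::ggplot(d, ggplot2::aes(.data$set, .data$min_mismatches)) +
    ggplot2::geom_jitter(width = 0.2, height = 0.05, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = NULL, y = "minimum mismatches to probe site",
                  title = sprintf("5'-%s-3'", evaluation$probe)) +
    ggplot2::theme_minimal()
}
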