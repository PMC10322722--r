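# Expression tables are wide tibbles: gene_id, organism (optional),
# length_bp, is_rrna (0/1), then one integer count column per sample.
# fpk()/clr() append fpk_<sample> / clr_<sample> columns in place.

meta_cols <- c("gene_id", "organism", "length_bp", "is_rrna")

detect_samples <- function(table) {
  cand <- setdiff(names(table), meta_cols)
  cand <- cand[!grepl("^(fpk|clr)_", cand)]
  cand <- cand[vapply(table[cand], is.numeric, logical(1))]
  if (length(cand) == 0) {
    abort("no sample count columns found (numeric columns besides gene metadata).")
  }
  cand
}

assert_expression_table <- function(table) {
  if (!is.data.frame(table) || !all(c("gene_id", "length_bp") %in% names(table))) {
    abort("expression table needs `gene_id` and `length_bp` columns.")
  }
  if (anyDuplicated(table$gene_id)) abort("`gene_id` values must be unique.")
  if (any(table$length_bp <= 0)) abort("gene lengths must be positive (bp).")
  samples <- detect_samples(table)
  for (s in samples) {
    if (any(table[[s]] < 0)) abort(sprintf("negative counts in sample `%s`.", s))
  }
  invisible(samples)
}

#' Remove rRNA genes from an expression table
#'
#' rRNA fragments dominate total RNA libraries and are excluded before any
#' normalization. Rows whose `is_rrna` flag is 1 (or `TRUE`) are dropped;
#' surviving rows are returned unchanged.
#'
#' @param table Expression table: a data frame with columns `gene_id`,
#'   `length_bp`, `is_rrna`, optional `organism`, and one numeric count
#'   column per sample.
#' @return The table without rRNA rows.
#' @export
filter_rrna <- function(table) {
  assert_expression_table(table)
  if (!"is_rrna" %in% names(table)) {
    return(as_tibble(table))
  }
  out <- dplyr::filter(as_tibble(table), !(.data$is_rrna %in% c(1, TRUE)))
  if (nrow(out) == 0) abort("no genes remain after rRNA exclusion.")
  out
}

#' Fragments per kilobase (FPK)
#'
#' Length normalization of fragment counts:
#' \deqn{FPK_i = C_i / L_i} with the gene length \eqn{L_i} in kilobases.
#' Unlike FPKM no sequencing-depth scaling is applied. A warning is issued
#' if rRNA-flagged rows are still present (use [filter_rrna()] first).
#'
#' @inheritParams filter_rrna
#' @param samples Character vector of count column names; autodetected by
#'   default.
#' @return The table with an added `fpk_<sample>` column per sample.
#' @examples
#' tb <- tibble::tibble(gene_id = c("g1", "g2"), length_bp = c(2000, 350),
#'                      s1 = c(100, 7))
#' fpk(tb)  # 50 and 20
#' @export
fpk <- function(table, samples = NULL) {
  detected <- assert_expression_table(table)
  samples <- samples %||% detected
  if ("is_rrna" %in% names(table) && any(table$is_rrna %in% c(1, TRUE))) {
    warn("table still contains rRNA-flagged genes; FPK is normally computed after rRNA exclusion.")
  }
  out <- as_tibble(table)
  for (s in samples) {
    out[[paste0("fpk_", s)]] <- out[[s]] / (out$length_bp / 1000)
  }
  out
}

#' Centred log-ratio (CLR) normalization
#'
#' Compositional normalization of length-corrected counts. With
#' \eqn{x_i = (C_i + 0.5) / L_i} (length in kilobases; the 0.5 pseudocount
#' keeps zero counts defined),
#' \deqn{CLR_i = \log_{10}\!\left(x_i \middle/
#'       \sqrt[G]{x_1 x_2 \cdots x_G}\right),}
#' the base-10 log of each gene's value over the geometric mean of all `G`
#' genes. CLR values within one composition sum to zero and are invariant
#' to any common scaling of the \eqn{x_i}.
#'
#' When the table has an `organism` column the composition is each
#' organism's gene set within each sample (per-genome normalization);
#' otherwise the whole table forms one composition per sample.
#'
#' @inheritParams fpk
#' @return The table with an added `clr_<sample>` column per sample.
#' @export
clr <- function(table, samples = NULL) {
  detected <- assert_expression_table(table)
  samples <- samples %||% detected
  out <- as_tibble(table)
  grp <- if ("organism" %in% names(out)) out$organism else rep("all", nrow(out))
  for (s in samples) {
    x <- (out[[s]] + 0.5) / (out$length_bp / 1000)
    clr_vals <- rep(NA_real_, length(x))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(idx) < 2) {
        abort("CLR needs at least 2 genes per composition (geometric mean degenerate).")
      }
      lg <- log10(x[idx])
      clr_vals[idx] <- lg - mean(lg)  # log of geometric mean = mean of logs
    }
    out[[paste0("clr_", s)]] <- clr_vals
  }
  out
}

#' Full expression normalization pipeline
#'
#' Convenience wrapper: rRNA exclusion, then FPK and CLR columns.
#'
#' @inheritParams fpk
#' @return The rRNA-filtered table with `fpk_*` and `clr_*` columns.
#' @export
normalize_expression <- function(table, samples = NULL) {
  table |>
    filter_rrna() |>
    fpk(samples = samples) |>
    clr(samples = samples)
}

#' Mean expression per organism and sample
#'
#' The per-organism average expression line: the sum of all FPK values
#' divided by the number of genes (arithmetic mean FPK).
#'
#' @param norm An expression table with `fpk_<sample>` columns (see [fpk()]).
#' @return A tibble with columns `organism`, `sample`, `mean_fpk`,
#'   `n_genes`.
#' @export
mean_expression <- function(norm) {
  fpk_cols <- grep("^fpk_", names(norm), value = TRUE)
  if (length(fpk_cols) == 0) abort("no `fpk_*` columns: run fpk() first.")
  if (nrow(norm) == 0) abort("empty gene set: mean expression undefined.")
  norm2 <- as_tibble(norm)
  if (!"organism" %in% names(norm2)) norm2$organism <- "all"
  norm2 |>
    dplyr::select("organism", dplyr::all_of(fpk_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(fpk_cols),
                        names_to = "sample", values_to = "fpk",
                        names_prefix = "fpk_") |>
    dplyr::group_by(.data$organism, .data$sample) |>
    dplyr::summarise(mean_fpk = mean(.data$fpk), n_genes = dplyr::n(),
                     .groups = "drop")
}

#' Rank genes by expression
#'
#' Descending competition ranking by FPK within each organism and sample:
#' the highest-FPK gene has rank 1; ties share the smaller rank and the
#' following rank is skipped accordingly (ranks 1, 1, 3 for a two-way tie at
#' the top). Used for "top-N expressed genes" statements.
#'
#' @inheritParams mean_expression
#' @param gene_id Optional gene identifier(s); if supplied, only those
#'   genes' rows are returned (unknown ids are an error).
#' @return A tibble with columns `gene_id`, `organism`, `sample`, `fpk`,
#'   `rank`.
#' @export
rank_genes <- function(norm, gene_id = NULL) {
  fpk_cols <- grep("^fpk_", names(norm), value = TRUE)
  if (length(fpk_cols) == 0) abort("no `fpk_*` columns: run fpk() first.")
  norm2 <- as_tibble(norm)
  if (!"organism" %in% names(norm2)) norm2$organism <- "all"
  ranks <- norm2 |>
    dplyr::select("gene_id", "organism", dplyr::all_of(fpk_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(fpk_cols),
                        names_to = "sample", values_to = "fpk",
                        names_prefix = "fpk_") |>
    dplyr::group_by(.data$organism, .data$sample) |>
    dplyr::mutate(rank = rank(-.data$fpk, ties.method = "min")) |>
    dplyr::ungroup()
  if (!is.null(gene_id)) {
    unknown <- setdiff(gene_id, ranks$gene_id)
    if (length(unknown) > 0) {
      abort(paste0("unknown gene id(s): ", paste(unknown, collapse = ", ")))
    }
    ranks <- dplyr::filter(ranks, .data$gene_id %in% !!gene_id)
  }
  ranks
}
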