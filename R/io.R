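# Readers and writers for the package's tabular and FASTA dialects.

#' Read and write culture time series
#'
#' Tab-separated files with header columns `time_d`, `replicate`,
#' `sulfide_mM` and optionally `dic_mM`, `sulfate_mM`, `dilution` (0/1).
#'
#' @param file Path to a TSV file.
#' @return `read_culture_series()`: a validated tibble.
#' @export
read_culture_series <- function(file) {
  series <- readr::read_tsv(file, show_col_types = FALSE)
  assert_culture_series(series)
  as_tibble(series)
}

#' @rdname read_culture_series
#' @param series Culture time series tibble.
#' @export
write_culture_series <- function(series, file) {
  assert_culture_series(series)
  readr::write_tsv(series, file)
  invisible(file)
}

#' Read and write gene expression tables
#'
#' Tab-separated files with columns `gene_id`, optional `organism`,
#' `length_bp`, `is_rrna` (0/1) and one numeric count column per sample.
#' Normalized tables carry additional `fpk_<sample>` / `clr_<sample>`
#' columns.
#'
#' @param file Path to a TSV file.
#' @return `read_expression_table()`: a validated tibble.
#' @export
read_expression_table <- function(file) {
  table <- readr::read_tsv(file, show_col_types = FALSE)
  assert_expression_table(table)
  as_tibble(table)
}

#' @rdname read_expression_table
#' @param table Expression table tibble.
#' @export
write_expression_table <- function(table, file) {
  readr::write_tsv(table, file)
  invisible(file)
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers around Biostrings that exchange named character vectors,
#' the representation the scanning functions use.
#'
#' @param file Path to a FASTA file.
#' @param type `"AA"` for protein, `"DNA"` for nucleotide sequences.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(file, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") {
    Biostrings::readAAStringSet(file)
  } else {
    Biostrings::readDNAStringSet(file)
  }
  setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, file, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") {
    Biostrings::AAStringSet(seqs)
  } else {
    Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}
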