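AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

as_named_seqs <- function(x, what = "sequence") {
  if (methods::is(x, "XStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (!is.character(x)) {
    abort(sprintf("`%s` must be a character vector or Biostrings XStringSet.", what))
  }
  if (length(x) > 0 && is.null(names(x))) {
    names(x) <- paste0("seq", seq_along(x))
  }
  x
}

#' Scan protein sequences for CxxCH haem-binding motifs
#'
#' The five-residue motif Cys-X-X-Cys-His covalently binds haem in c-type
#' cytochromes; proteins with several such motifs are multihaem cytochromes
#' (MHCs), candidate conduits for direct interspecies electron transfer.
#' All windows are reported, including overlapping ones, with 1-based start
#' positions.
#'
#' @param proteins Amino-acid sequences: a character vector (optionally
#'   named), or a `Biostrings::AAStringSet`. Case-insensitive; the 20
#'   standard residues plus `X` and `*` are accepted, anything else is an
#'   error naming the offending symbol.
#' @return A tibble with one row per protein: `protein_id`, `motif_count`,
#'   and `positions`, a list-column of integer start positions.
#' @examples
#' scan_cxxch(c(p1 = "MKCAACHAA", p2 = "ACDEFGH"))
#' @export
scan_cxxch <- function(proteins) {
  proteins <- as_named_seqs(proteins, "proteins")
  purrr::imap(proteins, function(seq, id) {
    s <- toupper(seq)
    chars <- strsplit(s, "")[[1]]
    bad <- setdiff(unique(chars), AA_ALPHABET)
    if (length(bad) > 0) {
      abort(sprintf("illegal character(s) in protein `%s`: %s",
                    id, paste(bad, collapse = ", ")))
    }
    # lookahead regex so overlapping motifs are all found; the wildcard
    # positions may be any residue (including X) but not a stop
    hits <- gregexpr("(?=C[^*][^*]CH)", s, perl = TRUE)[[1]]
    pos <- if (hits[1] == -1) integer(0) else as.integer(hits)
    tibble(protein_id = id, motif_count = length(pos), positions = list(pos))
  }) |>
    dplyr::bind_rows()
}

#' Classify proteins as multihaem cytochromes
#'
#' A protein counts as a multihaem c-type cytochrome (MHC) when its CxxCH
#' motif count reaches `min_motifs` (default 2; configurable because the
#' field uses no single canonical cutoff).
#'
#' @param scan Output of [scan_cxxch()].
#' @param min_motifs Minimum motif count (>= 1) to call a protein multihaem.
#' @return The scan tibble with an added logical `multihaem` column.
#' @export
classify_multihaem <- function(scan, min_motifs = 2) {
  if (!is.numeric(min_motifs) || length(min_motifs) != 1 || min_motifs < 1) {
    abort("`min_motifs` must be a single integer >= 1.")
  }
  if (!is.data.frame(scan) || is.null(scan$motif_count)) {
    abort("`scan` must be the output of scan_cxxch().")
  }
  dplyr::mutate(as_tibble(scan), multihaem = .data$motif_count >= min_motifs)
}

#' GC content of an oligonucleotide
#'
#' Percentage of G and C bases. Probe sequences must be plain `ACGT`
#' (IUPAC ambiguity codes are rejected: the screening criteria are defined
#' for fully specified oligonucleotides).
#'
#' @param probe DNA sequence(s), 5'->3', as a character vector.
#' @return Numeric vector of GC percentages in `[0, 100]`.
#' @examples
#' gc_content("GCATTCCAGCACTCCATGG")  # 57.9% for the Aph183 probe
#' @export
gc_content <- function(probe) {
  if (!is.character(probe) || length(probe) < 1 || any(!nzchar(probe))) {
    abort("`probe` must be one or more non-empty DNA strings.")
  }
  vapply(toupper(probe), function(s) {
    chars <- strsplit(s, "")[[1]]
    bad <- setdiff(unique(chars), c("A", "C", "G", "T"))
    if (length(bad) > 0) {
      abort(sprintf("probe contains non-ACGT character(s): %s", paste(bad, collapse = ", ")))
    }
    100 * sum(chars %in% c("G", "C")) / length(chars)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count mismatches between a probe and an equal-length site
#'
#' Positional (Hamming) comparison of two aligned equal-length sequences.
#' Ambiguity codes in the site count as mismatches unless the characters are
#' exactly equal.
#'
#' @param probe DNA string.
#' @param site DNA string of the same length.
#' @return A list with `n_mismatches` (integer) and `positions` (1-based
#'   from the probe's 5' end).
#' @examples
#' count_mismatches("ACGT", "ACTT")
#' @export
count_mismatches <- function(probe, site) {
  if (!is.character(probe) || !is.character(site) ||
      length(probe) != 1 || length(site) != 1) {
    abort("`probe` and `site` must be single strings.")
  }
  if (nchar(probe) != nchar(site)) {
    abort("`probe` and `site` must have equal length.")
  }
  a <- strsplit(toupper(probe), "")[[1]]
  b <- strsplit(toupper(site), "")[[1]]
  pos <- which(a != b)
  list(n_mismatches = length(pos), positions = as.integer(pos))
}

# Minimum Hamming distance of `pattern` over all windows of `subject`.
# Returns Inf when the subject is shorter than the pattern.
best_window_mismatches <- function(pattern, subject) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  k <- length(p)
  n <- length(s)
  if (n < k) return(Inf)
  best <- k
  for (i in seq_len(n - k + 1)) {
    d <- sum(p != s[i:(i + k - 1)])
    if (d < best) {
      best <- d
      if (best == 0) break
    }
  }
  best
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Evaluate an rRNA-targeted oligonucleotide probe
#'
#' Screens a FISH probe candidate against target (in-group) and non-target
#' (out-group) sequence sets using the standard probe-design criteria:
#' every target must contain a perfect (0-mismatch) probe site
#' (`min_group_fraction = 1`, "min. group hits, 100%"), at most
#' `max_nongroup_hits` non-targets may contain a perfect site
#' ("max. non-group hits, 5"), every non-target must show at least one
#' mismatch, GC content must stay below `max_gc` (60%), and the probe must
#' have `required_length` nucleotides (19) unless `required_length = NULL`.
#'
#' Probes hybridize to rRNA, so by default each subject sequence's sense
#' strand is scanned with the reverse complement of the probe; the best
#' (minimum-mismatch) window per sequence is scored. Set
#' `strand = "forward"` to compare the probe itself. Subjects shorter than
#' the probe are scored as no-hit with a warning.
#'
#' @inheritParams gc_content
#' @param targets,nontargets Nucleotide sequence sets (character vector or
#'   `Biostrings::DNAStringSet`). `targets` must be non-empty.
#' @param max_nongroup_hits Maximum allowed number of non-target sequences
#'   with a perfect probe site (default 5).
#' @param min_group_fraction Minimum fraction of targets with a perfect site
#'   (default 1).
#' @param max_gc Upper GC bound in percent, exclusive (default 60).
#' @param required_length Required probe length in nt (default 19); `NULL`
#'   to skip the length check.
#' @param strand `"reverse"` (default; probe reverse complement vs sense
#'   strand) or `"forward"`.
#' @return An object of class `probe_evaluation`: a list with the probe,
#'   per-criterion results, and per-sequence minimum mismatch counts.
#'   [tidy()] returns one row per criterion; [glance()] a one-row summary
#'   with the overall `pass` flag.
#' @export
evaluate_probe <- function(probe, targets, nontargets = character(0),
                           max_nongroup_hits = 5, min_group_fraction = 1,
                           max_gc = 60, required_length = 19,
                           strand = c("reverse", "forward")) {
  strand <- match.arg(strand)
  gc <- gc_content(probe)
  targets <- as_named_seqs(targets, "targets")
  if (length(targets) == 0) abort("`targets` must contain at least one sequence.")
  nontargets <- if (length(nontargets) > 0) as_named_seqs(nontargets, "nontargets") else character(0)

  pattern <- if (strand == "reverse") reverse_complement(probe) else toupper(probe)
  score_set <- function(seqs, set) {
    if (length(seqs) == 0) {
      return(tibble(seq_id = character(0), set = character(0), min_mismatches = double(0)))
    }
    mm <- purrr::imap_dbl(seqs, function(s, id) {
      d <- best_window_mismatches(pattern, s)
      if (is.infinite(d)) {
        warn(sprintf("sequence `%s` is shorter than the probe: scored as no-hit.", id))
      }
      d
    })
    tibble(seq_id = names(seqs), set = set, min_mismatches = unname(mm))
  }
  hits <- dplyr::bind_rows(
    score_set(targets, "target"),
    score_set(nontargets, "nontarget")
  )

  tgt <- dplyr::filter(hits, .data$set == "target")
  ntg <- dplyr::filter(hits, .data$set == "nontarget")
  group_hit_fraction <- mean(tgt$min_mismatches == 0)
  nongroup_zero <- sum(ntg$min_mismatches == 0)
  min_nongroup_mm <- if (nrow(ntg) > 0) min(ntg$min_mismatches) else NA_real_

  criteria <- tibble(
    criterion = c("group_hits", "nongroup_hits", "nongroup_mismatch", "gc_content", "length"),
    value = c(group_hit_fraction, nongroup_zero,
              if (nrow(ntg) > 0) min_nongroup_mm else Inf,
              gc, nchar(probe)),
    threshold = c(min_group_fraction, max_nongroup_hits, 1, max_gc,
                  if (is.null(required_length)) NA_real_ else required_length),
    pass = c(
      group_hit_fraction >= min_group_fraction,
      nongroup_zero <= max_nongroup_hits,
      nrow(ntg) == 0 || min_nongroup_mm >= 1,
      gc < max_gc,
      is.null(required_length) || nchar(probe) == required_length
    )
  )

  structure(
    list(
      probe = toupper(probe),
      length = nchar(probe),
      gc_percent = gc,
      strand = strand,
      group_hit_fraction = group_hit_fraction,
      nongroup_zero_mismatch_hits = nongroup_zero,
      min_nongroup_mismatches = min_nongroup_mm,
      criteria = criteria,
      pass = all(criteria$pass),
      hits = hits
    ),
    class = "probe_evaluation"
  )
}

#' @export
print.probe_evaluation <- function(x, ...) {
  cat(sprintf("Probe evaluation: 5'-%s-3' (%d nt, GC %.1f%%) — %s\n",
              x$probe, x$length, x$gc_percent, if (x$pass) "PASS" else "FAIL"))
  print(x$criteria)
  invisible(x)
}

#' @describeIn evaluate_probe Per-criterion tibble (`criterion`, `value`,
#'   `threshold`, `pass`).
#' @param x A `probe_evaluation` object.
#' @param ... Unused.
#' @method tidy probe_evaluation
#' @export
tidy.probe_evaluation <- function(x, ...) {
  x$criteria
}

#' @describeIn evaluate_probe One-row summary tibble.
#' @method glance probe_evaluation
#' @export
glance.probe_evaluation <- function(x, ...) {
  tibble(
    probe = x$probe,
    length = x$length,
    gc_percent = x$gc_percent,
    group_hit_fraction = x$group_hit_fraction,
    nongroup_zero_mismatch_hits = x$nongroup_zero_mismatch_hits,
    min_nongroup_mismatches = x$min_nongroup_mismatches,
    pass = x$pass
  )
}
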