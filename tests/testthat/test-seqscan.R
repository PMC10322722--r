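test_that("CxxCH scanning reports all overlapping motif windows 1-based", {
  one <- scan_cxxch(c(p = "MKCAACHAA"))
  expect_identical(one$motif_count, 1L)
  expect_identical(one$positions[[1]], 3L)

  overlap <- scan_cxxch("CCACCH")
  expect_identical(overlap$positions[[1]], 2L)

  none <- scan_cxxch("ACDEFGH")
  expect_identical(none$motif_count, 0L)

  expect_identical(scan_cxxch("mkcaachaa")$positions[[1]], 3L)
  expect_identical(scan_cxxch("")$motif_count, 0L)
  expect_error(scan_cxxch(c(bad = "MKCB1CH")), "illegal character.*B")

  # stops cannot stand in the wildcard positions
  expect_identical(scan_cxxch("C**CH")$motif_count, 0L)
  expect_identical(scan_cxxch("CXXCH")$motif_count, 1L)
})

test_that("motif scan agrees with the exhaustive window oracle", {
  withr::with_seed(11, {
    for (i in 1:200) {
      seq <- random_protein(sample(5:120, 1))
      got <- scan_cxxch(seq)$positions[[1]]
      expect_identical(got, as.integer(oracle_cxxch(seq)))
    }
  })
})

test_that("multihaem classification applies the motif-count threshold", {
  scan <- tibble::tibble(
    protein_id = c("a", "b", "c"),
    motif_count = c(0L, 2L, 1L),
    positions = list(integer(0), c(1L, 10L), 5L)
  )
  expect_identical(classify_multihaem(scan)$multihaem, c(FALSE, TRUE, FALSE))
  expect_identical(classify_multihaem(scan, min_motifs = 1)$multihaem,
                   c(FALSE, TRUE, TRUE))
  expect_error(classify_multihaem(scan, min_motifs = 0), "integer >= 1")
})

test_that("GC content counts G and C bases as a percentage", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCATTCCAGCACTCCATGG"), 100 * 11 / 19)
  expect_error(gc_content(""), "non-empty")
  expect_error(gc_content("ACGN"), "non-ACGT")

  # invariant under reverse complementation
  withr::with_seed(3, {
    for (i in 1:20) {
      s <- random_dna_str(30)
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      expect_equal(gc_content(s), gc_content(rc))
    }
  })
})

test_that("mismatch counting is positional Hamming distance", {
  expect_identical(count_mismatches("ACGT", "ACGT")$n_mismatches, 0L)
  one <- count_mismatches("ACGT", "ACTT")
  expect_identical(one$n_mismatches, 1L)
  expect_identical(one$positions, 3L)
  expect_error(count_mismatches("ACGT", "ACG"), "equal length")

  withr::with_seed(5, {
    for (i in 1:50) {
      a <- random_dna_str(20)
      b <- random_dna_str(20)
      brute <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      expect_identical(count_mismatches(a, b)$n_mismatches, as.integer(brute))
    }
  })
})

make_probe_sets <- function(probe, n_targets = 3, n_nontargets = 4,
                            exact_nontargets = 0, len = 120, seed = 9) {
  withr::with_seed(seed, {
    site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(probe)))
    plant <- function(seq, s) {
      pos <- sample.int(nchar(seq) - nchar(s) + 1, 1)
      paste0(substr(seq, 1, pos - 1), s, substr(seq, pos + nchar(s), nchar(seq)))
    }
    targets <- vapply(seq_len(n_targets), function(i) plant(random_dna_str(len), site),
                      character(1))
    nontargets <- vapply(seq_len(n_nontargets), function(i) {
      s <- site
      if (i > exact_nontargets) {
        p <- sample.int(nchar(s), 1)
        old <- substr(s, p, p)
        substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
      }
      plant(random_dna_str(len), s)
    }, character(1))
    list(targets = targets, nontargets = nontargets)
  })
}

test_that("probe evaluation applies each screening criterion independently", {
  probe <- "GCATTCCAGCACTCCATGG"
  sets <- make_probe_sets(probe)
  ev <- evaluate_probe(probe, sets$targets, sets$nontargets)
  expect_true(ev$pass)
  expect_equal(ev$group_hit_fraction, 1)
  expect_identical(ev$nongroup_zero_mismatch_hits, 0L)
  expect_gte(ev$min_nongroup_mismatches, 1)

  # six non-targets carrying exact sites break the non-group limit of 5
  sets6 <- make_probe_sets(probe, n_nontargets = 7, exact_nontargets = 6)
  ev6 <- evaluate_probe(probe, sets6$targets, sets6$nontargets)
  expect_false(ev6$pass)
  crit <- tidy(ev6)
  expect_false(crit$pass[crit$criterion == "nongroup_hits"])

  # a GC-rich probe fails on GC alone, however good its hits
  rich <- "GCGCGCGCGCGCGCGCGCG"   # 100% GC, 19 nt
  sets_rich <- make_probe_sets(rich)
  ev_rich <- evaluate_probe(rich, sets_rich$targets, sets_rich$nontargets)
  expect_false(ev_rich$pass)
  crit_rich <- tidy(ev_rich)
  expect_false(crit_rich$pass[crit_rich$criterion == "gc_content"])
  expect_true(crit_rich$pass[crit_rich$criterion == "group_hits"])

  # wrong length fails the length criterion
  ev_short <- evaluate_probe("GCATTCCAGCACTCC", make_probe_sets("GCATTCCAGCACTCC")$targets)
  expect_false(tidy(ev_short)$pass[tidy(ev_short)$criterion == "length"])

  expect_error(evaluate_probe(probe, character(0)), "at least one sequence")
  expect_warning(
    evaluate_probe(probe, c(long = sets$targets[1], short = "ACGT")),
    "shorter than the probe"
  )
})

test_that("probe evaluation is monotone under growing sequence sets", {
  probe <- "GCATTCCAGCACTCCATGG"
  sets <- make_probe_sets(probe, n_targets = 4, n_nontargets = 3)
  base <- evaluate_probe(probe, sets$targets, sets$nontargets)

  # adding a non-target can only keep or worsen the non-group criteria
  site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(probe)))
  extra_bad <- paste0(random_dna_str(40), site, random_dna_str(40))
  more <- evaluate_probe(probe, sets$targets, c(sets$nontargets, extra_bad))
  expect_gte(more$nongroup_zero_mismatch_hits, base$nongroup_zero_mismatch_hits)
  expect_lte(more$min_nongroup_mismatches, base$min_nongroup_mismatches)

  # adding a target without the site can only lower the group hit fraction
  more_t <- evaluate_probe(probe, c(sets$targets, random_dna_str(120)), sets$nontargets)
  expect_lte(more_t$group_hit_fraction, base$group_hit_fraction)
})

test_that("forward-strand matching finds the probe itself, not its complement", {
  probe <- "AAAAAAAAAACCCCCCCCC"
  subject <- paste0("TTTT", probe, "TTTT")
  fwd <- evaluate_probe(probe, subject, strand = "forward")
  expect_equal(fwd$group_hit_fraction, 1)
  rev <- evaluate_probe(probe, subject, strand = "reverse")
  expect_lt(rev$group_hit_fraction, 1)
})
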