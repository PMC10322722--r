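#' Configuration for the synthetic-data generators
#'
#' Collects every knob of the seeded generators in one validated list. The
#' defaults describe a hexane-oxidizing sulfate-reducing culture at 70 degC:
#' carbon number 6, ~10.7% of alkane carbon assimilated into
#' carbohydrate-like biomass (z = 0), activity doubling time 20 days (within
#' the reported 13-40 d range), triplicate incubations sampled weekly,
#' sulfide starting near 0.5 mM and plateauing at 15 mM (the upper dilution
#' trigger), 1:3 dilutions with fresh medium, seawater-like 28 mM sulfate
#' and 10 mM initial DIC, and 5% relative (lognormal multiplicative)
#' measurement noise.
#'
#' @param seed Integer seed; every generator is a pure function of it.
#' @param n Carbon-chain length of the alkane substrate.
#' @param f True assimilated-carbon fraction in `[0, 1)`.
#' @param z Biomass mean carbon oxidation state.
#' @param doubling_time True activity doubling time (days).
#' @param noise Relative measurement noise (sd of the lognormal
#'   multiplicative error); `0` for noise-free data.
#' @param replicates Number of culture replicates.
#' @param times Sampling grid (days).
#' @param dilution_times Times (days) of 1:3 dilution events; must lie on
#'   `times`.
#' @param sulfide0 Initial sulfide (mM).
#' @param plateau Sulfide plateau (mM) at which activity stalls.
#' @param sulfate0,dic0 Fresh-medium sulfate and DIC (mM).
#' @param n_genes,n_rrna Gene count and number of rRNA genes for
#'   [simulate_counts()].
#' @param count_samples Sample names for the count table.
#' @param probe Probe sequence (5'->3') used by [simulate_sequences()].
#' @param n_targets,n_nontargets Sizes of the target / non-target 16S-like
#'   sequence sets.
#' @param seq_length Length (nt) of the generated nucleotide sequences.
#' @param nontarget_mismatches Substitutions planted into each non-target's
#'   probe site (>= 1).
#' @param n_nontarget_exact Number of non-targets that instead carry an
#'   exact (0-mismatch) probe site, to exercise the non-group criterion.
#' @param n_proteins Number of synthetic proteins.
#' @param protein_length Protein length (residues).
#' @param max_motifs Maximum number of CxxCH motifs planted per protein
#'   (each protein receives 0..`max_motifs`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n = 6,
                       f = 0.107,
                       z = 0,
                       doubling_time = 20,
                       noise = 0.05,
                       replicates = 3,
                       times = seq(0, 112, by = 7),
                       dilution_times = numeric(0),
                       sulfide0 = 0.5,
                       plateau = 15,
                       sulfate0 = 28,
                       dic0 = 10,
                       n_genes = 2000,
                       n_rrna = 5,
                       count_samples = c("s1", "s2"),
                       probe = "GCATTCCAGCACTCCATGG",
                       n_targets = 5,
                       n_nontargets = 8,
                       seq_length = 300,
                       nontarget_mismatches = 1,
                       n_nontarget_exact = 0,
                       n_proteins = 30,
                       protein_length = 120,
                       max_motifs = 5) {
  assert_carbon_number(n)
  assert_fraction(f)
  if (noise < 0) abort("`noise` must be >= 0.")
  if (doubling_time <= 0) abort("`doubling_time` must be positive (days).")
  if (length(dilution_times) > 0 && !all(dilution_times %in% times)) {
    abort("`dilution_times` must lie on the sampling grid `times`.")
  }
  structure(
    list(
      seed = as.integer(seed), n = n, f = f, z = z,
      doubling_time = doubling_time, noise = noise,
      replicates = replicates, times = times,
      dilution_times = dilution_times,
      sulfide0 = sulfide0, plateau = plateau,
      sulfate0 = sulfate0, dic0 = dic0,
      n_genes = n_genes, n_rrna = n_rrna, count_samples = count_samples,
      probe = toupper(probe), n_targets = n_targets,
      n_nontargets = n_nontargets, seq_length = seq_length,
      nontarget_mismatches = nontarget_mismatches,
      n_nontarget_exact = n_nontarget_exact,
      n_proteins = n_proteins, protein_length = protein_length,
      max_motifs = max_motifs
    ),
    class = "sim_config"
  )
}

noisy <- function(x, noise) {
  if (noise == 0) return(x)
  x * exp(rnorm(length(x), mean = 0, sd = noise))
}

#' Simulate culture concentration trajectories
#'
#' Generates replicate sulfide, DIC and sulfate time series with the
#' structure the stoichiometric and kinetic analyses assume: sulfide grows
#' exponentially at rate \eqn{m = \ln(2)/T_d} from `sulfide0`, hard-capped
#' at `plateau`; each mole of sulfide produced consumes one mole of sulfate
#' and releases `predicted_ratio(n, f, z)` moles of DIC; at each dilution
#' time the culture is mixed 1:3 with fresh medium (sulfide divided by 3,
#' sulfate and DIC relaxed two-thirds of the way to the medium composition)
#' and the recorded value at that time is post-dilution. Lognormal
#' multiplicative noise at level `noise` is applied per measurement; the
#' matched abiotic control is flat at the initial composition (zero sulfide)
#' with the same noise.
#'
#' @param config A [sim_config()].
#' @return A list with `series` and `control` tibbles (columns `time_d`,
#'   `replicate`, `sulfide_mM`, `dic_mM`, `sulfate_mM`, `dilution`) and
#'   `truth`, a one-row tibble of the generating parameters (including the
#'   expected DIC:sulfate ratio).
#' @export
simulate_culture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ratio <- predicted_ratio(config$n, config$f, config$z)
  m <- log(2) / config$doubling_time

  one_replicate <- function(rep_name, with_noise) {
    t_seg <- 0
    sulfide_seg <- config$sulfide0
    sulfate_seg <- config$sulfate0
    dic_seg <- config$dic0
    rows <- vector("list", length(config$times))
    for (i in seq_along(config$times)) {
      t <- config$times[i]
      diluted <- t %in% config$dilution_times && t > 0
      if (diluted) {
        # state just before dilution
        s_pre <- min(config$plateau, sulfide_seg * exp(m * (t - t_seg)))
        produced <- s_pre - sulfide_seg
        sulfate_pre <- sulfate_seg - produced
        dic_pre <- dic_seg + ratio * produced
        # 1 part culture + 2 parts fresh medium
        sulfide_seg <- s_pre / 3
        sulfate_seg <- sulfate_pre / 3 + 2 / 3 * config$sulfate0
        dic_seg <- dic_pre / 3 + 2 / 3 * config$dic0
        t_seg <- t
      }
      s <- min(config$plateau, sulfide_seg * exp(m * (t - t_seg)))
      produced <- s - sulfide_seg
      rows[[i]] <- tibble(
        time_d = t,
        replicate = rep_name,
        sulfide_mM = s,
        dic_mM = dic_seg + ratio * produced,
        sulfate_mM = sulfate_seg - produced,
        dilution = as.integer(diluted)
      )
    }
    out <- dplyr::bind_rows(rows)
    if (with_noise && config$noise > 0) {
      out$sulfide_mM <- noisy(out$sulfide_mM, config$noise)
      out$dic_mM <- noisy(out$dic_mM, config$noise)
      out$sulfate_mM <- noisy(out$sulfate_mM, config$noise)
    }
    out
  }

  withr::with_seed(config$seed, {
    series <- dplyr::bind_rows(lapply(
      paste0("r", seq_len(config$replicates)),
      one_replicate, with_noise = TRUE
    ))
    control <- tibble(
      time_d = config$times,
      replicate = "control",
      sulfide_mM = 0,
      dic_mM = noisy(rep(config$dic0, length(config$times)), config$noise),
      sulfate_mM = noisy(rep(config$sulfate0, length(config$times)), config$noise),
      dilution = 0L
    )
    list(
      series = series,
      control = control,
      truth = tibble(
        n = config$n, f = config$f, z = config$z,
        doubling_time = config$doubling_time,
        ratio_dic_sulfate = ratio
      )
    )
  })
}

#' Simulate a per-gene fragment-count table
#'
#' Generates a metatranscriptome-like count table: gene lengths uniform on
#' 300-6000 bp, lognormal fragment counts, one designated top gene
#' (`gene_top`) whose FPK is guaranteed to exceed every other gene's, and
#' `n_rrna` rRNA genes flagged `is_rrna = 1` whose counts are 100 times the
#' median (rRNA contamination that must be excluded before normalization).
#'
#' @inheritParams simulate_culture
#' @return A list with `table` (columns `gene_id`, `organism`, `length_bp`,
#'   `is_rrna`, one count column per sample) and `truth` (the planted top
#'   gene id per sample).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 2) abort("`n_genes` must be >= 2.")
  withr::with_seed(config$seed + 1L, {
    g <- config$n_genes
    ids <- sprintf("gene_%04d", seq_len(g))
    lengths <- round(runif(g, 300, 6000))
    is_rrna <- as.integer(seq_len(g) %in% sample(2:g, min(config$n_rrna, g - 1)))
    tab <- tibble(
      gene_id = ids, organism = "MAG1",
      length_bp = lengths, is_rrna = is_rrna
    )
    for (s in config$count_samples) {
      counts <- round(rlnorm(g, meanlog = log(50), sdlog = 1))
      counts[is_rrna == 1] <- round(100 * median(counts))
      # plant the top gene: FPK strictly above every non-rRNA competitor
      mrna <- which(is_rrna == 0 & seq_len(g) != 1)
      max_fpk <- max(counts[mrna] / lengths[mrna])
      counts[1] <- ceiling(2 * max_fpk * lengths[1]) + 1
      tab[[s]] <- counts
    }
    list(
      table = tab,
      truth = tibble(sample = config$count_samples, top_gene = ids[1])
    )
  })
}

random_dna <- function(n_seq, len) {
  vapply(seq_len(n_seq), function(i) {
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

plant_site <- function(seq, site) {
  pos <- sample.int(nchar(seq) - nchar(site) + 1, 1)
  paste0(substr(seq, 1, pos - 1), site, substr(seq, pos + nchar(site), nchar(seq)))
}

mutate_site <- function(site, k) {
  chars <- strsplit(site, "")[[1]]
  pos <- sample.int(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste0(chars, collapse = "")
}

#' Simulate protein and 16S-like nucleotide sequence sets
#'
#' Proteins are drawn from a cysteine-free background alphabet with 0 to
#' `max_motifs` CxxCH motifs planted at non-overlapping recorded positions,
#' so the truth table is exactly the set of motif windows present. Target
#' nucleotide sequences each carry the exact reverse complement of the
#' configured probe; non-targets carry the site with
#' `nontarget_mismatches` planted substitutions (or, for the first
#' `n_nontarget_exact` of them, the exact site, to exercise the non-group
#' hit criterion).
#'
#' @inheritParams simulate_culture
#' @return A list with `proteins` (named character), `motif_truth`
#'   (tibble `protein_id`, `position`), `targets`, `nontargets` (named
#'   character vectors) and `probe`.
#' @export
simulate_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 2L, {
    # cysteine-free background: planted motifs are the only CxxCH occurrences
    bg <- strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]]
    proteins <- character(config$n_proteins)
    names(proteins) <- sprintf("prot_%03d", seq_len(config$n_proteins))
    truth <- list()
    for (i in seq_len(config$n_proteins)) {
      chars <- sample(bg, config$protein_length, replace = TRUE)
      k <- sample(0:config$max_motifs, 1)
      starts <- integer(0)
      if (k > 0) {
        # non-overlapping 5-residue slots, so planted motifs never merge
        slots <- seq(1, config$protein_length - 4, by = 5)
        starts <- sort(sample(slots, k))
        for (p in starts) {
          chars[p] <- "C"
          chars[p + 1] <- sample(bg, 1)
          chars[p + 2] <- sample(bg, 1)
          chars[p + 3] <- "C"
          chars[p + 4] <- "H"
        }
      }
      proteins[i] <- paste0(chars, collapse = "")
      if (length(starts) > 0) truth[[names(proteins)[i]]] <- starts
    }
    motif_truth <- if (length(truth) > 0) {
      dplyr::bind_rows(purrr::imap(truth, function(pos, id) {
        tibble(protein_id = id, position = as.integer(pos))
      }))
    } else {
      tibble(protein_id = character(0), position = integer(0))
    }

    site <- reverse_complement(config$probe)
    targets <- setNames(
      vapply(random_dna(config$n_targets, config$seq_length), plant_site,
             character(1), site = site, USE.NAMES = FALSE),
      sprintf("target_%02d", seq_len(config$n_targets))
    )
    nontargets <- character(config$n_nontargets)
    names(nontargets) <- sprintf("nontarget_%02d", seq_len(config$n_nontargets))
    for (i in seq_len(config$n_nontargets)) {
      this_site <- if (i <= config$n_nontarget_exact) {
        site
      } else {
        mutate_site(site, config$nontarget_mismatches)
      }
      nontargets[i] <- plant_site(random_dna(1, config$seq_length), this_site)
    }
    list(
      proteins = proteins,
      motif_truth = motif_truth,
      targets = targets,
      nontargets = nontargets,
      probe = config$probe
    )
  })
}
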