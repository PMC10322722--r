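# Independent brute-force oracles used to check the implementation paths.

# Solve predicted_ratio(n, f, z) = r for f by interval bisection; the forward
# model is strictly decreasing in f, so the bracket [0, 1) always works.
bisect_assimilation <- function(n, r, z = 0, iter = 200) {
  lo <- 0
  hi <- 1 - 1e-12
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (predicted_ratio(n, mid, z) > r) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Exhaustive window enumeration for the CxxCH motif (positions 1-based).
oracle_cxxch <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  if (L < 5) return(integer(0))
  hits <- integer(0)
  for (p in seq_len(L - 4)) {
    if (chars[p] == "C" && chars[p + 3] == "C" && chars[p + 4] == "H" &&
        chars[p + 1] != "*" && chars[p + 2] != "*") {
      hits <- c(hits, p)
    }
  }
  hits
}

# Random protein over the full accepted alphabet (no stop codons, so every
# window is eligible).
random_protein <- function(len, letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste0(sample(letters, len, replace = TRUE), collapse = "")
}

random_dna_str <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
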