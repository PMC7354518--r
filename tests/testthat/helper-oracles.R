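# Independent oracles used across the suite. These deliberately avoid the
# package's own DP/scan implementations: exhaustive enumeration for global
# alignment, expansion-set substring search for degenerate primers, and ape
# for tree comparisons.

# Exhaustive global alignment score: enumerate every monotone alignment path
# and score it with affine gap costs (gap of length k costs go + (k-1)*ge).
brute_force_align_score <- function(a, b, smat, go, ge) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, smat[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- if (last == "U") ge else go
      best <- max(best, -cost + rec(i + 1, j, "U"))
    }
    if (j <= m) {
      cost <- if (last == "L") ge else go
      best <- max(best, -cost + rec(i, j + 1, "L"))
    }
    best
  }
  rec(1, 1, "")
}

# All start positions where any expansion of a degenerate pattern occurs as an
# exact substring of the template (overlaps included).
brute_force_sites <- function(iupac_pattern, template) {
  k <- nchar(iupac_pattern)
  expansions <- expand_iupac(iupac_pattern)
  starts <- seq_len(nchar(template) - k + 1)
  windows <- substring(template, starts, starts + k - 1)
  sort(unique(starts[windows %in% expansions]))
}

# Random DNA / protein strings
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# A fast helper family config (small but structurally complete)
small_family_config <- function(seed, n_isolates = 24L) {
  family_config(
    n_isolates = n_isolates,
    multiplicities = c(6L, 4L, rep(2L, 4L), rep(1L, n_isolates - 18L)),
    n_synonymous = 3L,
    n_turret_insertion = 1L, n_cterm6 = 1L, n_cterm9 = 1L,
    seed = seed
  )
}
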