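# Global pairwise alignment: affine-gap Needleman-Wunsch (Gotoh) over a
# precomputed cell-score matrix, shared by sequence-sequence and
# profile-profile alignment. Gap of length k costs gap_open + (k-1)*gap_extend.

#' Create an alignment scoring scheme
#'
#' @param smat Symmetric substitution score matrix with residue dimnames.
#' @param gap_open Penalty charged for the first position of a gap (>= 0).
#' @param gap_extend Penalty per additional gap position (>= 0, <= gap_open).
#' @param alphabet `"dna_iupac"` or `"protein"` (which records it applies to).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(smat, gap_open, gap_extend,
                           alphabet = c("protein", "dna_iupac")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.matrix(smat), gap_open >= gap_extend, gap_extend >= 0,
            isTRUE(all.equal(smat, t(smat))))
  structure(list(smat = smat, gap_open = gap_open, gap_extend = gap_extend,
                 alphabet = alphabet),
            class = "scoring_scheme")
}

#' Default DNA scoring scheme
#'
#' Match +2, mismatch -3, gap open 5, gap extend 2 — conventional defaults in
#' the spirit of megablast-era nucleotide scoring.
#' @return A `scoring_scheme`.
#' @export
dna_scheme <- function() {
  bases <- c("A", "C", "G", "T")
  smat <- matrix(-3, 4, 4, dimnames = list(bases, bases))
  diag(smat) <- 2
  scoring_scheme(smat, gap_open = 5, gap_extend = 2, alphabet = "dna_iupac")
}

#' Default protein scoring scheme (BLOSUM62, gap open 10 / extend 0.5)
#' @return A `scoring_scheme`.
#' @export
protein_scheme <- function() {
  if (is.null(.kcvkit_cache$protein_scheme)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .kcvkit_cache$protein_scheme <- scoring_scheme(
      e$BLOSUM62, gap_open = 10, gap_extend = 0.5, alphabet = "protein")
  }
  .kcvkit_cache$protein_scheme
}

# Gotoh global alignment over a cell score matrix S (n x m): S[i, j] is the
# score of pairing unit i of `a` with unit j of `b`. Deterministic traceback,
# tie-break preference diagonal > up (consume a) > left (consume b).
# Returns list(score, path_a, path_b) where paths are index vectors with 0 for
# a gap, equal length, degapping to 1..n / 1..m.
.gotoh <- function(S, go, ge) {
  n <- nrow(S); m <- ncol(S)
  gapcost <- function(k) if (k == 0L) 0 else go + (k - 1) * ge
  if (n == 0L && m == 0L) return(list(score = 0, path_a = integer(0), path_b = integer(0)))
  if (n == 0L) return(list(score = -gapcost(m), path_a = rep(0L, m), path_b = seq_len(m)))
  if (m == 0L) return(list(score = -gapcost(n), path_a = seq_len(n), path_b = rep(0L, n)))
  NEG <- -.Machine$double.xmax / 4
  M <- matrix(NEG, n + 1L, m + 1L)  # last move diagonal
  E <- matrix(NEG, n + 1L, m + 1L)  # last move left (gap in a, consumes b)
  F_ <- matrix(NEG, n + 1L, m + 1L) # last move up (gap in b, consumes a)
  # pointer codes: 1 = came from M, 2 = came from F, 3 = came from E
  pM <- matrix(0L, n + 1L, m + 1L)
  pE <- matrix(0L, n + 1L, m + 1L)
  pF <- matrix(0L, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (j in 2L:(m + 1L)) { E[1L, j] <- -gapcost(j - 1L); pE[1L, j] <- 3L }
  if (m >= 1L) pE[1L, 2L] <- 1L
  for (i in 2L:(n + 1L)) { F_[i, 1L] <- -gapcost(i - 1L); pF[i, 1L] <- 2L }
  if (n >= 1L) pF[2L, 1L] <- 1L
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      # M: pair (i-1, j-1)
      prev <- c(M[i - 1L, j - 1L], F_[i - 1L, j - 1L], E[i - 1L, j - 1L])
      k <- which.max(prev)  # ties: M > F (up) > E (left)
      M[i, j] <- prev[k] + S[i - 1L, j - 1L]
      pM[i, j] <- c(1L, 2L, 3L)[k]
      # F: gap in b, consume a (move up)
      open_f <- M[i - 1L, j] - go
      ext_f <- F_[i - 1L, j] - ge
      if (open_f >= ext_f) { F_[i, j] <- open_f; pF[i, j] <- 1L }
      else { F_[i, j] <- ext_f; pF[i, j] <- 2L }
      # E: gap in a, consume b (move left)
      open_e <- M[i, j - 1L] - go
      ext_e <- E[i, j - 1L] - ge
      if (open_e >= ext_e) { E[i, j] <- open_e; pE[i, j] <- 1L }
      else { E[i, j] <- ext_e; pE[i, j] <- 3L }
    }
  }
  finals <- c(M[n + 1L, m + 1L], F_[n + 1L, m + 1L], E[n + 1L, m + 1L])
  state <- which.max(finals)  # M > F > E on ties
  score <- finals[state]
  # traceback
  pa <- integer(0); pb <- integer(0)
  i <- n + 1L; j <- m + 1L
  state <- c(1L, 2L, 3L)[state]
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      pa <- c(i - 1L, pa); pb <- c(j - 1L, pb)
      state <- pM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      pa <- c(i - 1L, pa); pb <- c(0L, pb)
      state <- pF[i, j]; i <- i - 1L
    } else {
      pa <- c(0L, pa); pb <- c(j - 1L, pb)
      state <- pE[i, j]; j <- j - 1L
    }
  }
  list(score = score, path_a = pa, path_b = pb)
}

#' Optimal global alignment of two sequence records
#'
#' Needleman-Wunsch with affine gaps (Gotoh). A gap of length k costs
#' `gap_open + (k-1) * gap_extend`. The traceback is deterministic with
#' tie-break preference diagonal > up > left, so downstream column-difference
#' counts are reproducible. Aligning against an empty sequence yields an
#' all-gap row.
#'
#' @param a,b [seq_record()]s over the same alphabet (`b` may be constructed
#'   with empty residues only via internal calls; see details).
#' @param scheme A [scoring_scheme()]; defaults by alphabet.
#' @return Object of class `pairwise_alignment`: list with gapped `row_a`,
#'   `row_b`, `score`, and the input ids.
#' @export
global_align <- function(a, b, scheme = NULL) {
  stopifnot(inherits(a, "seq_record"), inherits(b, "seq_record"))
  if (a$alphabet != b$alphabet) stop("alphabet mismatch", call. = FALSE)
  if (is.null(scheme)) {
    scheme <- if (a$alphabet == "protein") protein_scheme() else dna_scheme()
  }
  ca <- strsplit(a$residues, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b$residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(c(ca, cb), rownames(scheme$smat))
  if (length(bad) > 0L) {
    stop("residue(s) absent from scoring matrix: ", paste(bad, collapse = ","),
         call. = FALSE)
  }
  S <- scheme$smat[ca, cb, drop = FALSE]
  res <- .gotoh(S, scheme$gap_open, scheme$gap_extend)
  gap_or <- function(chars, path) ifelse(path == 0L, "-", chars[pmax(path, 1L)])
  structure(list(
    id_a = a$id, id_b = b$id,
    row_a = paste(gap_or(ca, res$path_a), collapse = ""),
    row_b = paste(gap_or(cb, res$path_b), collapse = ""),
    score = res$score
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment %s/%s score %.2f>\n%s\n%s\n",
              x$id_a, x$id_b, x$score, x$row_a, x$row_b))
  invisible(x)
}
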