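# IUPAC nucleotide ambiguity tables and degenerate-sequence helpers.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", `-` = "-"
)

.dna_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1L]]

.check_iupac <- function(chars, allow_gap = FALSE) {
  legal <- names(.IUPAC_SETS)
  if (allow_gap) legal <- c(legal, "-")
  bad <- setdiff(unique(chars), legal)
  if (length(bad) > 0L) {
    stop("invalid IUPAC character(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(chars)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Complements every base IUPAC-aware (R<->Y, K<->M, S and W self-complementary,
#' B<->V, D<->H, N->N) and reverses the result, so that reverse-complementing a
#' degenerate primer yields the degenerate pattern of its binding site on the
#' plus strand. The operation is an involution.
#'
#' @param seq A single nucleotide string, possibly containing IUPAC ambiguity
#'   codes. Case-insensitive; the result is upper case.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("AAGC")  # "GCTT"
#' reverse_complement("TYG")   # "CRA"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- .dna_chars(seq)
  .check_iupac(chars, allow_gap = TRUE)
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Degeneracy of an IUPAC nucleotide string
#'
#' The number of distinct unambiguous DNA strings a degenerate sequence
#' represents: the product over positions of the ambiguity-set sizes
#' (N counts 4, three-fold codes 3, two-fold codes 2, plain bases 1).
#'
#' @param seq A single nucleotide string with IUPAC codes.
#' @return A positive number (may exceed integer range for very long primers).
#' @examples
#' degeneracy("ACGT")  # 1
#' degeneracy("NN")    # 16
#' @export
degeneracy <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- .dna_chars(seq)
  .check_iupac(chars)
  prod(vapply(chars, function(ch) length(.IUPAC_SETS[[ch]]), numeric(1)))
}

#' Enumerate all unambiguous expansions of an IUPAC string
#'
#' Brute-force expansion of a degenerate sequence into every concrete ACGT
#' string it matches. Refuses to expand beyond `max_expansions` strings.
#'
#' @param seq A nucleotide string with IUPAC codes.
#' @param max_expansions Safety cap on the expansion-set size.
#' @return Character vector of unambiguous DNA strings (lexicographic order).
#' @export
expand_iupac <- function(seq, max_expansions = 1e4) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- .dna_chars(seq)
  .check_iupac(chars)
  if (degeneracy(seq) > max_expansions) {
    stop("degeneracy exceeds max_expansions (", max_expansions, ")", call. = FALSE)
  }
  out <- ""
  for (ch in chars) {
    out <- as.vector(outer(out, .IUPAC_SETS[[ch]], paste0))
  }
  sort(out)
}

# TRUE where the template base (unambiguous) lies in the ambiguity set of the
# primer base, vectorized over equal-length character vectors.
.iupac_base_match <- function(primer_chars, template_chars) {
  mapply(function(p, t) t %in% .IUPAC_SETS[[p]], primer_chars, template_chars,
         USE.NAMES = FALSE)
}
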