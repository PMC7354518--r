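# Progressive multiple alignment and column conservation. Guide order comes
# from single-linkage clustering on 3-mer Jaccard distances; profiles are
# merged by affine-gap profile-profile alignment ("once a gap, always a gap").

#' Construct a multiple alignment
#'
#' @param ids Character vector of row ids (unique).
#' @param rows Equal-length gapped strings, one per id.
#' @param alphabet Residue alphabet of the rows.
#' @return Object of class `multiple_alignment` with fields `ids`, `rows`,
#'   `n_columns`, `alphabet`.
#' @export
multiple_alignment <- function(ids, rows, alphabet = c("protein", "dna_iupac")) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(ids) == length(rows), !anyDuplicated(ids))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) stop("rows differ in length", call. = FALSE)
  structure(list(ids = unname(as.character(ids)),
                 rows = unname(toupper(as.character(rows))),
                 n_columns = unname(widths[1L]), alphabet = alphabet),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment %d rows x %d columns [%s]>\n",
              length(x$ids), x$n_columns, x$alphabet))
  invisible(x)
}

# rows as a character matrix (n x L)
.msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
}

#' Remove gaps from an alignment row
#' @param row A gapped string.
#' @return The ungapped sequence string.
#' @export
degap <- function(row) gsub("-", "", row, fixed = TRUE)

# 3-mer set of a sequence string
.kmer_set <- function(s, k = 3L) {
  n <- nchar(s)
  if (n < k) return(s)
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# column frequency matrix (residues x columns), counts / n_rows; gaps drop out
.profile_freq <- function(mat, residues) {
  L <- ncol(mat)
  f <- matrix(0, nrow = length(residues), ncol = L, dimnames = list(residues, NULL))
  for (j in seq_len(L)) {
    tab <- table(factor(mat[, j], levels = residues))
    f[, j] <- as.numeric(tab) / nrow(mat)
  }
  f
}

# merge two alignment matrices by profile-profile Gotoh alignment
.merge_profiles <- function(ma, mb, scheme) {
  residues <- rownames(scheme$smat)
  fa <- .profile_freq(ma, residues)
  fb <- .profile_freq(mb, residues)
  S <- t(fa) %*% scheme$smat %*% fb
  res <- .gotoh(S, scheme$gap_open, scheme$gap_extend)
  take <- function(m, path) {
    out <- matrix("-", nrow = nrow(m), ncol = length(path))
    rownames(out) <- rownames(m)
    nz <- path != 0L
    out[, nz] <- m[, path[nz], drop = FALSE]
    out
  }
  rbind(take(ma, res$path_a), take(mb, res$path_b))
}

#' Progressive multiple sequence alignment
#'
#' A deterministic stand-in for an interactive aligner's default global
#' alignment: the guide order is single-linkage clustering on pairwise 3-mer
#' Jaccard distances, and clusters are merged by affine-gap profile-profile
#' alignment in which a gap, once inserted into a profile, is inserted into
#' every row of that profile and never removed. Row order in the result
#' follows the input order.
#'
#' @param seqs List of >= 2 [seq_record()]s over one alphabet.
#' @param scheme A [scoring_scheme()]; defaults by alphabet.
#' @return A [multiple_alignment()].
#' @export
progressive_msa <- function(seqs, scheme = NULL) {
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  alphabet <- seqs[[1L]]$alphabet
  if (!all(vapply(seqs, `[[`, character(1), "alphabet") == alphabet)) {
    stop("alphabet mismatch across inputs", call. = FALSE)
  }
  if (is.null(scheme)) {
    scheme <- if (alphabet == "protein") protein_scheme() else dna_scheme()
  }
  ids <- vapply(seqs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  n <- length(seqs)
  strs <- vapply(seqs, `[[`, character(1), "residues")
  kmers <- lapply(strs, .kmer_set)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    inter <- length(intersect(kmers[[i]], kmers[[j]]))
    uni <- length(union(kmers[[i]], kmers[[j]]))
    D[i, j] <- D[j, i] <- 1 - inter / uni
  }
  singleton <- function(i) matrix(strsplit(strs[i], "", fixed = TRUE)[[1L]],
                                  nrow = 1L,
                                  dimnames = list(ids[i], NULL))
  if (n == 2L) {
    merged <- .merge_profiles(singleton(1L), singleton(2L), scheme)
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = "single")
    nodes <- vector("list", n - 1L)
    for (r in seq_len(nrow(hc$merge))) {
      pick <- function(v) if (v < 0L) singleton(-v) else nodes[[v]]
      nodes[[r]] <- .merge_profiles(pick(hc$merge[r, 1L]), pick(hc$merge[r, 2L]), scheme)
    }
    merged <- nodes[[n - 1L]]
  }
  merged <- merged[ids, , drop = FALSE]
  multiple_alignment(ids, apply(merged, 1L, paste, collapse = ""),
                     alphabet = alphabet)
}

#' Per-column conservation of a multiple alignment
#'
#' Conservation of a column is the fraction of rows carrying its modal symbol;
#' the gap character counts as a symbol class of its own. Values lie in
#' (0, 1]; a column is fully conserved at 1.
#'
#' @param msa A [multiple_alignment()].
#' @return List with `fraction` (numeric vector, one entry per column),
#'   `modal` (modal symbol per column) and `n_fully_conserved`.
#' @export
column_conservation <- function(msa) {
  mat <- .msa_matrix(msa)
  modal <- character(ncol(mat)); frac <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    tab <- sort(table(mat[, j]), decreasing = TRUE)
    modal[j] <- names(tab)[1L]
    frac[j] <- as.numeric(tab[1L]) / nrow(mat)
  }
  list(fraction = frac, modal = modal,
       n_fully_conserved = sum(frac == 1))
}

#' Write a conservation profile as TSV (column, modal symbol, fraction)
#' @param cons Result of [column_conservation()].
#' @param path Output path.
#' @export
write_conservation_tsv <- function(cons, path) {
  utils::write.table(
    data.frame(column = seq_along(cons$fraction), modal = cons$modal,
               fraction = cons$fraction),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gapped (aligned) FASTA file as a multiple alignment
#' @param path FASTA path.
#' @param alphabet Residue alphabet.
#' @return A [multiple_alignment()].
#' @export
read_msa_fasta <- function(path, alphabet = c("protein", "dna_iupac")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  multiple_alignment(ids, as.character(set), alphabet = alphabet)
}

#' Write a multiple alignment as gapped FASTA
#' @param msa A [multiple_alignment()].
#' @param path Output path.
#' @export
write_msa_fasta <- function(msa, path) {
  recs <- lapply(seq_along(msa$ids), function(i) {
    seq_record(msa$ids[i], msa$rows[i], alphabet = msa$alphabet, allow_gap = TRUE)
  })
  write_fasta(recs, path)
}
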