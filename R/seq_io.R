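# Sequence records, FASTA input/output, and translation.

.PROTEIN_CHARS <- c(LETTERS, "*", "-")

#' Create a sequence record
#'
#' A `seq_record` is the basic currency of the package: an identified
#' nucleotide or protein sequence with an explicit alphabet tag. Nucleotide
#' records accept the full IUPAC ambiguity alphabet; `U` is tolerated on input
#' and mapped to `T`. The gap character `-` is only legal inside alignment
#' rows, never in raw records.
#'
#' @param id Record identifier (first whitespace-delimited token of a FASTA
#'   header). Must be non-empty.
#' @param residues The sequence itself; canonicalized to upper case.
#' @param alphabet `"dna_iupac"` or `"protein"`.
#' @param description Free-text remainder of the header, may be empty.
#' @param allow_gap Permit `-` characters (used internally for alignment rows).
#' @param allow_empty Permit an empty sequence (used for degenerate alignment
#'   inputs only; raw records are always non-empty).
#' @return An object of class `seq_record` with fields `id`, `description`,
#'   `residues`, `alphabet`.
#' @export
seq_record <- function(id, residues, alphabet = c("dna_iupac", "protein"),
                       description = "", allow_gap = FALSE, allow_empty = FALSE) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues) && !allow_empty) {
    stop("record '", id, "' has an empty sequence", call. = FALSE)
  }
  if (alphabet == "dna_iupac") {
    residues <- gsub("U", "T", residues, fixed = TRUE)
    .check_iupac(strsplit(residues, "", fixed = TRUE)[[1L]], allow_gap = allow_gap)
  } else {
    chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
    legal <- if (allow_gap) .PROTEIN_CHARS else setdiff(.PROTEIN_CHARS, "-")
    bad <- setdiff(unique(chars), legal)
    if (length(bad) > 0L) {
      stop("record '", id, "' has illegal protein character(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(id = unname(id), description = unname(description),
                 residues = unname(residues), alphabet = alphabet),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s [%s] %d residues>\n", x$id, x$alphabet,
              nchar(x$residues)))
  invisible(x)
}

#' Read a FASTA file into a list of sequence records
#'
#' Arbitrary line wrapping is accepted; record order is preserved and each id
#' is the first whitespace-delimited token of its header. An empty file, a
#' header with no sequence, or a duplicated id is an error.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Alphabet tag applied to every record.
#' @return A list of [seq_record()] objects, in file order.
#' @export
read_fasta <- function(path, alphabet = c("dna_iupac", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  empty <- Biostrings::width(set) == 0L
  if (any(empty)) {
    stop("record(s) with no sequence: ", paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  descs <- sub("^\\S+[ \t]*", "", headers)
  seqs <- as.character(set)
  lapply(seq_along(set), function(i) {
    seq_record(ids[i], seqs[i], alphabet = alphabet, description = descs[i])
  })
}

#' Write sequence records to a FASTA file
#'
#' @param records A list of [seq_record()] objects (gapped rows allowed).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", header), con)
    s <- r$residues
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' The standard genetic code
#'
#' Codon-to-amino-acid map (64 entries, stops as `*`) used by [translate_cds()].
#' Only the standard code is supported.
#'
#' @return Named character vector of length 64.
#' @export
genetic_code_table <- function() {
  if (is.null(.kcvkit_cache$genetic_code)) {
    gc <- Biostrings::GENETIC_CODE
    stopifnot(length(gc) == 64L)
    .kcvkit_cache$genetic_code <- gc
  }
  .kcvkit_cache$genetic_code
}

#' Translate a coding sequence
#'
#' Standard-code translation of an unambiguous, in-frame CDS. An internal stop
#' codon, a length not divisible by three, or any ambiguity code is an error.
#'
#' @param cds A DNA [seq_record()] (plain ACGT only).
#' @param strip_terminal_stop Drop a trailing stop codon instead of failing on
#'   the `*` it would introduce.
#' @return A protein [seq_record()] with the same id.
#' @examples
#' translate_cds(seq_record("x", "ATGGTT"))$residues            # "MV"
#' translate_cds(seq_record("x", "ATGTAA"), TRUE)$residues      # "M"
#' @export
translate_cds <- function(cds, strip_terminal_stop = FALSE) {
  stopifnot(inherits(cds, "seq_record"), cds$alphabet == "dna_iupac")
  s <- cds$residues
  n <- nchar(s)
  if (n %% 3L != 0L) {
    stop("CDS length ", n, " is not a multiple of 3 (", cds$id, ")", call. = FALSE)
  }
  if (grepl("[^ACGT]", s)) {
    stop("ambiguity code or gap in CDS '", cds$id, "'", call. = FALSE)
  }
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(genetic_code_table()[codons])
  if (strip_terminal_stop && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) {
    stop("internal stop codon in CDS '", cds$id, "' at codon ",
         which(aa == "*")[1L], call. = FALSE)
  }
  seq_record(cds$id, paste(aa, collapse = ""), alphabet = "protein",
             description = cds$description)
}
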