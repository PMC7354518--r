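# Core counting analysis: unique-haplotype collapse, variable sites, pairwise
# divergence, protein length classes and selectivity-filter motif classes.

#' Collapse sequences into unique groups
#'
#' Exact, case-insensitive string identity on the residues (for CDSs this
#' includes the stop codon). Groups are ordered by descending multiplicity,
#' ties by first appearance in the input; the representative is the first
#' member seen.
#'
#' @param seqs Non-empty list of ungapped [seq_record()]s over one alphabet.
#' @return List of `unique_group` objects, each with `representative`
#'   ([seq_record()]), `member_ids` and `count`.
#' @export
collapse_unique <- function(seqs) {
  if (length(seqs) == 0L) stop("empty input", call. = FALSE)
  alph <- unique(vapply(seqs, `[[`, character(1), "alphabet"))
  if (length(alph) != 1L) stop("mixed alphabets", call. = FALSE)
  if (any(grepl("-", vapply(seqs, `[[`, character(1), "residues"), fixed = TRUE))) {
    stop("gapped sequences cannot be collapsed", call. = FALSE)
  }
  keys <- toupper(vapply(seqs, `[[`, character(1), "residues"))
  first <- !duplicated(keys)
  reps <- keys[first]
  groups <- lapply(reps, function(k) {
    idx <- which(keys == k)
    structure(list(representative = seqs[[idx[1L]]],
                   member_ids = vapply(seqs[idx], `[[`, character(1), "id"),
                   count = length(idx)),
              class = "unique_group")
  })
  counts <- vapply(groups, `[[`, integer(1), "count")
  groups[order(-counts, seq_along(groups))]
}

#' Count variable columns of a multiple alignment
#'
#' A column is variable iff at least two distinct symbols occur in it; the gap
#' character counts as a symbol.
#'
#' @param msa A [multiple_alignment()].
#' @return List with `variable_count` and `n_columns`.
#' @export
variable_sites <- function(msa) {
  mat <- .msa_matrix(msa)
  nvar <- sum(apply(mat, 2L, function(col) length(unique(col)) > 1L))
  list(variable_count = nvar, n_columns = ncol(mat))
}

#' Count differences between two proteins after global alignment
#'
#' The pair is globally aligned and differences are counted over alignment
#' columns; a residue opposite a gap counts as one difference. The percentage
#' uses the alignment length as denominator (so indels dilute as well as
#' count).
#'
#' @param a,b Protein [seq_record()]s.
#' @param scheme A [scoring_scheme()]; defaults to [protein_scheme()].
#' @return List with `diff_count`, `alignment_length`, `percent`.
#' @export
pairwise_differences <- function(a, b, scheme = NULL) {
  stopifnot(nzchar(a$residues), nzchar(b$residues))
  aln <- global_align(a, b, scheme)
  ca <- strsplit(aln$row_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$row_b, "", fixed = TRUE)[[1L]]
  d <- sum(ca != cb)
  list(diff_count = d, alignment_length = length(ca),
       percent = 100 * d / length(ca))
}

#' Protein length histogram
#'
#' @param proteins List of protein [seq_record()]s (typically unique ones).
#' @return Named integer vector mapping length to count (ascending lengths);
#'   empty input gives an empty vector.
#' @export
length_histogram <- function(proteins) {
  if (length(proteins) == 0L) return(integer(0))
  lens <- vapply(proteins, function(r) nchar(r$residues), integer(1))
  tab <- table(lens)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Locate and classify the K+ selectivity-filter motif
#'
#' Searches for the leftmost match of the octapeptide pattern
#' `T-T-x-G-[YF]-G-[DN]-x` (the canonical filter signature of two-TM K+
#' channels, covering the TTVGYGDL / TTTGYGDL / TTTGFGDV classes seen in
#' chlorovirus Kcvs). Absence of the motif is reported explicitly, never
#' silently.
#'
#' @param protein A protein [seq_record()].
#' @return List with `found` (logical), `motif` (8-mer string or `NA`), and
#'   `start` (1-based position or `NA`).
#' @export
classify_filter_motif <- function(protein) {
  stopifnot(inherits(protein, "seq_record"), protein$alphabet == "protein")
  m <- regexpr("TT[A-Z]G[YF]G[DN][A-Z]", protein$residues)
  if (m[1L] == -1L) {
    return(list(found = FALSE, motif = NA_character_, start = NA_integer_))
  }
  list(found = TRUE,
       motif = substr(protein$residues, m[1L], m[1L] + 7L),
       start = as.integer(m[1L]))
}

#' Re-annotate a protein to an internal start methionine
#'
#' Some deposited CDSs begin upstream of the probable true start codon,
#' producing an N-terminally extended protein that contains an internal Met
#' at exactly the offset that would restore the family's canonical length.
#' If `protein` is longer than `target_length` and carries `M` at position
#' `length - target_length + 1`, the trimmed protein is returned; otherwise
#' the record is returned unchanged.
#'
#' @param protein A protein [seq_record()].
#' @param target_length Canonical protein length to restore.
#' @return A protein [seq_record()] (possibly unchanged).
#' @export
reannotate_start <- function(protein, target_length) {
  n <- nchar(protein$residues)
  off <- n - target_length + 1L
  if (n > target_length && substr(protein$residues, off, off) == "M") {
    protein$residues <- substr(protein$residues, off, n)
  }
  protein
}

#' Full diversity report for a family of kcv coding sequences
#'
#' Runs the counting pipeline: collapse to unique DNA haplotypes, translate
#' representatives (terminal stop stripped), collapse to unique proteins,
#' tabulate protein lengths and filter-motif classes, count variable sites
#' over the modal-length class (stacked without gaps, i.e. assuming those
#' CDSs are colinear), and compute pairwise differences of every unique
#' protein against a named reference.
#'
#' @param cds_list List of DNA [seq_record()]s (in-frame CDSs incl. stop).
#' @param reference_id Id of the reference isolate for the difference table;
#'   default: the representative of the largest DNA group.
#' @param scheme Protein [scoring_scheme()] for the difference table.
#' @param reannotate_internal_start If `TRUE`, N-terminally extended proteins
#'   whose internal Met would restore the modal protein length are trimmed to
#'   that internal start ([reannotate_start()]) before protein-level counting.
#'   Default off: sequences are analysed as deposited.
#' @return Object of class `diversity_report`; see fields in the details.
#' @details Fields: `n_input`, `n_unique_dna`, `n_unique_protein`,
#'   `dna_groups`, `protein_groups`, `length_histogram`, `motif_classes`
#'   (named counts incl. `"none"`), `variable` (list: `variable_count`,
#'   `n_columns`, computed over the modal nucleotide length class),
#'   `reference_id`, `diff_table` (data.frame id/diff_count/alignment_length/
#'   percent vs reference).
#' @export
diversity_report <- function(cds_list, reference_id = NULL, scheme = NULL,
                             reannotate_internal_start = FALSE) {
  dna_groups <- collapse_unique(cds_list)
  reps <- lapply(dna_groups, `[[`, "representative")
  prots <- lapply(reps, translate_cds, strip_terminal_stop = TRUE)
  if (reannotate_internal_start) {
    plens <- vapply(prots, function(p) nchar(p$residues), integer(1))
    modal_plen <- as.integer(names(sort(table(plens), decreasing = TRUE))[1L])
    prots <- lapply(prots, reannotate_start, target_length = modal_plen)
  }
  protein_groups <- collapse_unique(prots)
  uprot <- lapply(protein_groups, `[[`, "representative")
  # protein-group multiplicity = number of isolates, not number of DNA groups
  dna_count_of <- stats::setNames(vapply(dna_groups, `[[`, integer(1), "count"),
                                  vapply(reps, `[[`, character(1), "id"))
  for (i in seq_along(protein_groups)) {
    protein_groups[[i]]$count <-
      sum(dna_count_of[protein_groups[[i]]$member_ids])
  }
  motifs <- vapply(uprot, function(p) {
    cl <- classify_filter_motif(p)
    if (cl$found) cl$motif else "none"
  }, character(1))
  # variable sites over the modal CDS length class, stacked without gaps
  rep_lens <- vapply(reps, function(r) nchar(r$residues), integer(1))
  modal_len <- as.integer(names(sort(table(rep_lens), decreasing = TRUE))[1L])
  cls <- reps[rep_lens == modal_len]
  varsites <- if (length(cls) >= 2L) {
    variable_sites(multiple_alignment(
      vapply(cls, `[[`, character(1), "id"),
      vapply(cls, `[[`, character(1), "residues"),
      alphabet = "dna_iupac"))
  } else list(variable_count = 0L, n_columns = modal_len)
  if (is.null(reference_id)) reference_id <- dna_groups[[1L]]$representative$id
  ref_prot <- NULL
  for (p in uprot) if (p$id == reference_id) ref_prot <- p
  if (is.null(ref_prot)) {
    # reference may be any input isolate id; translate its CDS
    for (g in dna_groups) {
      if (reference_id %in% g$member_ids) {
        ref_prot <- translate_cds(g$representative, strip_terminal_stop = TRUE)
        ref_prot$id <- reference_id
        break
      }
    }
  }
  if (is.null(ref_prot)) stop("reference id not found: ", reference_id, call. = FALSE)
  diffs <- lapply(uprot, pairwise_differences, b = ref_prot, scheme = scheme)
  structure(list(
    n_input = length(cds_list),
    n_unique_dna = length(dna_groups),
    n_unique_protein = length(protein_groups),
    dna_groups = dna_groups,
    protein_groups = protein_groups,
    length_histogram = length_histogram(uprot),
    motif_classes = c(table(motifs)),
    variable = varsites,
    reference_id = reference_id,
    diff_table = data.frame(
      id = vapply(uprot, `[[`, character(1), "id"),
      diff_count = vapply(diffs, `[[`, numeric(1), "diff_count"),
      alignment_length = vapply(diffs, `[[`, numeric(1), "alignment_length"),
      percent = vapply(diffs, `[[`, numeric(1), "percent"))
  ), class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Kcv diversity report\n",
    "  isolates:        %d\n",
    "  unique DNA:      %d\n",
    "  unique proteins: %d\n",
    "  variable sites:  %d of %d (modal length class)\n"),
    x$n_input, x$n_unique_dna, x$n_unique_protein,
    x$variable$variable_count, x$variable$n_columns))
  cat("  protein lengths: ",
      paste(sprintf("%s aa x %d", names(x$length_histogram), x$length_histogram),
            collapse = ", "), "\n", sep = "")
  cat("  filter motifs:   ",
      paste(sprintf("%s x %d", names(x$motif_classes), x$motif_classes),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a diversity report as TSV sections plus JSON
#'
#' `<stem>.tsv` holds human-readable sections (summary, length histogram,
#' motif classes, difference table); `<stem>.json` the same content
#' machine-readable.
#'
#' @param report A [diversity_report()].
#' @param stem Output path stem (without extension).
#' @export
write_diversity_report <- function(report, stem) {
  tsv <- paste0(stem, ".tsv")
  con <- file(tsv, "w")
  writeLines("# section\tkey\tvalue", con)
  writeLines(sprintf("summary\t%s\t%d",
                     c("n_input", "n_unique_dna", "n_unique_protein",
                       "variable_sites", "alignment_columns"),
                     c(report$n_input, report$n_unique_dna, report$n_unique_protein,
                       report$variable$variable_count, report$variable$n_columns)), con)
  writeLines(sprintf("length_histogram\t%s\t%d",
                     names(report$length_histogram), report$length_histogram), con)
  writeLines(sprintf("motif_class\t%s\t%d",
                     names(report$motif_classes), report$motif_classes), con)
  writeLines(sprintf("diff_vs_%s\t%s\t%g", report$reference_id,
                     report$diff_table$id, report$diff_table$diff_count), con)
  close(con)
  json <- paste0(stem, ".json")
  jsonlite::write_json(list(
    n_input = report$n_input,
    n_unique_dna = report$n_unique_dna,
    n_unique_protein = report$n_unique_protein,
    variable_sites = report$variable$variable_count,
    alignment_columns = report$variable$n_columns,
    length_histogram = as.list(report$length_histogram),
    motif_classes = as.list(report$motif_classes),
    reference_id = report$reference_id,
    diff_table = report$diff_table
  ), json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
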