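# Domain architecture of the two-TM viral K+ channel subunit and transfer of
# a reference annotation onto query proteins through pairwise alignment.

.DOMAIN_NAMES <- c("slide_helix", "TMD1", "turret", "pore_helix", "filter",
                   "TMD2", "c_tail")

#' Create a domain annotation
#'
#' Half-open residue intervals `[start, end)` in 1-based protein coordinates
#' for the domains `slide_helix`, `TMD1`, `turret`, `pore_helix`, `filter`,
#' `TMD2`, `c_tail`. Intervals must be ordered and non-overlapping; a domain
#' may be empty (`start == end`, e.g. the slide helix, which chlorovirus Kcvs
#' of this clade essentially lack). The filter interval is always 8 residues.
#'
#' @param intervals Named list of `c(start, end)` pairs covering all seven
#'   domain names.
#' @return Object of class `domain_annotation` (named list of integer pairs).
#' @export
domain_annotation <- function(intervals) {
  stopifnot(setequal(names(intervals), .DOMAIN_NAMES))
  intervals <- intervals[.DOMAIN_NAMES]
  prev_end <- -Inf
  for (nm in .DOMAIN_NAMES) {
    iv <- intervals[[nm]]
    stopifnot(length(iv) == 2L, iv[1L] <= iv[2L])
    if (iv[1L] < prev_end) stop("domain intervals overlap or are out of order at ", nm,
                                call. = FALSE)
    if (iv[2L] > iv[1L]) prev_end <- iv[2L]
  }
  if (diff(intervals$filter) != 8L) stop("filter interval must span 8 residues",
                                         call. = FALSE)
  structure(lapply(intervals, as.integer), class = "domain_annotation")
}

#' Default domain map of an 82-residue chlorovirus Kcv subunit
#'
#' The stated architecture used by the synthetic generator and as the
#' reference layout: no slide helix, outer helix TMD1 (4-25), extracellular
#' turret (26-39), pore helix (40-49), selectivity filter octapeptide (50-57),
#' inner helix TMD2 (58-78), short cytosolic tail (79-82). Half-open
#' intervals.
#'
#' @return A [domain_annotation()].
#' @export
default_domain_annotation <- function() {
  domain_annotation(list(
    slide_helix = c(1L, 1L),
    TMD1 = c(4L, 26L),
    turret = c(26L, 40L),
    pore_helix = c(40L, 50L),
    filter = c(50L, 58L),
    TMD2 = c(58L, 79L),
    c_tail = c(79L, 83L)
  ))
}

# domain name for each residue index of an annotated protein ("" outside)
.residue_domains <- function(annotation, n_residues) {
  out <- rep("", n_residues)
  for (nm in .DOMAIN_NAMES) {
    iv <- annotation[[nm]]
    if (iv[2L] > iv[1L]) out[iv[1L]:(iv[2L] - 1L)] <- nm
  }
  out
}

#' Transfer a reference domain annotation onto a query protein
#'
#' The query is globally aligned to the annotated reference and each residue
#' inherits the domain of the reference residue it aligns to. Insertions
#' (query residues opposite reference gaps) inherit the domain of the nearest
#' preceding aligned reference residue, except that insertions falling between
#' TMD1 and the pore helix are assigned to the turret (the region where the
#' larger Kcv variants carry extra residues) and insertions after the last
#' reference residue extend the C-terminal tail. Finally the filter interval
#' is re-anchored on the query's own motif match and its neighbours trimmed to
#' it. Both proteins must carry a filter motif.
#'
#' @param protein Query protein [seq_record()].
#' @param reference Reference protein [seq_record()].
#' @param ref_annotation [domain_annotation()] of the reference.
#' @param scheme Protein [scoring_scheme()].
#' @return A [domain_annotation()] for the query.
#' @export
annotate_domains <- function(protein, reference,
                             ref_annotation = default_domain_annotation(),
                             scheme = NULL) {
  qm <- classify_filter_motif(protein)
  rm_ <- classify_filter_motif(reference)
  if (!qm$found || !rm_$found) stop("filter motif missing", call. = FALSE)
  aln <- global_align(protein, reference, scheme)
  cq <- strsplit(aln$row_a, "", fixed = TRUE)[[1L]]
  cr <- strsplit(aln$row_b, "", fixed = TRUE)[[1L]]
  ref_dom <- .residue_domains(ref_annotation, nchar(reference$residues))
  turret_zone <- c("TMD1", "turret", "pore_helix")
  qlab <- character(0)  # domain label per query residue
  ri <- 0L
  pending <- 0L  # insertions seen before any aligned ref residue
  for (k in seq_along(cq)) {
    if (cr[k] != "-") ri_next <- ri + 1L else ri_next <- ri
    if (cq[k] != "-") {
      if (cr[k] != "-") {
        lab <- if (ri_next >= 1L && ri_next <= length(ref_dom)) ref_dom[ri_next] else ""
      } else if (ri == 0L) {
        lab <- ""  # N-terminal insertion, resolved below
        pending <- pending + 1L
      } else if (ri >= length(ref_dom)) {
        lab <- "c_tail"
      } else {
        prev <- ref_dom[ri]
        nxt <- ref_dom[min(ri + 1L, length(ref_dom))]
        lab <- if (prev %in% turret_zone && nxt %in% c("turret", "pore_helix", "filter"))
          "turret" else prev
      }
      qlab <- c(qlab, lab)
    }
    ri <- ri_next
  }
  # N-terminal insertions stay unassigned (lab ""), like reference residues
  # outside any domain.
  n <- length(qlab)
  stopifnot(n == nchar(protein$residues))
  # build intervals from contiguous labels, in canonical domain order
  iv <- stats::setNames(vector("list", length(.DOMAIN_NAMES)), .DOMAIN_NAMES)
  cursor <- 1L
  for (nm in .DOMAIN_NAMES) {
    idx <- which(qlab == nm)
    if (length(idx) == 0L) {
      iv[[nm]] <- c(cursor, cursor)
    } else {
      iv[[nm]] <- c(min(idx), max(idx) + 1L)
      cursor <- max(idx) + 1L
    }
  }
  # re-anchor the filter on the query's own motif
  fs <- qm$start
  iv$filter <- c(fs, fs + 8L)
  if (iv$pore_helix[2L] > fs) iv$pore_helix[2L] <- fs
  if (iv$pore_helix[1L] > iv$pore_helix[2L]) iv$pore_helix[1L] <- iv$pore_helix[2L]
  if (iv$TMD2[1L] < fs + 8L) iv$TMD2[1L] <- fs + 8L
  if (iv$TMD2[2L] < iv$TMD2[1L]) iv$TMD2[2L] <- iv$TMD2[1L]
  domain_annotation(iv)
}

#' Mean per-domain conservation of an alignment
#'
#' For each domain of an annotated reference row, the mean of
#' [column_conservation()] over the alignment columns whose reference residue
#' lies in that domain. Domains with no columns are reported as `NA` (absent).
#'
#' @param msa A [multiple_alignment()] containing the reference row.
#' @param reference_id Row id of the annotated reference.
#' @param ref_annotation [domain_annotation()] of the (ungapped) reference.
#' @return Named numeric vector, one entry per domain.
#' @export
per_domain_conservation <- function(msa, reference_id,
                                    ref_annotation = default_domain_annotation()) {
  ridx <- match(reference_id, msa$ids)
  if (is.na(ridx)) stop("reference row not in alignment", call. = FALSE)
  cons <- column_conservation(msa)$fraction
  rrow <- strsplit(msa$rows[ridx], "", fixed = TRUE)[[1L]]
  ref_res_at_col <- cumsum(rrow != "-")
  ref_res_at_col[rrow == "-"] <- NA
  ref_dom <- .residue_domains(ref_annotation, sum(rrow != "-"))
  out <- stats::setNames(rep(NA_real_, length(.DOMAIN_NAMES)), .DOMAIN_NAMES)
  for (nm in .DOMAIN_NAMES) {
    cols <- which(!is.na(ref_res_at_col) & ref_dom[pmax(ref_res_at_col, 1L)] == nm)
    if (length(cols) > 0L) out[nm] <- mean(cons[cols])
  }
  out
}

#' Write domain annotations as BED-like TSV
#'
#' Columns: id, domain, start, end — 1-based inclusive start, exclusive end
#' (stated in the header line). Empty domains are omitted.
#'
#' @param annotations Named list of [domain_annotation()]s (names = protein ids).
#' @param path Output path.
#' @export
write_domain_bed <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id\tdomain\tstart\tend (1-based inclusive start, exclusive end)", con)
  for (id in names(annotations)) {
    ann <- annotations[[id]]
    for (nm in .DOMAIN_NAMES) {
      iv <- ann[[nm]]
      if (iv[2L] > iv[1L]) {
        writeLines(sprintf("%s\t%s\t%d\t%d", id, nm, iv[1L], iv[2L]), con)
      }
    }
  }
  invisible(path)
}
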