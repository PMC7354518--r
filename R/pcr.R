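# Degenerate-primer in-silico PCR: IUPAC matching, site finding, amplicon
# prediction, panel evaluation, and primer arithmetic (GC%, Wallace Tm).

#' Create a degenerate primer
#'
#' @param name Primer name, unique within a panel.
#' @param iupac_seq Primer sequence written 5'->3' (reverse primers 5'->3' on
#'   the minus strand, the standard convention; they are matched on the plus
#'   strand via their reverse complement).
#' @param orientation `"forward"` or `"reverse"`.
#' @param annotated_position Optional signed position annotation relative to
#'   the target start codon. Carried as documentation only and never used in
#'   matching, because anchor conventions differ between primer tables.
#' @return An object of class `primer`.
#' @export
primer <- function(name, iupac_seq, orientation = c("forward", "reverse"),
                   annotated_position = NA_integer_) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  iupac_seq <- gsub("[ \t]", "", toupper(iupac_seq))
  .check_iupac(strsplit(iupac_seq, "", fixed = TRUE)[[1L]])
  structure(list(name = name, iupac_seq = iupac_seq, orientation = orientation,
                 annotated_position = as.integer(annotated_position)),
            class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer %s %s %s (degeneracy %d)>\n", x$name, x$orientation,
              x$iupac_seq, degeneracy(x$iupac_seq)))
  invisible(x)
}

#' The kcv screening primer panel
#'
#' The four forward / four reverse degenerate primers used to screen
#' chlorovirus isolates for the kcv gene, with their annotated positions
#' relative to the start codon. Shipped as `inst/extdata/kcv_primers.tsv`.
#'
#' @return A list of [primer()] objects.
#' @export
kcv_primer_panel <- function() {
  path <- system.file("extdata", "kcv_primers.tsv", package = "kcvkit",
                      mustWork = TRUE)
  read_primer_panel(path)
}

#' Read a primer panel from TSV
#'
#' Expected columns: `name`, `sequence`, `orientation`, `position` (position
#' may be blank).
#'
#' @param path TSV file path.
#' @return A list of [primer()] objects.
#' @export
read_primer_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "orientation")
  if (!all(need %in% names(tab))) {
    stop("primer panel needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$name)) stop("duplicate primer name in panel", call. = FALSE)
  pos <- if ("position" %in% names(tab)) suppressWarnings(as.integer(tab$position)) else NA
  lapply(seq_len(nrow(tab)), function(i) {
    primer(tab$name[i], tab$sequence[i], tab$orientation[i],
           annotated_position = pos[i])
  })
}

#' Match a primer window against a template window under IUPAC semantics
#'
#' A position matches iff the (unambiguous) template base lies in the ambiguity
#' set of the primer base. Returns the mismatch count if it does not exceed
#' `max_mismatches`, otherwise `NA` (no match).
#'
#' @param primer_window Primer-length IUPAC string.
#' @param template_window Equal-length unambiguous ACGT string.
#' @param max_mismatches Maximum tolerated mismatches.
#' @return Integer mismatch count, or `NA_integer_` for no-match.
#' @export
iupac_match <- function(primer_window, template_window, max_mismatches = 0L) {
  p <- .dna_chars(primer_window)
  t <- .dna_chars(template_window)
  if (length(p) != length(t)) stop("window length mismatch", call. = FALSE)
  .check_iupac(p)
  if (any(!t %in% c("A", "C", "G", "T"))) {
    stop("template window must be unambiguous ACGT", call. = FALSE)
  }
  mm <- sum(!.iupac_base_match(p, t))
  if (mm <= max_mismatches) as.integer(mm) else NA_integer_
}

# All binding sites of `pattern` (IUPAC, plus-strand orientation already
# resolved) on a template char vector; returns data.frame(start, mismatches).
.scan_sites <- function(pattern_chars, template_chars, max_mismatches) {
  k <- length(pattern_chars)
  n <- length(template_chars)
  if (n < k) stop("template shorter than primer", call. = FALSE)
  # logical match matrix: rows = primer positions, cols = template positions
  hit <- matrix(FALSE, nrow = k, ncol = n)
  for (i in seq_len(k)) {
    hit[i, ] <- template_chars %in% .IUPAC_SETS[[pattern_chars[i]]]
  }
  starts <- integer(0); mms <- integer(0)
  for (s in seq_len(n - k + 1L)) {
    mm <- k - sum(hit[cbind(seq_len(k), s:(s + k - 1L))])
    if (mm <= max_mismatches) { starts <- c(starts, s); mms <- c(mms, mm) }
  }
  data.frame(start = starts, mismatches = mms)
}

#' Find binding sites of a primer on a template
#'
#' Forward primers are scanned as written on the plus strand; reverse primers
#' are scanned as the reverse complement of their 5'->3' sequence. All start
#' positions (1-based, plus strand) with at most `max_mismatches` IUPAC
#' mismatches are returned in ascending order.
#'
#' @param primer A [primer()].
#' @param template A DNA [seq_record()] (unambiguous).
#' @param max_mismatches Maximum mismatches per site.
#' @return Integer vector of 1-based start positions (possibly empty), with a
#'   `mismatches` attribute giving per-site mismatch counts.
#' @export
find_sites <- function(primer, template, max_mismatches = 0L) {
  stopifnot(inherits(primer, "primer"), inherits(template, "seq_record"))
  pat <- if (primer$orientation == "forward") primer$iupac_seq
         else reverse_complement(primer$iupac_seq)
  df <- .scan_sites(.dna_chars(pat), .dna_chars(template$residues), max_mismatches)
  structure(df$start, mismatches = df$mismatches)
}

#' Predict amplicons for a primer pair on one template
#'
#' Every combination of a forward site upstream of a reverse site whose product
#' length lies in `[min_len, max_len]` yields one hit. Coordinates are 1-based
#' inclusive on the plus strand; `product_length = rev_last - fwd_start + 1`.
#'
#' @param fwd,rev Forward and reverse [primer()]s.
#' @param template A DNA [seq_record()].
#' @param max_mismatches Per-primer mismatch tolerance.
#' @param min_len,max_len Product-length bounds (defaults 200-2000 nt, the
#'   range of a clean single-band screening amplicon).
#' @return data.frame with columns `template_id`, `fwd_start`, `rev_last`,
#'   `product_length`, `fwd_mismatches`, `rev_mismatches`, sorted by
#'   `fwd_start` then `product_length`.
#' @export
simulate_pcr <- function(fwd, rev, template, max_mismatches = 0L,
                         min_len = 200L, max_len = 2000L) {
  stopifnot(fwd$orientation == "forward", rev$orientation == "reverse")
  if (min_len > max_len) stop("min_len > max_len", call. = FALSE)
  fs <- find_sites(fwd, template, max_mismatches)
  rs <- find_sites(rev, template, max_mismatches)
  out <- data.frame(template_id = character(0), fwd_start = integer(0),
                    rev_last = integer(0), product_length = integer(0),
                    fwd_mismatches = integer(0), rev_mismatches = integer(0))
  if (length(fs) == 0L || length(rs) == 0L) return(out)
  rlen <- nchar(rev$iupac_seq)
  grid <- expand.grid(fi = seq_along(fs), ri = seq_along(rs))
  fwd_start <- as.integer(fs)[grid$fi]
  rev_last <- as.integer(rs)[grid$ri] + rlen - 1L
  len <- rev_last - fwd_start + 1L
  keep <- fwd_start <= (as.integer(rs)[grid$ri]) & len >= min_len & len <= max_len &
    fwd_start + nchar(fwd$iupac_seq) - 1L < as.integer(rs)[grid$ri]
  if (!any(keep)) return(out)
  hits <- data.frame(
    template_id = template$id,
    fwd_start = fwd_start[keep],
    rev_last = rev_last[keep],
    product_length = len[keep],
    fwd_mismatches = attr(fs, "mismatches")[grid$fi][keep],
    rev_mismatches = attr(rs, "mismatches")[grid$ri][keep]
  )
  hits[order(hits$fwd_start, hits$product_length), , drop = FALSE]
}

#' Evaluate every forward/reverse primer pair against a template panel
#'
#' Mirrors an in-silico wet screen: for each pair, records which templates
#' yield at least one amplicon and whether the pair amplifies all of them.
#'
#' @param fwd_primers,rev_primers Non-empty lists of [primer()]s.
#' @param templates Non-empty list of DNA [seq_record()]s.
#' @param max_mismatches,min_len,max_len Passed to [simulate_pcr()].
#' @return An object of class `panel_report`: data.frame with one row per
#'   pair (`fwd`, `rev`, `n_amplified`, `covers_all`) plus a logical
#'   `matrix` attribute (pair x template).
#' @export
evaluate_panel <- function(fwd_primers, rev_primers, templates,
                           max_mismatches = 0L, min_len = 200L, max_len = 2000L) {
  if (length(fwd_primers) == 0L || length(rev_primers) == 0L) {
    stop("empty primer panel", call. = FALSE)
  }
  if (length(templates) == 0L) stop("empty template list", call. = FALSE)
  tids <- vapply(templates, `[[`, character(1), "id")
  pairs <- expand.grid(fi = seq_along(fwd_primers), ri = seq_along(rev_primers))
  amp <- matrix(FALSE, nrow = nrow(pairs), ncol = length(templates),
                dimnames = list(NULL, tids))
  for (p in seq_len(nrow(pairs))) {
    for (t in seq_along(templates)) {
      hits <- simulate_pcr(fwd_primers[[pairs$fi[p]]], rev_primers[[pairs$ri[p]]],
                           templates[[t]], max_mismatches, min_len, max_len)
      amp[p, t] <- nrow(hits) > 0L
    }
  }
  rep <- data.frame(
    fwd = vapply(fwd_primers, `[[`, character(1), "name")[pairs$fi],
    rev = vapply(rev_primers, `[[`, character(1), "name")[pairs$ri],
    n_amplified = rowSums(amp),
    covers_all = rowSums(amp) == length(templates)
  )
  structure(rep, matrix = amp, class = c("panel_report", "data.frame"))
}

#' Write a panel report as a TSV matrix
#'
#' One row per primer pair, one column per template (TRUE/FALSE), plus a
#' `covers_all` column.
#'
#' @param report A `panel_report` from [evaluate_panel()].
#' @param path Output path.
#' @export
write_panel_report <- function(report, path) {
  m <- attr(report, "matrix")
  out <- cbind(data.frame(fwd = report$fwd, rev = report$rev),
               as.data.frame(m), covers_all = report$covers_all)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' GC content of a degenerate primer
#'
#' `unambiguous_only` counts G/C only among non-degenerate positions but
#' divides by the full primer length (the convention that reproduces published
#' GC percentages for this primer panel's fully resolved rows). `expected`
#' averages the per-position probability of G or C under a uniform draw within
#' each ambiguity set.
#'
#' @param primer A [primer()].
#' @param mode `"unambiguous_only"` or `"expected"`.
#' @return GC percentage rounded to the nearest integer.
#' @export
gc_content <- function(primer, mode = c("unambiguous_only", "expected")) {
  mode <- match.arg(mode)
  chars <- .dna_chars(primer$iupac_seq)
  sets <- .IUPAC_SETS[chars]
  if (mode == "unambiguous_only") {
    gc <- sum(vapply(sets, function(s) length(s) == 1L && s %in% c("G", "C"),
                     logical(1)))
  } else {
    gc <- sum(vapply(sets, function(s) mean(s %in% c("G", "C")), numeric(1)))
  }
  round(100 * gc / length(chars))
}

#' Wallace-rule melting temperature of a degenerate primer
#'
#' Tm = 2(#A + #T) + 4(#G + #C) degrees C, evaluated over a concrete
#' realization of the degenerate sequence: the minimum-GC realization
#' (`"min"`), the maximum-GC realization (`"max"`), or expected base counts
#' under uniform draws (`"expected"`). A rule of thumb for short oligos only.
#'
#' @param primer A [primer()].
#' @param mode `"min"`, `"max"` or `"expected"`.
#' @return Temperature in degrees C (not rounded).
#' @export
wallace_tm <- function(primer, mode = c("min", "max", "expected")) {
  mode <- match.arg(mode)
  chars <- .dna_chars(primer$iupac_seq)
  sets <- .IUPAC_SETS[chars]
  L <- length(chars)
  gc <- switch(mode,
    min = sum(vapply(sets, function(s) all(s %in% c("G", "C")), logical(1))),
    max = sum(vapply(sets, function(s) any(s %in% c("G", "C")), logical(1))),
    expected = sum(vapply(sets, function(s) mean(s %in% c("G", "C")), numeric(1)))
  )
  # Tm = 2*(A+T) + 4*(G+C) = 2*L + 2*(G+C)
  2 * L + 2 * gc
}
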