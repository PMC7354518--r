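# Seeded generator of kcv-like gene families with known ground truth:
# a 249-nt ancestral CDS (82 aa + stop) carrying the TTVGYGDL filter,
# domain-structured substitution rates, duplicate isolate clusters,
# C-terminal extensions, one turret-insertion lineage, and primer-compatible
# flanks, so that every pipeline stage can be tested without real data.

.sense_codons <- function() {
  gc <- genetic_code_table()
  names(gc)[gc != "*"]
}

# codons encoding each amino acid
.codons_for <- function(aa) {
  gc <- genetic_code_table()
  names(gc)[gc == aa]
}

#' Configuration of a synthetic kcv-like family
#'
#' The defaults state a family shaped like the published survey panel:
#' 103 isolates over 42 distinct DNA haplotypes (duplicate clusters of 20 and
#' 9, twelve clusters of 3, ten of 2, eighteen singletons), 16 of the
#' haplotypes differing only synonymously from another (so 26 distinct
#' proteins), one lineage with a 24-nt in-frame turret insertion (89-aa
#' protein), four with +6-nt and two with +9-nt C-terminal extensions
#' (84/85-aa proteins). Substitution pressure is domain-structured:
#' filter < pore helix = turret < TMD1 = TMD2.
#'
#' @param n_isolates Total isolates.
#' @param multiplicities Integer vector of haplotype multiplicities; its
#'   length is the number of distinct DNA lineages and it must sum to
#'   `n_isolates`.
#' @param n_synonymous Number of lineages that are synonymous twins of
#'   another lineage (distinct DNA, identical protein).
#' @param domain_probs Named per-site substitution probabilities for
#'   `TMD1`, `turret`, `pore_helix`, `filter`, `TMD2`, `c_tail`, `other`
#'   (residues outside any domain).
#' @param n_turret_insertion Lineages carrying the 24-nt turret insertion.
#' @param n_cterm6,n_cterm9 Lineages with 6-nt / 9-nt C-terminal extensions.
#' @param flank_up,flank_down Flank lengths (nt) around the CDS.
#' @param preserve_motif Restrict filter codons to synonymous changes.
#' @param seed Integer RNG seed.
#' @return Object of class `family_config`.
#' @export
family_config <- function(n_isolates = 103L,
                          multiplicities = c(20L, 9L, rep(3L, 12L),
                                             rep(2L, 10L), rep(1L, 18L)),
                          n_synonymous = 16L,
                          domain_probs = c(TMD1 = 0.08, turret = 0.03,
                                           pore_helix = 0.03, filter = 0.01,
                                           TMD2 = 0.08, c_tail = 0.04,
                                           other = 0.04),
                          n_turret_insertion = 1L, n_cterm6 = 4L, n_cterm9 = 2L,
                          flank_up = 400L, flank_down = 300L,
                          preserve_motif = TRUE, seed = 1L) {
  multiplicities <- as.integer(multiplicities)
  if (sum(multiplicities) != n_isolates) {
    stop("multiplicities must sum to n_isolates", call. = FALSE)
  }
  if (any(multiplicities < 1L)) stop("multiplicities must be >= 1", call. = FALSE)
  n_lineages <- length(multiplicities)
  if (n_synonymous >= n_lineages) stop("too many synonymous lineages", call. = FALSE)
  n_protein <- n_lineages - n_synonymous
  if (n_turret_insertion + n_cterm6 + n_cterm9 >= n_protein) {
    stop("more indel lineages than protein lineages", call. = FALSE)
  }
  stopifnot(all(domain_probs >= 0), all(domain_probs <= 1))
  structure(list(n_isolates = as.integer(n_isolates),
                 multiplicities = multiplicities,
                 n_lineages = n_lineages, n_synonymous = as.integer(n_synonymous),
                 domain_probs = domain_probs,
                 n_turret_insertion = as.integer(n_turret_insertion),
                 n_cterm6 = as.integer(n_cterm6), n_cterm9 = as.integer(n_cterm9),
                 flank_up = as.integer(flank_up), flank_down = as.integer(flank_down),
                 preserve_motif = preserve_motif, seed = as.integer(seed)),
            class = "family_config")
}

# random in-frame codon string of n_codons sense codons
.random_codons <- function(n_codons) {
  paste(sample(.sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# ancestral 249-nt CDS: ATG start, TTVGYGDL filter at residues 50-57, TAA stop
.ancestral_cds <- function(annotation = default_domain_annotation()) {
  codons <- sample(.sense_codons(), 82L, replace = TRUE)
  codons[1L] <- "ATG"
  filt <- strsplit("TTVGYGDL", "")[[1L]]
  fs <- annotation$filter[1L]
  for (k in seq_along(filt)) {
    codons[fs + k - 1L] <- sample(.codons_for(filt[k]), 1L)
  }
  paste(c(codons, "TAA"), collapse = "")
}

#' Mutate a CDS with domain-specific substitution probabilities
#'
#' Per-nucleotide substitution at the probability of the domain its codon
#' falls in; the start and stop codons are never touched, and with
#' `preserve_motif` the filter codons admit only synonymous codon swaps (at
#' the filter's per-codon probability), so the translated filter motif is
#' invariant. Draws from the current RNG stream.
#'
#' @param cds A DNA [seq_record()] (in-frame CDS incl. stop).
#' @param annotation Protein-coordinate [domain_annotation()] mapping codons
#'   to domains.
#' @param probs Named per-site probabilities (see [family_config()]).
#' @param preserve_motif Keep the filter motif invariant at protein level.
#' @return A DNA [seq_record()] with the same id, mutated residues.
#' @export
mutate_cds <- function(cds, annotation = default_domain_annotation(),
                       probs = family_config()$domain_probs,
                       preserve_motif = TRUE) {
  chars <- .dna_chars(cds$residues)
  n <- length(chars)
  stopifnot(n %% 3L == 0L)
  n_codons <- n %/% 3L
  aa_dom <- .residue_domains(annotation, n_codons - 1L)
  aa_dom[aa_dom == ""] <- "other"
  site_dom <- rep(c(aa_dom, "stop"), each = 3L)
  p <- ifelse(site_dom == "stop", 0, probs[site_dom])
  p[1:3] <- 0  # keep the start codon
  filter_sites <- site_dom == "filter"
  if (preserve_motif) p[filter_sites] <- 0
  hit <- stats::runif(n) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  out <- paste(chars, collapse = "")
  if (preserve_motif) {
    # synonymous swaps inside the filter, one codon at a time
    fs <- annotation$filter
    for (ci in fs[1L]:(fs[2L] - 1L)) {
      if (stats::runif(1) < probs["filter"]) {
        cod <- substr(out, 3L * ci - 2L, 3L * ci)
        syn <- setdiff(.codons_for(genetic_code_table()[[cod]]), cod)
        if (length(syn) > 0L) {
          substr(out, 3L * ci - 2L, 3L * ci) <- sample(syn, 1L)
        }
      }
    }
  }
  seq_record(cds$id, out, alphabet = "dna_iupac", description = cds$description)
}

# apply >= 1 synonymous codon change anywhere except start/stop; returns string
.synonymous_variant <- function(cds_str, rate = 0.03) {
  n_codons <- nchar(cds_str) %/% 3L
  repeat {
    out <- cds_str
    changed <- FALSE
    for (ci in 2L:(n_codons - 1L)) {
      if (stats::runif(1) < rate) {
        cod <- substr(out, 3L * ci - 2L, 3L * ci)
        syn <- setdiff(.codons_for(genetic_code_table()[[cod]]), cod)
        if (length(syn) > 0L) {
          substr(out, 3L * ci - 2L, 3L * ci) <- sample(syn, 1L)
          changed <- TRUE
        }
      }
    }
    if (changed && out != cds_str) return(out)
  }
}

# insert `n_nt` random stop-free in-frame nucleotides after codon `after`
.insert_codons <- function(cds_str, after, n_nt) {
  stopifnot(n_nt %% 3L == 0L)
  ins <- paste(sample(.sense_codons(), n_nt %/% 3L, replace = TRUE), collapse = "")
  paste0(substr(cds_str, 1L, 3L * after), ins,
         substr(cds_str, 3L * after + 1L, nchar(cds_str)))
}

#' Generate a synthetic kcv-like gene family with ground truth
#'
#' Deterministic under the config seed. The returned isolates carry the CDS
#' alone (`cds`) and with primer-compatible flanks (`flanked`): every isolate
#' has one Kcv9 forward-primer site planted in the upstream flank and one Kcv6
#' reverse-primer site in the downstream flank, each drawn from the primer's
#' expansion set, so the standard Kcv9/Kcv6 pair amplifies the whole family.
#'
#' @param config A [family_config()].
#' @return List with `cds` (list of [seq_record()]), `flanked` (ditto),
#'   and `truth`, a ground-truth list: `ancestral`, `n_unique_dna`,
#'   `n_unique_protein`, `group_sizes` (sorted multiplicities),
#'   `length_histogram`, `motif_classes`, `lineage_of_isolate`,
#'   `lineage_cds`, `fwd_site`, `rev_site` (planted plus-strand positions on
#'   the flanked template).
#' @export
generate_family <- function(config = family_config()) {
  stopifnot(inherits(config, "family_config"))
  set.seed(config$seed)
  ann <- default_domain_annotation()
  anc <- .ancestral_cds(ann)
  n_prot <- config$n_lineages - config$n_synonymous
  # which protein lineages carry indels (placed at the end of the block)
  idx_turret <- if (config$n_turret_insertion > 0L)
    (n_prot - config$n_turret_insertion + 1L):n_prot else integer(0)
  idx_c9 <- if (config$n_cterm9 > 0L)
    (n_prot - config$n_turret_insertion - config$n_cterm9 + 1L):
      (n_prot - config$n_turret_insertion) else integer(0)
  idx_c6 <- if (config$n_cterm6 > 0L)
    (n_prot - config$n_turret_insertion - config$n_cterm9 - config$n_cterm6 + 1L):
      (n_prot - config$n_turret_insertion - config$n_cterm9) else integer(0)
  lineage_cds <- character(config$n_lineages)
  lineage_cds[1L] <- anc
  anc_rec <- seq_record("ancestor", anc)
  protein_of <- function(s) translate_cds(seq_record("x", s), TRUE)$residues
  # mutation can create an internal stop; such candidates are rejected
  protein_or_null <- function(s) tryCatch(protein_of(s), error = function(e) NULL)
  for (i in seq_len(n_prot)[-1L]) {
    for (attempt in 1:100) {
      cand <- mutate_cds(anc_rec, ann, config$domain_probs,
                         config$preserve_motif)$residues
      if (i %in% idx_turret) {
        # in-frame insertion inside the turret (after codon 32)
        cand <- .insert_codons(cand, 32L, 24L)
      } else if (i %in% idx_c9) {
        cand <- .insert_codons(cand, nchar(cand) %/% 3L - 1L, 9L)
      } else if (i %in% idx_c6) {
        cand <- .insert_codons(cand, nchar(cand) %/% 3L - 1L, 6L)
      }
      cand_prot <- protein_or_null(cand)
      if (!is.null(cand_prot)) {
        prots <- vapply(lineage_cds[seq_len(i - 1L)], protein_of, character(1))
        if (!cand %in% lineage_cds[seq_len(i - 1L)] && !cand_prot %in% prots) {
          lineage_cds[i] <- cand
          break
        }
      }
      if (attempt == 100L) stop("could not generate distinct lineage", call. = FALSE)
    }
  }
  # synonymous twins: distinct DNA, protein identical to a source lineage
  if (config$n_synonymous > 0L) {
    sources <- sample(seq_len(n_prot), config$n_synonymous, replace = TRUE)
    for (k in seq_len(config$n_synonymous)) {
      i <- n_prot + k
      for (attempt in 1:100) {
        cand <- .synonymous_variant(lineage_cds[sources[k]])
        if (!cand %in% lineage_cds[seq_len(i - 1L)]) {
          lineage_cds[i] <- cand
          break
        }
        if (attempt == 100L) stop("could not generate distinct twin", call. = FALSE)
      }
    }
  }
  stopifnot(!anyDuplicated(lineage_cds))
  prots <- vapply(lineage_cds, protein_of, character(1), USE.NAMES = FALSE)
  n_unique_protein <- length(unique(prots))
  stopifnot(n_unique_protein == n_prot)
  # isolates: assign lineages by multiplicity, shuffled
  lineage_of_isolate <- sample(rep(seq_len(config$n_lineages),
                                   config$multiplicities))
  ids <- sprintf("SAG%03d", seq_len(config$n_isolates))
  # primer sites planted at fixed flank offsets
  panel <- kcv_primer_panel()
  pick <- function(nm) Filter(function(p) p$name == nm, panel)[[1L]]
  fwd <- pick("Kcv9_Frw"); rev <- pick("Kcv6_Rvs")
  fwd_exp <- expand_iupac(fwd$iupac_seq)
  rev_exp <- expand_iupac(rev$iupac_seq)
  fwd_pos <- config$flank_up - 376L + 1L
  stopifnot(fwd_pos >= 1L, fwd_pos + nchar(fwd$iupac_seq) <= config$flank_up)
  rev_last_flank <- min(256L, config$flank_down)
  cds <- vector("list", config$n_isolates)
  flanked <- vector("list", config$n_isolates)
  rev_site <- integer(config$n_isolates)
  for (n in seq_len(config$n_isolates)) {
    s <- lineage_cds[lineage_of_isolate[n]]
    up <- paste(sample(c("A", "C", "G", "T"), config$flank_up, replace = TRUE),
                collapse = "")
    down <- paste(sample(c("A", "C", "G", "T"), config$flank_down, replace = TRUE),
                  collapse = "")
    substr(up, fwd_pos, fwd_pos + nchar(fwd$iupac_seq) - 1L) <-
      sample(fwd_exp, 1L)
    rc <- reverse_complement(sample(rev_exp, 1L))
    substr(down, rev_last_flank - nchar(rc) + 1L, rev_last_flank) <- rc
    cds[[n]] <- seq_record(ids[n], s, description = "synthetic kcv CDS")
    flanked[[n]] <- seq_record(ids[n], paste0(up, s, down),
                               description = "synthetic kcv CDS with flanks")
    rev_site[n] <- config$flank_up + nchar(s) + rev_last_flank - nchar(rc) + 1L
  }
  uprot <- unique(prots)
  motif <- vapply(uprot, function(p) {
    cl <- classify_filter_motif(seq_record("x", p, alphabet = "protein"))
    if (cl$found) cl$motif else "none"
  }, character(1), USE.NAMES = FALSE)
  truth <- list(
    ancestral = anc,
    n_unique_dna = config$n_lineages,
    n_unique_protein = n_unique_protein,
    group_sizes = sort(config$multiplicities, decreasing = TRUE),
    length_histogram = {
      tab <- table(nchar(uprot))
      stats::setNames(as.integer(tab), names(tab))
    },
    motif_classes = c(table(motif)),
    lineage_of_isolate = stats::setNames(lineage_of_isolate, ids),
    lineage_cds = lineage_cds,
    fwd_site = fwd_pos,
    rev_site = stats::setNames(rev_site, ids)
  )
  list(cds = cds, flanked = flanked, truth = truth)
}

#' Write a generated family to disk
#'
#' Emits `<stem>_cds.fasta`, `<stem>_flanked.fasta` and a JSON ground-truth
#' sidecar `<stem>_truth.json`.
#'
#' @param family Result of [generate_family()].
#' @param stem Output path stem.
#' @export
write_family <- function(family, stem) {
  write_fasta(family$cds, paste0(stem, "_cds.fasta"))
  write_fasta(family$flanked, paste0(stem, "_flanked.fasta"))
  tr <- family$truth
  tr$lineage_of_isolate <- as.list(tr$lineage_of_isolate)
  tr$length_histogram <- as.list(tr$length_histogram)
  tr$motif_classes <- as.list(tr$motif_classes)
  tr$rev_site <- as.list(tr$rev_site)
  jsonlite::write_json(tr, paste0(stem, "_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}
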