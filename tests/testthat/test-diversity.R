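test_that("collapse_unique groups by exact identity with correct ordering", {
  seqs <- list(seq_record("a", "AAA"), seq_record("b", "AAA"), seq_record("c", "AAC"))
  g <- collapse_unique(seqs)
  expect_length(g, 2L)
  expect_equal(vapply(g, `[[`, integer(1), "count"), c(2L, 1L))
  expect_equal(g[[1]]$member_ids, c("a", "b"))
  expect_equal(g[[1]]$representative$id, "a")
  # all distinct
  g2 <- collapse_unique(list(seq_record("a", "AA"), seq_record("b", "AC")))
  expect_equal(vapply(g2, `[[`, integer(1), "count"), c(1L, 1L))
  expect_error(collapse_unique(list()), "empty")
  expect_error(collapse_unique(list(seq_record("a", "A-A", allow_gap = TRUE))),
               "gapped")
})

test_that("collapse is idempotent and counts are conserved", {
  set.seed(41)
  pool <- replicate(6, random_dna(30))
  seqs <- lapply(1:40, function(i) seq_record(paste0("s", i), sample(pool, 1)))
  g <- collapse_unique(seqs)
  expect_equal(sum(vapply(g, `[[`, integer(1), "count")), 40L)
  reps <- lapply(g, `[[`, "representative")
  g2 <- collapse_unique(reps)
  expect_equal(length(g2), length(g))
  expect_true(all(vapply(g2, `[[`, integer(1), "count") == 1L))
  expect_setequal(vapply(g2, function(x) x$representative$residues, character(1)),
                  vapply(g, function(x) x$representative$residues, character(1)))
})

test_that("variable_sites partitions columns", {
  m <- multiple_alignment(c("a", "b", "c"), c("ACGTAC", "ACGTAC", "ACGTAC"),
                          "dna_iupac")
  expect_equal(variable_sites(m), list(variable_count = 0L, n_columns = 6L))
  m2 <- multiple_alignment(c("a", "b"), c("ACGTAC", "TCGAAG"), "dna_iupac")
  expect_equal(variable_sites(m2)$variable_count, 3L)
})

test_that("pairwise_differences counts alignment columns incl. gap columns", {
  a <- seq_record("a", "MKTAYIAKQR", "protein")
  self <- pairwise_differences(a, a)
  expect_equal(self$diff_count, 0)
  expect_equal(self$percent, 0)
  b <- seq_record("b", "MKTAYIVKQR", "protein")
  d <- pairwise_differences(a, b)
  expect_equal(d$diff_count, 1)
  expect_equal(d$alignment_length, 10)
  expect_equal(d$percent, 10)
  expect_equal(pairwise_differences(b, a)$diff_count, 1)
  # 3-residue insertion counts 3 differences and stretches the denominator
  c_ <- seq_record("c", "MKTAYWWWIAKQR", "protein")
  d2 <- pairwise_differences(a, c_)
  expect_equal(d2$diff_count, 3)
  expect_equal(d2$alignment_length, 13)
})

test_that("length_histogram sums to input size", {
  prots <- list(seq_record("a", strrep("M", 82), "protein"),
                seq_record("b", strrep("M", 82), "protein"),
                seq_record("c", strrep("M", 89), "protein"))
  h <- length_histogram(prots)
  expect_equal(h, c(`82` = 2L, `89` = 1L))
  expect_equal(length_histogram(list()), integer(0))
})

test_that("classify_filter_motif finds the canonical octapeptide classes", {
  for (motif in c("TTVGYGDL", "TTTGYGDL", "TTTGFGDV")) {
    p <- seq_record("p", paste0("MAAAA", motif, "WWWW"), "protein")
    cl <- classify_filter_motif(p)
    expect_true(cl$found)
    expect_equal(cl$motif, motif)
    expect_equal(cl$start, 6L)
  }
  none <- classify_filter_motif(seq_record("q", strrep("A", 40), "protein"))
  expect_false(none$found)
  expect_true(is.na(none$motif))
})

ref_protein <- function() {
  set.seed(42)
  fam <- generate_family(small_family_config(seed = 42))
  translate_cds(seq_record("ref", fam$truth$ancestral), strip_terminal_stop = TRUE)
}

test_that("annotate_domains transfers, re-anchors, and absorbs insertions", {
  ref <- ref_protein()
  ann <- default_domain_annotation()
  self <- annotate_domains(ref, ref, ann)
  expect_equal(unclass(self), unclass(ann))
  # 8 residues inserted mid-turret -> turret 8 longer, other lengths unchanged
  s <- ref$residues
  ins_at <- 32L  # inside the turret (26-39)
  q <- seq_record("q", paste0(substr(s, 1, ins_at), "GSGSGSGS",
                              substr(s, ins_at + 1, nchar(s))), "protein")
  qa <- annotate_domains(q, ref, ann)
  width <- function(a, nm) diff(a[[nm]])
  expect_equal(width(qa, "turret"), width(ann, "turret") + 8L)
  for (nm in c("TMD1", "pore_helix", "filter", "TMD2", "c_tail")) {
    expect_equal(width(qa, nm), width(ann, nm), info = nm)
  }
  # 3 extra C-terminal residues -> c_tail grows by 3
  q2 <- seq_record("q2", paste0(s, "GSG"), "protein")
  qa2 <- annotate_domains(q2, ref, ann)
  expect_equal(width(qa2, "c_tail"), width(ann, "c_tail") + 3L)
  expect_equal(width(qa2, "turret"), width(ann, "turret"))
  expect_error(annotate_domains(seq_record("x", strrep("A", 50), "protein"), ref),
               "motif")
})

test_that("per_domain_conservation ranks mutated domains below the filter", {
  ref <- ref_protein()
  ann <- default_domain_annotation()
  ids <- paste0("v", 1:6)
  rows <- vapply(1:6, function(i) ref$residues, character(1))
  m_ident <- multiple_alignment(c("ref", ids), c(ref$residues, rows), "protein")
  cons <- per_domain_conservation(m_ident, "ref", ann)
  expect_true(all(cons[!is.na(cons)] == 1))
  expect_true(is.na(cons["slide_helix"]))  # empty domain reported absent
  # mutate only inside the TMDs
  set.seed(43)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  tmd_cols <- c(ann$TMD1[1]:(ann$TMD1[2] - 1), ann$TMD2[1]:(ann$TMD2[2] - 1))
  rows2 <- vapply(1:6, function(i) {
    ch <- strsplit(ref$residues, "")[[1]]
    at <- sample(tmd_cols, 8)
    ch[at] <- sample(aas, 8, TRUE)
    paste(ch, collapse = "")
  }, character(1))
  m_mut <- multiple_alignment(c("ref", ids), c(ref$residues, rows2), "protein")
  cons2 <- per_domain_conservation(m_mut, "ref", ann)
  expect_equal(cons2[["filter"]], 1)
  expect_true(cons2[["filter"]] > cons2[["TMD1"]])
  expect_true(cons2[["filter"]] > cons2[["TMD2"]])
  expect_equal(cons2[["turret"]], 1)
})

test_that("diversity_report invariants hold on a synthetic family", {
  set.seed(44)
  fam <- generate_family(small_family_config(seed = 44))
  rep <- diversity_report(fam$cds)
  expect_true(rep$n_unique_protein <= rep$n_unique_dna)
  expect_true(rep$n_unique_dna <= rep$n_input)
  expect_equal(sum(rep$length_histogram), rep$n_unique_protein)
  expect_equal(sum(vapply(rep$protein_groups, `[[`, integer(1), "count")),
               rep$n_input)
  self_row <- rep$diff_table[rep$diff_table$id == rep$reference_id, ]
  expect_equal(self_row$diff_count, 0)
  path <- withr::local_tempfile()
  write_diversity_report(rep, path)
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js$n_unique_dna, rep$n_unique_dna)
  expect_equal(js$n_unique_protein, rep$n_unique_protein)
})

test_that("reannotate_start trims N-terminal extensions to an internal Met", {
  # 5-residue extension in front of an internal M restoring length 9
  p <- seq_record("x", "AAAAAMKTAYIAKQ", "protein")
  trimmed <- reannotate_start(p, 9L)
  expect_equal(trimmed$residues, "MKTAYIAKQ")
  # wrong offset residue -> unchanged
  p2 <- seq_record("y", "AAAAAWKTAYIAKQ", "protein")
  expect_equal(reannotate_start(p2, 9L)$residues, p2$residues)
  # already at target length -> unchanged
  expect_equal(reannotate_start(trimmed, 9L)$residues, trimmed$residues)
})
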