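test_that("generate_family is deterministic under seed", {
  f1 <- generate_family(small_family_config(seed = 61))
  f2 <- generate_family(small_family_config(seed = 61))
  expect_identical(lapply(f1$cds, `[[`, "residues"),
                   lapply(f2$cds, `[[`, "residues"))
  expect_identical(lapply(f1$flanked, `[[`, "residues"),
                   lapply(f2$flanked, `[[`, "residues"))
  expect_identical(f1$truth, f2$truth)
  f3 <- generate_family(small_family_config(seed = 62))
  expect_false(identical(lapply(f1$cds, `[[`, "residues"),
                         lapply(f3$cds, `[[`, "residues")))
})

test_that("degenerate configs collapse to the planted structure", {
  # all substitution probabilities 0, no indels, no twins -> 1 unique haplotype
  cfg <- family_config(n_isolates = 10L, multiplicities = c(10L),
                       n_synonymous = 0L,
                       domain_probs = c(TMD1 = 0, turret = 0, pore_helix = 0,
                                        filter = 0, TMD2 = 0, c_tail = 0, other = 0),
                       n_turret_insertion = 0L, n_cterm6 = 0L, n_cterm9 = 0L,
                       seed = 63)
  fam <- generate_family(cfg)
  g <- collapse_unique(fam$cds)
  expect_length(g, 1L)
  expect_equal(g[[1]]$count, 10L)
  # a planted duplicate cluster of 20 shows up as a group of 20
  cfg2 <- family_config(n_isolates = 26L, multiplicities = c(20L, rep(1L, 6L)),
                        n_synonymous = 2L, n_turret_insertion = 1L,
                        n_cterm6 = 1L, n_cterm9 = 1L, seed = 64)
  g2 <- collapse_unique(generate_family(cfg2)$cds)
  expect_equal(g2[[1]]$count, 20L)
})

test_that("invalid configs are rejected", {
  expect_error(family_config(n_isolates = 10L, multiplicities = c(5L, 4L)),
               "sum")
  expect_error(family_config(n_isolates = 4L, multiplicities = rep(1L, 4L),
                             n_synonymous = 4L), "synonymous")
})

test_that("the ancestral CDS states the expected world", {
  fam <- generate_family(small_family_config(seed = 65))
  anc <- fam$truth$ancestral
  expect_equal(nchar(anc), 249L)
  expect_equal(substr(anc, 1, 3), "ATG")
  prot <- translate_cds(seq_record("a", anc), TRUE)
  cl <- classify_filter_motif(prot)
  expect_equal(cl$motif, "TTVGYGDL")
  expect_equal(cl$start, default_domain_annotation()$filter[1])
})

test_that("mutate_cds: identity at p=0, motif preserved, stop intact", {
  fam <- generate_family(small_family_config(seed = 66))
  anc <- seq_record("anc", fam$truth$ancestral)
  p0 <- c(TMD1 = 0, turret = 0, pore_helix = 0, filter = 0, TMD2 = 0,
          c_tail = 0, other = 0)
  expect_equal(mutate_cds(anc, probs = p0)$residues, anc$residues)
  # probability 1 in TMD1 only, motif preserved
  p1 <- p0; p1["TMD1"] <- 1
  set.seed(67)
  mut <- mutate_cds(anc, probs = p1, preserve_motif = TRUE)
  mp <- tryCatch(translate_cds(mut, TRUE), error = function(e) NULL)
  if (!is.null(mp)) {  # internal stop is possible at p=1; motif check if not
    expect_equal(classify_filter_motif(mp)$motif, "TTVGYGDL")
  }
  expect_equal(substr(mut$residues, 247, 249), substr(anc$residues, 247, 249))
  expect_equal(substr(mut$residues, 1, 3), "ATG")
  # untouched outside TMD1
  ann <- default_domain_annotation()
  tmd1_nt <- (3 * (ann$TMD1[1] - 1) + 1):(3 * (ann$TMD1[2] - 1))
  outside <- setdiff(seq_len(249), tmd1_nt)
  a_ch <- strsplit(anc$residues, "")[[1]]
  m_ch <- strsplit(mut$residues, "")[[1]]
  expect_equal(m_ch[outside], a_ch[outside])
  expect_true(all(m_ch[tmd1_nt] != a_ch[tmd1_nt]))
})

test_that("per-domain substitution counts match their binomial expectation", {
  fam <- generate_family(small_family_config(seed = 68))
  anc <- seq_record("anc", fam$truth$ancestral)
  ann <- default_domain_annotation()
  probs <- c(TMD1 = 0.10, turret = 0.02, pore_helix = 0.02, filter = 0,
             TMD2 = 0.10, c_tail = 0.02, other = 0.02)
  tmd1_nt <- (3 * (ann$TMD1[1] - 1) + 1):(3 * (ann$TMD1[2] - 1))
  set.seed(69)
  n_rep <- 200
  hits <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    mut <- mutate_cds(anc, probs = probs)
    hits[k] <- sum(strsplit(mut$residues, "")[[1]][tmd1_nt] !=
                     strsplit(anc$residues, "")[[1]][tmd1_nt])
  }
  L <- length(tmd1_nt)
  expected <- 0.10 * L
  se <- sqrt(L * 0.10 * 0.90 / n_rep)
  expect_lt(abs(mean(hits) - expected), 4 * se)
})

test_that("pipeline output equals generator ground truth on the default config", {
  fam <- generate_family(family_config(seed = 70))
  truth <- fam$truth
  rep <- diversity_report(fam$cds)
  expect_equal(rep$n_input, 103L)
  expect_equal(rep$n_unique_dna, truth$n_unique_dna)
  expect_equal(rep$n_unique_protein, truth$n_unique_protein)
  expect_equal(sort(vapply(rep$dna_groups, `[[`, integer(1), "count"),
                    decreasing = TRUE), as.integer(truth$group_sizes))
  hist <- rep$length_histogram
  expect_equal(hist[names(truth$length_histogram)],
               truth$length_histogram)
  expect_equal(c(rep$motif_classes[names(truth$motif_classes)]),
               truth$motif_classes)
})

test_that("write_family emits fasta pair plus JSON sidecar", {
  fam <- generate_family(small_family_config(seed = 71))
  stem <- withr::local_tempfile()
  write_family(fam, stem)
  cds <- read_fasta(paste0(stem, "_cds.fasta"))
  expect_length(cds, length(fam$cds))
  js <- jsonlite::read_json(paste0(stem, "_truth.json"))
  expect_equal(js$n_unique_dna, fam$truth$n_unique_dna)
})
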