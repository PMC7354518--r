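test_that("p_distance_matrix ignores gap columns and matches a direct scan", {
  m <- multiple_alignment(c("a", "b", "c"),
                          c("ACGTACGTAC", "ACGTACGTAC", "TCGTACGAAC"), "dna_iupac")
  D <- p_distance_matrix(m)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.2)
  set.seed(51)
  rows <- vapply(1:4, function(i) {
    ch <- sample(c("A", "C", "G", "T", "-"), 30, TRUE, prob = c(rep(0.22, 4), 0.12))
    paste(ch, collapse = "")
  }, character(1))
  m2 <- multiple_alignment(paste0("t", 1:4), rows, "dna_iupac")
  D2 <- p_distance_matrix(m2)
  cm <- do.call(rbind, strsplit(rows, ""))
  for (i in 1:3) for (j in (i + 1):4) {
    ok <- cm[i, ] != "-" & cm[j, ] != "-"
    expect_equal(D2[i, j], sum(cm[i, ok] != cm[j, ok]) / sum(ok))
  }
  expect_equal(D2, t(D2))
  expect_error(p_distance_matrix(multiple_alignment(c("a", "b"), c("AC", "AC"),
                                                    "dna_iupac")), "at least 3")
})

test_that("neighbor_joining: 3-taxon closed form and additive 4-taxon recovery", {
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(D3)
  pl <- tree_path_lengths(t3)
  expect_equal(pl[rownames(D3), colnames(D3)], D3)
  # additive 4-taxon metric from tree ((A:2,B:3):1,(C:4,D:5))
  D4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D4["A", "B"] <- 5; D4["A", "C"] <- 7; D4["A", "D"] <- 8
  D4["B", "C"] <- 8; D4["B", "D"] <- 9; D4["C", "D"] <- 9
  D4 <- D4 + t(D4)
  t4 <- neighbor_joining(D4)
  expect_equal(tree_path_lengths(t4)[rownames(D4), colnames(D4)], D4)
  expect_true(is_monophyletic(t4, c("A", "B")))
  expect_true(is_monophyletic(t4, c("C", "D")))
  expect_false(is_monophyletic(t4, c("A", "C")))
  expect_error(neighbor_joining(D4[1:2, 1:2]), "at least 3")
})

test_that("NJ reproduces random additive metrics exactly (n <= 8, ape oracle)", {
  skip_if_not_installed("ape")
  set.seed(52)
  for (n in c(4, 5, 6, 8)) {
    for (rep in 1:5) {
      tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
      D <- ape::cophenetic.phylo(tr)
      D <- D[order(rownames(D)), order(colnames(D))]
      nj <- neighbor_joining(D)
      pl <- tree_path_lengths(nj)
      expect_lt(max(abs(pl[rownames(D), colnames(D)] - D)), 1e-9)
    }
  }
})

test_that("branch lengths are nonnegative after clamping on noisy matrices", {
  set.seed(53)
  for (rep in 1:5) {
    n <- 6
    M <- matrix(stats::runif(n * n, 0.05, 1), n, n,
                dimnames = list(letters[1:n], letters[1:n]))
    D <- (M + t(M)) / 2; diag(D) <- 0
    tr <- neighbor_joining(D)
    lens <- c()
    walk <- function(node) {
      if (!is.na(node$length)) lens <<- c(lens, node$length)
      for (ch in node$children) walk(ch)
    }
    walk(tr)
    expect_true(all(lens >= 0))
    expect_setequal(kcvkit:::.tree_leaves(tr), letters[1:n])
  }
})

test_that("write_newick output parses back with identical metrics (ape oracle)", {
  skip_if_not_installed("ape")
  star <- structure(list(label = NA_character_, length = NA_real_, children = list(
    list(label = "A", length = 1, children = list()),
    list(label = "B", length = 1, children = list()),
    list(label = "C", length = 1, children = list()))), class = "kcv_tree")
  expect_equal(write_newick(star), "(A:1.0,B:1.0,C:1.0);")
  set.seed(54)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 3))
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    parsed <- ape::read.tree(text = write_newick(nj))
    Dp <- ape::cophenetic.phylo(parsed)
    expect_lt(max(abs(Dp[rownames(D), colnames(D)] - D)), 1e-8)
  }
  # cherry nesting in a 4-leaf tree
  D4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D4["A", "B"] <- 2; D4["A", "C"] <- 6; D4["A", "D"] <- 6
  D4["B", "C"] <- 6; D4["B", "D"] <- 6; D4["C", "D"] <- 2
  D4 <- D4 + t(D4)
  nwk <- write_newick(neighbor_joining(D4))
  expect_match(nwk, "\\(A:[0-9.]+,B:[0-9.]+\\)|\\(B:[0-9.]+,A:[0-9.]+\\)")
})

test_that("is_monophyletic agrees with exhaustive bipartition enumeration", {
  # fixed 5-leaf tree ((A,B),(C,D),E) at the trifurcating root
  D <- matrix(0, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  pairs <- list(c("A","B",2), c("A","C",8), c("A","D",8), c("A","E",6),
                c("B","C",8), c("B","D",8), c("B","E",6),
                c("C","D",2), c("C","E",6), c("D","E",6))
  for (p in pairs) { D[p[1], p[2]] <- as.numeric(p[3]); D[p[2], p[1]] <- as.numeric(p[3]) }
  tr <- neighbor_joining(D)
  leaves <- LETTERS[1:5]
  # every edge bipartition side of ((A,B),(C,D),E): singleton sides and their
  # complements, the two cherries, and their complements
  true_sides <- c(lapply(leaves, identity),
                  lapply(leaves, function(l) setdiff(leaves, l)),
                  list(c("A", "B"), c("C", "D"),
                       c("C", "D", "E"), c("A", "B", "E"), leaves))
  subsets <- unlist(lapply(1:5, function(k) combn(leaves, k, simplify = FALSE)),
                    recursive = FALSE)
  for (s in subsets) {
    want <- any(vapply(true_sides, function(ts) setequal(s, ts), logical(1)))
    expect_equal(is_monophyletic(tr, s), want, info = paste(s, collapse = ""))
  }
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown")
})

test_that("NJ tie-break is deterministic and stable across permutations", {
  # perfectly symmetric star distances force Q ties
  n <- 4
  D <- matrix(2, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  diag(D) <- 0
  nwk1 <- write_newick(neighbor_joining(D))
  nwk2 <- write_newick(neighbor_joining(D))
  expect_identical(nwk1, nwk2)
})
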