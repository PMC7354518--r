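# Distance phylogeny: p-distances, canonical neighbor joining with a
# deterministic tie-break, Newick output, and bipartition queries.

#' p-distance matrix of a multiple alignment
#'
#' `d(i, j)` is the proportion of differing columns among columns where
#' neither row carries a gap. A pair with no comparable columns is an error.
#'
#' @param msa A [multiple_alignment()] with >= 3 rows.
#' @return Symmetric numeric matrix with taxon ids as dimnames, zero diagonal,
#'   entries in `[0, 1]`.
#' @export
p_distance_matrix <- function(msa) {
  mat <- .msa_matrix(msa)
  n <- nrow(mat)
  if (n < 3L) stop("need at least 3 rows", call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok)) stop("no comparable columns between ", msa$ids[i], " and ",
                       msa$ids[j], call. = FALSE)
    D[i, j] <- D[j, i] <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
  }
  D
}

# internal node constructors: a tree node is list(label, length, children)
.leaf <- function(label) list(label = label, length = NA_real_, children = list())
.node <- function(children) list(label = NA_character_, length = NA_real_,
                                 children = children)

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining. Ties in the Q criterion are broken
#' deterministically by the lexicographically smallest (sorted) pair of
#' cluster ids, a cluster's id being the smallest leaf id it contains.
#' Negative branch lengths are clamped to zero with the deficit added to the
#' sibling branch of the join (so the joined pair's mutual distance is
#' preserved). The result is unrooted, represented with a trifurcating root.
#'
#' @param dm Symmetric distance matrix with taxon-id dimnames (>= 3 taxa).
#' @return Object of class `kcv_tree` (nested node list; root has >= 3
#'   children for > 3 taxa inputs).
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  ids <- rownames(dm)
  if (is.null(ids)) stop("distance matrix needs taxon dimnames", call. = FALSE)
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-12 || any(diag(dm) != 0) || any(dm < 0)) {
    stop("not a valid distance matrix", call. = FALSE)
  }
  D <- dm
  nodes <- lapply(ids, .leaf)
  cid <- ids  # cluster id = smallest member leaf id
  while (length(nodes) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest sorted id pair
    keys <- apply(cand, 1L, function(ij) {
      p <- sort(c(cid[ij[1L]], cid[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    ni <- nodes[[i]]; ni$length <- li
    nj <- nodes[[j]]; nj$length <- lj
    newnode <- .node(list(ni, nj))
    newdist <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newdist[keep]),
                c(newdist[keep], 0))
    nodes <- c(nodes[keep], list(newnode))
    cid <- c(cid[keep], min(cid[c(i, j)]))
    D <- D2
  }
  # final trifurcation: three-point formulas
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  ls <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  ls <- pmax(ls, 0)
  for (k in 1:3) nodes[[k]]$length <- ls[k]
  structure(.node(nodes), class = "kcv_tree")
}

.tree_leaves <- function(node) {
  if (length(node$children) == 0L) return(node$label)
  unlist(lapply(node$children, .tree_leaves))
}

#' @export
print.kcv_tree <- function(x, ...) {
  lv <- .tree_leaves(x)
  cat(sprintf("<kcv_tree %d leaves: %s%s>\n", length(lv),
              paste(utils::head(lv, 5), collapse = ","),
              if (length(lv) > 5) ",..." else ""))
  invisible(x)
}

.newick_label <- function(label) {
  if (grepl("[():;,' \t]", label)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else label
}

.newick_length <- function(x) {
  if (is.na(x)) return("")
  s <- if (x == round(x)) sprintf("%.1f", x) else format(x, digits = 12)
  paste0(":", s)
}

#' Serialize a tree to Newick
#'
#' Branch lengths are emitted for every non-root node; labels containing
#' Newick special characters are single-quoted. Parsing the output with any
#' standard Newick reader reproduces the topology and branch lengths.
#'
#' @param tree A `kcv_tree` from [neighbor_joining()].
#' @return A single Newick string terminated by `;`.
#' @export
write_newick <- function(tree) {
  rec <- function(node) {
    if (length(node$children) == 0L) {
      paste0(.newick_label(node$label), .newick_length(node$length))
    } else {
      paste0("(", paste(vapply(node$children, rec, character(1)), collapse = ","),
             ")", .newick_length(node$length))
    }
  }
  paste0("(", paste(vapply(tree$children, rec, character(1)), collapse = ","), ");")
}

# all non-trivial subtree leaf sets (one per internal edge + leaf edges)
.tree_clades <- function(tree) {
  clades <- list()
  rec <- function(node) {
    if (length(node$children) == 0L) {
      lv <- node$label
    } else {
      lv <- unlist(lapply(node$children, rec))
    }
    clades[[length(clades) + 1L]] <<- lv
    lv
  }
  for (ch in tree$children) rec(ch)
  clades
}

#' Test whether a taxon set is monophyletic
#'
#' TRUE iff some edge of the (trifurcation-rooted) tree bipartitions the
#' leaves into exactly the given set and its complement. The full leaf set and
#' singletons are trivially monophyletic.
#'
#' @param tree A `kcv_tree`.
#' @param taxa Character vector of leaf labels (subset of the leaf set).
#' @return Logical.
#' @export
is_monophyletic <- function(tree, taxa) {
  leaves <- .tree_leaves(tree)
  taxa <- unique(taxa)
  unknown <- setdiff(taxa, leaves)
  if (length(unknown) > 0L) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (setequal(taxa, leaves)) return(TRUE)
  for (cl in .tree_clades(tree)) {
    if (setequal(cl, taxa) || setequal(setdiff(leaves, cl), taxa)) return(TRUE)
  }
  FALSE
}

#' Leaf-to-leaf path-length matrix of a tree
#'
#' Sum of branch lengths along the path between every leaf pair; exactly
#' reproduces the input distances when the metric is additive.
#'
#' @param tree A `kcv_tree`.
#' @return Symmetric numeric matrix with leaf labels as dimnames.
#' @export
tree_path_lengths <- function(tree) {
  leaves <- .tree_leaves(tree)
  n <- length(leaves)
  D <- matrix(0, n, n, dimnames = list(leaves, leaves))
  # depth of each leaf below each node, computed recursively
  rec <- function(node) {
    if (length(node$children) == 0L) {
      depths <- stats::setNames(0, node$label)
    } else {
      parts <- lapply(node$children, rec)
      for (a in seq_along(parts)) for (b in seq_along(parts)) {
        if (a < b) {
          for (la in names(parts[[a]])) for (lb in names(parts[[b]])) {
            d <- parts[[a]][la] + parts[[b]][lb]
            D[la, lb] <<- D[lb, la] <<- d
          }
        }
      }
      depths <- unlist(parts)
    }
    if (!is.na(node$length)) depths <- depths + node$length
    depths
  }
  rec(tree)
  D
}

#' Write a distance matrix as square TSV
#' @param dm Distance matrix with dimnames.
#' @param path Output path.
#' @export
write_distance_tsv <- function(dm, path) {
  utils::write.table(cbind(id = rownames(dm), as.data.frame(dm)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
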