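# Distance-based phylogeny: pairwise-deletion p-distance with Poisson
# correction, Saitou-Nei neighbor joining (Studier-Keppler Q), column
# bootstrap, and subfamily assignment by cutting the longest well-supported
# internal branches.

#' Poisson-corrected pairwise distances from a protein alignment
#'
#' For each pair, sites where either sequence has a gap are excluded
#' (pairwise deletion); `p` is the proportion of differing compared sites and
#' `d = -ln(1 - p)` is the Poisson multiple-hit correction. Pairs with
#' `p >= 1` or zero comparable sites are flagged `NA` (an error in strict
#' mode).
#'
#' @param aln named character vector of aligned sequences, or a character
#'   matrix (rows = taxa).
#' @param strict error on missing/saturated distances instead of flagging.
#' @return Object of class `fam_dist`: list with `taxa`, `p`, `d` matrices.
#' @export
pairwise_distance <- function(aln, strict = FALSE) {
  m <- if (is.matrix(aln)) aln else seq_to_matrix(aln)
  if (nrow(m) < 2) stopf("need >= 2 sequences")
  taxa <- rownames(m) %||% paste0("t", seq_len(nrow(m)))
  valid <- m != "-" & m != "." & m != "X"
  n <- nrow(m)
  p <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- valid[i, ] & valid[j, ]
      nc <- sum(both)
      if (nc == 0) {
        if (strict) stopf("no comparable sites between %s and %s", taxa[i], taxa[j])
        p[i, j] <- p[j, i] <- NA_real_
        next
      }
      p[i, j] <- p[j, i] <- sum(m[i, both] != m[j, both]) / nc
    }
  }
  d <- -log(1 - p)
  d[!is.na(p) & p >= 1] <- NA_real_
  if (strict && anyNA(d[upper.tri(d)])) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)[1, ]
    stopf("distance undefined (p >= 1) between %s and %s", taxa[bad[1]], taxa[bad[2]])
  }
  structure(list(taxa = taxa, p = p, d = d), class = "fam_dist")
}

#' @export
print.fam_dist <- function(x, ...) {
  cat(sprintf("<fam_dist> %d taxa, mean d = %.4f\n",
              length(x$taxa), mean(x$d[upper.tri(x$d)], na.rm = TRUE)))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion. Negative
#' branch lengths are clamped to zero; ties in Q are broken by the
#' lexicographically smallest pair of cluster representatives (the smallest
#' leaf label each cluster contains), so the result is deterministic.
#'
#' @param dm a `fam_dist`, or a symmetric numeric matrix with dimnames.
#' @return An unrooted `ape::phylo` tree.
#' @export
build_nj <- function(dm) {
  d <- if (inherits(dm, "fam_dist")) dm$d else dm
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  taxa <- rownames(d)
  n <- nrow(d)
  if (n < 2) stopf("need >= 2 taxa")
  if (anyNA(d[upper.tri(d)])) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)[1, ]
    stopf("missing distance between %s and %s", taxa[bad[1]], taxa[bad[2]])
  }
  if (n == 2) {
    return(ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         taxa[1], d[1, 2] / 2, taxa[2], d[1, 2] / 2)))
  }
  # each active cluster: newick fragment + representative (smallest leaf label)
  node <- taxa
  rep_label <- taxa
  D <- d
  while (nrow(D) > 3) {
    nn <- nrow(D)
    rs <- rowSums(D)
    Q <- (nn - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      pr <- sort(c(rep_label[ij[1]], rep_label[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- max(0, D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (nn - 2)))
    vj <- max(0, D[i, j] - vi)
    vj <- max(0, min(vj, D[i, j])) # keep both ends non-negative
    new_node <- sprintf("(%s:%.10g,%s:%.10g)", node[i], vi, node[j], vj)
    new_rep <- min(rep_label[i], rep_label[j])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    du <- du[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, u = du), u = c(du, 0))
    node <- c(node[-c(i, j)], new_node)
    rep_label <- c(rep_label[-c(i, j)], new_rep)
  }
  # final three clusters joined at an unresolved root (unrooted tree)
  v1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  v2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  v3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 node[1], v1, node[2], v2, node[3], v3)
  ape::read.tree(text = txt)
}

# canonical string for the bipartition induced by the clade 'tips' within
# 'all_taxa': the side not containing the alphabetically first taxon
bipartition_key <- function(tips, all_taxa) {
  first <- sort(all_taxa)[1]
  side <- if (first %in% tips) setdiff(all_taxa, tips) else tips
  paste(sort(side), collapse = "|")
}

# internal-edge bipartitions of an unrooted phylo; returns tibble with child
# node number, key, branch length
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  internal_children <- tree$edge[, 2][tree$edge[, 2] > ntip]
  if (!length(internal_children)) {
    return(tibble::tibble(node = integer(), key = character(), length = numeric()))
  }
  desc <- phangorn::Descendants(tree, internal_children, type = "tips")
  keys <- vapply(desc, function(ix) bipartition_key(tree$tip.label[ix], tree$tip.label),
                 character(1))
  lens <- tree$edge.length[match(internal_children, tree$edge[, 2])]
  nontrivial <- vapply(desc, function(ix) {
    k <- length(ix); k >= 2 && k <= ntip - 2
  }, logical(1)) & !duplicated(keys) # rooted trees duplicate the root split
  tibble::tibble(node = internal_children, key = keys, length = lens)[nontrivial, ]
}

#' Bootstrap a neighbor-joining protein tree
#'
#' Columns are resampled with replacement `n_reps` times; each replicate's
#' Poisson-corrected distances and NJ tree are recomputed and the support of
#' every internal bipartition of the original tree is the count of replicates
#' containing it. Supports are stored as integer node labels (MEGA-style).
#' Replicate distance matrices with undefined entries fall back to the
#' largest finite replicate distance.
#'
#' @param aln named character vector of aligned sequences (or matrix).
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return List of class `fam_phylo`: `tree` (phylo with `node.label`
#'   supports), `n_reps`, `supports` tibble.
#' @export
bootstrap_nj <- function(aln, n_reps = 1000, seed = 1L) {
  stopifnot(n_reps >= 1)
  m <- if (is.matrix(aln)) aln else seq_to_matrix(aln)
  taxa <- rownames(m)
  L <- ncol(m)
  n <- nrow(m)
  # per-pair mismatch/validity indicators: bootstrap distances are then
  # weighted column sums, which keeps 1000 replicates cheap
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  valid <- m != "-" & m != "." & m != "X"
  V <- matrix(FALSE, nrow(pairs), L)
  M <- V
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    V[k, ] <- valid[i, ] & valid[j, ]
    M[k, ] <- V[k, ] & (m[i, ] != m[j, ])
  }
  dist_from_weights <- function(w) {
    cmp <- V %*% w
    mis <- M %*% w
    p <- ifelse(cmp > 0, mis / cmp, NA_real_)
    d <- -log(1 - p)
    d[!is.na(p) & p >= 1] <- NA_real_
    if (anyNA(d)) {
      mx <- max(d, na.rm = TRUE)
      d[is.na(d)] <- if (is.finite(mx)) mx * 1.05 else 1
    }
    out <- matrix(0, n, n, dimnames = list(taxa, taxa))
    for (k in seq_len(nrow(pairs))) out[pairs[k, 1], pairs[k, 2]] <- d[k]
    out[lower.tri(out)] <- t(out)[lower.tri(out)]
    out
  }
  original <- build_nj(dist_from_weights(rep(1, L)))
  bp <- tree_bipartitions(original)
  counts <- setNames(integer(nrow(bp)), bp$key)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    rep_tree <- build_nj(dist_from_weights(w))
    rk <- tree_bipartitions(rep_tree)$key
    hit <- bp$key %in% rk
    counts[hit] <- counts[hit] + 1L
  }
  ntip <- length(original$tip.label)
  n_internal <- original$Nnode
  labels <- rep("", n_internal)
  labels[bp$node - ntip] <- as.character(counts)
  original$node.label <- labels
  structure(list(tree = original, n_reps = n_reps,
                 supports = tibble::tibble(key = bp$key, node = bp$node,
                                           length = bp$length,
                                           support = unname(counts))),
            class = "fam_phylo")
}

#' @export
print.fam_phylo <- function(x, ...) {
  cat(sprintf("<fam_phylo> %d tips, %d bootstrap replicates, median support %s\n",
              length(x$tree$tip.label), x$n_reps,
              if (nrow(x$supports)) stats::median(x$supports$support) else "NA"))
  invisible(x)
}

#' Assign subfamilies by cutting the tree's longest supported branches
#'
#' Cuts the `k - 1` longest internal branches among those with bootstrap
#' support at least `min_support`, yielding `k` connected leaf groups.
#' Groups are labelled with Roman numerals ordered by decreasing size (ties:
#' by smallest member label), mirroring the convention that subfamily I is
#' the largest.
#'
#' @param phylo a `fam_phylo` from [bootstrap_nj()] (or an `ape::phylo` with
#'   numeric node labels as supports).
#' @param k number of subfamilies.
#' @param min_support minimum bootstrap count for a branch to qualify.
#' @return Tibble: member_id, subfamily.
#' @export
assign_subfamilies <- function(phylo, k = 5, min_support = NULL) {
  tree <- if (inherits(phylo, "fam_phylo")) phylo$tree else phylo
  n_reps <- if (inherits(phylo, "fam_phylo")) phylo$n_reps else 1000L
  min_support <- min_support %||% (n_reps / 2)
  stopifnot(k >= 1)
  tips <- tree$tip.label
  if (k == 1) {
    return(tibble::tibble(member_id = sort(tips), subfamily = "I"))
  }
  bp <- tree_bipartitions(tree)
  ntip <- length(tips)
  support <- suppressWarnings(as.numeric(tree$node.label[bp$node - ntip]))
  support[is.na(support)] <- 0
  qual <- bp[support >= min_support, ]
  if (nrow(qual) < k - 1) {
    stopf("only %d internal branches reach support >= %s; lower min_support or k",
          nrow(qual), format(min_support))
  }
  cut_nodes <- qual$node[order(-qual$length, qual$key)][seq_len(k - 1)]
  keep <- !(tree$edge[, 2] %in% cut_nodes)
  g <- igraph::graph_from_edgelist(apply(tree$edge[keep, , drop = FALSE], 2, as.character),
                                   directed = FALSE)
  all_nodes <- as.character(seq_len(ntip + tree$Nnode))
  g <- igraph::add_vertices(g, length(setdiff(all_nodes, igraph::V(g)$name)),
                            name = setdiff(all_nodes, igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  leaf_comp <- comp[as.character(seq_len(ntip))]
  groups <- split(tips, leaf_comp)
  groups <- groups[lengths(groups) > 0]
  ord <- order(-lengths(groups), vapply(groups, function(x) sort(x)[1], character(1)))
  groups <- groups[ord]
  romans <- as.character(utils::as.roman(seq_along(groups)))
  purrr::map2_dfr(groups, romans, function(members, lab) {
    tibble::tibble(member_id = sort(members), subfamily = lab)
  })
}
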