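## Clustering of distance matrices into trees: UPGMA for epograms
## (average-linkage dendrograms over electrostatic distances, the PIPSA
## convention) and neighbor-joining for sequence p-distance trees.
## Tie-breaking is lexicographic on label pairs so trees are
## reproducible across runs and platforms.

validate_distance_matrix <- function(d, min_leaves = 2) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (nrow(d) < min_leaves) stop("need at least ", min_leaves, " leaves")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("L", seq_len(nrow(d)))
  }
  if (any(is.na(d)) || any(!is.finite(d))) {
    stop("distance matrix contains NA/NaN/Inf entries")
  }
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (max(abs(diag(d))) > 1e-8) stop("distance matrix diagonal is not zero")
  d
}

new_epogram_tree <- function(method, labels, phylo, heights = NULL,
                             merges = NULL, hc = NULL) {
  structure(list(method = method, labels = labels, phylo = phylo,
                 heights = heights, merges = merges, hclust = hc),
            class = "epogram_tree")
}

#' @export
print.epogram_tree <- function(x, ...) {
  cat(sprintf("%s tree with %d leaves\n", toupper(x$method),
              length(x$labels)))
  if (!is.null(x$heights)) {
    cat("  merge heights:", paste(sprintf("%.4g", x$heights),
                                  collapse = ", "), "\n")
  }
  invisible(x)
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Agglomerates with the average-linkage update
#' `d(new, k) = (n_i d_ik + n_j d_jk) / (n_i + n_j)`; each merge sits at
#' ultrametric height `d_ij / 2`.  Ties on the minimum distance are
#' broken lexicographically on the (sorted) pair of cluster
#' representative labels, so the tree is deterministic.
#'
#' @param d symmetric labelled distance matrix, zero diagonal.
#' @return an `"epogram_tree"` with elements `phylo` (ape tree),
#'   `hclust`, `heights` (node heights, `d/2`) and `merges`.
#' @export
upgma_tree <- function(d) {
  d <- validate_distance_matrix(d, min_leaves = 2)
  n <- nrow(d)
  labels <- rownames(d)
  work <- d
  sizes <- rep(1L, n)
  repr <- labels                 # lexicographic representative per cluster
  code <- -seq_len(n)            # hclust codes: negative = leaf
  active <- seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(active)
    sub <- work[active, active, drop = FALSE]
    off <- sub + diag(Inf, m)
    dmin <- min(off)
    cand <- which(off <= dmin + 1e-12 & upper.tri(off), arr.ind = TRUE)
    keys <- apply(cand, 1, function(ij) {
      paste(sort(c(repr[active[ij[1]]], repr[active[ij[2]]])),
            collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- work[i, j]
    merges[[step]] <- list(a = repr[i], b = repr[j], height = work[i, j] / 2)
    ## merged cluster stored in slot i; slot j retired
    ni <- sizes[i]; nj <- sizes[j]
    newd <- (ni * work[i, ] + nj * work[j, ]) / (ni + nj)
    work[i, ] <- newd; work[, i] <- newd; work[i, i] <- 0
    sizes[i] <- ni + nj
    repr[i] <- min(repr[i], repr[j])
    code[i] <- step
    active <- setdiff(active, j)
  }
  leaf_ord <- integer(0)
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  leaf_ord <- expand(n - 1)
  hc <- structure(list(merge = merge, height = height, order = leaf_ord,
                       labels = labels, method = "average",
                       call = match.call(), dist.method = "electrostatic"),
                  class = "hclust")
  phylo <- if (n >= 3) ape::as.phylo(hc) else NULL
  new_epogram_tree("upgma", labels, phylo, heights = height / 2,
                   merges = merges, hc = hc)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape); negative branch lengths are
#' clamped to zero with a warning.  For additive matrices the input
#' distances are recovered exactly as path lengths.
#'
#' @param d symmetric labelled distance matrix, zero diagonal, >= 3
#'   leaves (>= 4 for a nontrivial unrooted topology).
#' @return an `"epogram_tree"` wrapping an unrooted `phylo`.
#' @export
nj_tree <- function(d) {
  d <- validate_distance_matrix(d, min_leaves = 3)
  phylo <- ape::nj(d)
  if (any(phylo$edge.length < 0)) {
    warning(sprintf("%d negative NJ branch length(s) clamped to 0",
                    sum(phylo$edge.length < 0)))
    phylo$edge.length[phylo$edge.length < 0] <- 0
  }
  new_epogram_tree("nj", rownames(d), phylo)
}

#' Cophenetic distances implied by a tree
#'
#' For UPGMA trees the cophenetic distance of a pair is the (full,
#' `2 x` node height) merge height; for NJ trees it is the path length
#' between leaves.
#'
#' @param tree an `"epogram_tree"`.
#' @return symmetric labelled matrix.
#' @export
cophenetic_distances <- function(tree) {
  if (tree$method == "upgma") {
    m <- as.matrix(stats::cophenetic(tree$hclust))
  } else {
    m <- ape::cophenetic.phylo(tree$phylo)
  }
  m[tree$labels, tree$labels]
}

#' Cut an UPGMA tree at a height
#'
#' @param tree an `"epogram_tree"` from [upgma_tree()].
#' @param height node height (same scale as `tree$heights`).
#' @return named integer vector of cluster assignments.
#' @export
cut_tree <- function(tree, height) {
  if (tree$method != "upgma") stop("cut_tree requires an UPGMA tree")
  stats::cutree(tree$hclust, h = 2 * height)
}

#' Leaf order of a tree (for heatmap/epogram rendering)
#'
#' @param tree an `"epogram_tree"`.
#' @return character vector of labels in display order.
#' @export
leaf_order <- function(tree) {
  if (tree$method == "upgma") {
    tree$labels[tree$hclust$order]
  } else {
    tree$phylo$tip.label
  }
}

#' Write a tree in Newick format
#'
#' @param tree an `"epogram_tree"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  if (is.null(tree$phylo)) {
    ## 2-leaf UPGMA tree: trivial newick written directly
    h <- tree$heights[1]
    writeLines(sprintf("(%s:%g,%s:%g);", tree$labels[1], h,
                       tree$labels[2], h), path)
  } else {
    ape::write.tree(tree$phylo, file = path)
  }
  invisible(path)
}
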