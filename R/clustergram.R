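# Ward-linkage hierarchical clustering of the activity x efficacy
# significance matrix, and the two-way ordered clustergram.

#' Agglomerative Ward clustering with Euclidean input
#'
#' Plain Lance-Williams agglomeration.  Initial inter-singleton
#' dissimilarities are half squared Euclidean distances, so every merge
#' height equals the increase in the Ward objective (total within-cluster
#' sum of squares) caused by that merge:
#' \code{|A||B|/(|A|+|B|) * ||centroid_A - centroid_B||^2}.  Ties break
#' toward the lexicographically lowest cluster-index pair, making the merge
#' sequence deterministic.
#'
#' @param rows numeric matrix; each row is one entity (>= 2 rows).
#' @return object of class \code{linkage_tree}: \code{merge} / \code{height}
#'   in \code{\link[stats]{hclust}} encoding, \code{order}, \code{labels},
#'   and a \code{merges} data frame (cluster_a, cluster_b, height, size).
#' @export
ward_cluster <- function(rows) {
  rows <- as.matrix(rows)
  n <- nrow(rows)
  if (n < 2) stop("need at least two rows to cluster", call. = FALSE)
  labels <- rownames(rows)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))

  # D[i,j] = Ward merge cost between current clusters i and j
  D <- as.matrix(stats::dist(rows))^2 / 2
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  id <- -seq_len(n)                    # hclust convention: leaves negative
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  sizes <- integer(n - 1)
  for (s in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    dmin <- min(sub)
    # ties (to numerical tolerance) break toward the lowest-index pair
    best <- which(sub <= dmin + 1e-8 * (1 + dmin), arr.ind = TRUE)
    pick <- best[order(pmin(best[, 1], best[, 2]), pmax(best[, 1], best[, 2]))[1], ]
    i <- idx[min(pick)]; j <- idx[max(pick)]
    height[s] <- D[i, j]
    pair <- c(id[i], id[j])
    # hclust row convention: singletons first (by leaf index), then clusters
    pair <- pair[order(pair >= 0, abs(pair))]
    merge[s, ] <- pair
    sizes[s] <- size[i] + size[j]
    # Lance-Williams update for Ward objective increments
    for (k in idx) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        ((size[i] + size[k]) * D[i, k] + (size[j] + size[k]) * D[j, k] -
           size[k] * D[i, j]) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- s
    D[j, ] <- D[, j] <- Inf
  }
  tree <- structure(list(merge = merge, height = height, order = integer(0),
                         labels = labels,
                         method = "ward", dist.method = "euclidean",
                         merges = data.frame(cluster_a = merge[, 1],
                                             cluster_b = merge[, 2],
                                             height = height, size = sizes)),
                    class = "linkage_tree")
  tree$order <- tree_leaf_order(merge)
  tree
}

tree_leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand2 <- function(node) {
    # iterative to be safe on deep trees
    out <- integer(0); stack <- node
    while (length(stack)) {
      nd <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (nd < 0) out <- c(out, -nd)
      else stack <- c(stack, merge[nd, 2], merge[nd, 1])
    }
    out
  }
  expand2(nrow(merge))
}

#' Convert a linkage tree to an \code{hclust} object
#'
#' @param x a \code{linkage_tree}.
#' @param ... ignored.
#' @return \code{\link[stats]{hclust}} object (heights are Ward objective
#'   increments, not the square-root dialect).
#' @export
as.hclust.linkage_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "ward",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Serialize a linkage tree as a Newick string
#'
#' Branch lengths are height differences between a node and its parent
#' (leaves hang from their first merge at that merge's height).
#'
#' @param tree a \code{linkage_tree}.
#' @param digits significant digits for branch lengths.
#' @return single Newick string, semicolon-terminated.
#' @export
to_newick <- function(tree, digits = 10) {
  fmt <- function(h) format(h, digits = digits, trim = TRUE, scientific = FALSE)
  node_str <- function(node, parent_h) {
    if (node < 0) {
      sprintf("%s:%s", tree$labels[-node], fmt(parent_h))
    } else {
      h <- tree$height[node]
      sprintf("(%s,%s):%s",
              node_str(tree$merge[node, 1], h),
              node_str(tree$merge[node, 2], h),
              fmt(parent_h - h))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(", node_str(tree$merge[root, 1], h), ",",
         node_str(tree$merge[root, 2], h), ");")
}

#' Two-way clustergram of an activity-by-efficacy significance matrix
#'
#' Rows (activities) and columns (efficacies) are clustered independently by
#' Ward/Euclidean; activities with no significant call are dropped (with a
#' message) before clustering; the matrix is returned reordered by the two
#' dendrogram leaf orders.
#'
#' @param S binary matrix (or a \code{significance_matrix} object).
#' @param drop_empty_rows drop all-zero rows first (default TRUE).
#' @return list with \code{row_tree}, \code{col_tree}, \code{matrix}
#'   (reordered), \code{row_order}, \code{col_order}.
#' @export
clustergram <- function(S, drop_empty_rows = TRUE) {
  if (inherits(S, "significance_matrix")) S <- S$S
  S <- as.matrix(S)
  check_binary(S, "significance matrix")
  if (drop_empty_rows) {
    empty <- rowSums(S) == 0
    if (any(empty)) {
      message(sprintf("clustergram: dropping %d activity row(s) with no significant call",
                      sum(empty)))
      S <- S[!empty, , drop = FALSE]
    }
  }
  if (nrow(S) < 2 || ncol(S) < 2) {
    stop("significance matrix has fewer than 2 rows or columns after filtering",
         call. = FALSE)
  }
  row_tree <- ward_cluster(S)
  col_tree <- ward_cluster(t(S))
  ro <- row_tree$order; co <- col_tree$order
  list(row_tree = row_tree, col_tree = col_tree,
       matrix = S[ro, co, drop = FALSE],
       row_order = rownames(S)[ro], col_order = colnames(S)[co])
}
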