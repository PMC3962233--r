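# Shared fixtures and small independent oracles.

tiny_config <- function(seed = 1, ...) {
  args <- list(I = 300, J = 30, K = 10, L = 3,
               n_main_per_class = 3, p_main = 0.7, p_support = 0.05,
               n_specific_activities_per_class = 2, n_general_activities = 3,
               p_activity_noise = 0.02, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(jamu_config, args)
}

random_tensor <- function(I, J, K, binary = FALSE) {
  if (binary) array(rbinom(I * J * K, 1, 0.4), c(I, J, K))
  else array(rnorm(I * J * K), c(I, J, K))
}

# brute-force Ward: at every step evaluate the objective increase of every
# candidate merge directly from centroids, ties to the lowest-index pair
ward_brute <- function(M, tol = 1e-8) {
  n <- nrow(M)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0); merges <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    cost <- matrix(Inf, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      A <- M[clusters[[i]], , drop = FALSE]
      B <- M[clusters[[j]], , drop = FALSE]
      cost[i, j] <- nrow(A) * nrow(B) / (nrow(A) + nrow(B)) *
        sum((colMeans(A) - colMeans(B))^2)
    }
    cmin <- min(cost)
    cand <- which(cost <= cmin + tol * (1 + cmin), arr.ind = TRUE)
    pick <- cand[order(cand[, 1], cand[, 2])[1], ]
    merges[[length(merges) + 1]] <- sort(unlist(clusters[pick]))
    heights <- c(heights, cost[pick[1], pick[2]])
    clusters[[pick[1]]] <- c(clusters[[pick[1]]], clusters[[pick[2]]])
    clusters[[pick[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# member sets of each merge of a linkage_tree, in merge order
tree_member_sets <- function(tree) {
  out <- vector("list", nrow(tree$merge))
  for (s in seq_len(nrow(tree$merge))) {
    grab <- function(nd) if (nd < 0) -nd else out[[nd]]
    out[[s]] <- sort(c(grab(tree$merge[s, 1]), grab(tree$merge[s, 2])))
  }
  out
}

# OLS fitted values on centered blocks
ols_fitted <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  Xc %*% solve(crossprod(Xc), crossprod(Xc, Yc)) + rep(colMeans(Y), each = nrow(X))
}

table3_counts <- function() {
  as.matrix(read.table(system.file("extdata", "plsda_confusion_counts.tsv",
                                   package = "jamuda"),
                       header = TRUE, sep = "\t", row.names = 1))
}
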