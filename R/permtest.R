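# Permutation test on PLS-DA coefficients: which plants are main ingredients
# for which efficacy?
#
# The null hypothesis is that plant usage does not affect efficacy.  It is
# simulated by permuting whole response rows (keeping each formula's dummy
# row intact, so the one-class-per-formula structure is preserved) while the
# predictor rows stay fixed, refitting the PLS-DA model, and accumulating the
# coefficients into a null distribution.

#' Null distribution of PLS-DA coefficients under row permutation of Y
#'
#' @param X n x m predictor matrix.
#' @param Y n x p response matrix (dummy-coded).
#' @param ncomp PLS components (identical settings to the observed fit).
#' @param n_perm number of permutation replicates (>= 1).
#' @param seed RNG seed; the replicate permutations are reproducible.
#' @param ... further arguments for \code{\link{fit_pls}}.
#' @return n_perm x m x p array of null coefficients.
#' @export
permutation_null <- function(X, Y, ncomp, n_perm, seed = 1, ...) {
  stopifnot(n_perm >= 1)
  X <- as.matrix(unclass(X)); Y <- as.matrix(unclass(Y))
  n <- nrow(X)
  null <- array(NA_real_, c(n_perm, ncol(X), ncol(Y)))
  set.seed(seed)
  b <- 1L
  while (b <= n_perm) {
    perm <- sample.int(n)
    fit <- tryCatch(fit_pls(X, Y[perm, , drop = FALSE], ncomp, ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      # degenerate permuted fit (e.g. zero-variance block): resample
      message(sprintf("permutation replicate %d degenerate; resampled", b))
      next
    }
    null[b, , ] <- fit$B
    b <- b + 1L
  }
  null
}

#' Two-sided permutation p-values for observed coefficients
#'
#' Add-one convention:
#' \code{p = (1 + #\{|b*| >= |b|\}) / (n_perm + 1)}, so p is never zero and
#' the test is exact under exchangeability.
#'
#' @param observed_B m x p observed coefficient matrix.
#' @param null_samples n_perm x m x p array from
#'   \code{\link{permutation_null}}.
#' @return m x p matrix of p-values in \code{(0, 1]}.
#' @export
coef_pvalues <- function(observed_B, null_samples) {
  observed_B <- as.matrix(observed_B)
  d <- dim(null_samples)
  stopifnot(length(d) == 3, d[2] == nrow(observed_B), d[3] == ncol(observed_B))
  n_perm <- d[1]
  exceed <- apply(sweep(abs(null_samples), c(2, 3), abs(observed_B), `>=`),
                  c(2, 3), sum)
  p <- (1 + exceed) / (n_perm + 1)
  dimnames(p) <- dimnames(observed_B)
  p
}

#' Permutation test for main-ingredient plants
#'
#' Fits the observed PLS-DA model, generates the permutation null, and
#' returns per-(plant, class) p-values and significance calls.
#'
#' @param usage binary formula-by-plant matrix.
#' @param labels efficacy labels.
#' @param ncomp PLS components.
#' @param n_perm permutation replicates (default 999).
#' @param alpha significance level (default 0.05); no multiplicity
#'   correction by default, optionally Benjamini-Hochberg.
#' @param seed RNG seed.
#' @param fdr logical; apply Benjamini-Hochberg across all m x L p-values.
#' @return object of class \code{permutation_result} with \code{observed_B},
#'   \code{p_values}, \code{significant} (binary m x L), \code{alpha},
#'   \code{n_perm}, \code{seed}.
#' @export
plsda_permutation_test <- function(usage, labels, ncomp, n_perm = 999,
                                   alpha = 0.05, seed = 1, fdr = FALSE) {
  labels <- efficacy_labels(labels, formula_ids = rownames(usage))
  Y <- to_dummy(labels)
  observed <- fit_pls(usage, Y, ncomp)
  null <- permutation_null(usage, Y, ncomp, n_perm, seed = seed)
  p <- coef_pvalues(observed$B, null)
  p_adj <- if (fdr) matrix(stats::p.adjust(p, "BH"), nrow(p), ncol(p),
                           dimnames = dimnames(p)) else p
  structure(list(observed_B = observed$B, p_values = p,
                 significant = (p_adj <= alpha) * 1,
                 alpha = alpha, n_perm = n_perm, seed = seed, fdr = fdr,
                 class_names = levels(labels)),
            class = "permutation_result")
}

#' Per-efficacy significant plants and the per-plant significance histogram
#'
#' @param result a \code{\link{plsda_permutation_test}} result (or any list
#'   with a binary \code{significant} matrix).
#' @return list with \code{plants_by_class} (named list of plant ids),
#'   \code{counts_per_class}, and \code{histogram}: the number of plants
#'   significant for exactly 0, 1, 2, ... efficacies (a partition of the
#'   plant set).
#' @export
significant_plants <- function(result) {
  S <- result$significant
  per_plant <- rowSums(S)
  hist <- table(factor(per_plant, levels = 0:max(max(per_plant), 1)))
  plants <- lapply(seq_len(ncol(S)), function(l) rownames(S)[S[, l] == 1])
  names(plants) <- colnames(S)
  list(plants_by_class = plants,
       counts_per_class = colSums(S),
       histogram = hist)
}

#' Percentage summary of a significance-count partition
#'
#' Given counts of plants significant for exactly 0, 1, 2, ... efficacies,
#' returns the share of each bin among all plants, rounded to one decimal.
#'
#' @param histogram named integer vector (names = number of efficacies).
#' @return named numeric vector of percentages summing to ~100.
#' @export
partition_percentages <- function(histogram) {
  h <- stats::setNames(as.numeric(histogram), names(histogram))
  round(100 * h / sum(h), 1)
}
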