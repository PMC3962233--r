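# PCA and biplot coordinates for the plant-by-efficacy frequency table.

#' Plant-by-efficacy usage frequency matrix
#'
#' Cell (j, l) counts the formulas of efficacy class l that use plant j.
#' Treating plants as observations and efficacy classes as variables, this
#' J x L count table is the input for the exploratory PCA biplot.
#'
#' @param usage binary formula-by-plant matrix.
#' @param labels efficacy labels aligned with the rows of \code{usage}.
#' @return J x L numeric count matrix.
#' @export
build_frequency_matrix <- function(usage, labels) {
  stopifnot(nrow(usage) == length(labels))
  Y <- to_dummy(labels)
  crossprod(unclass(usage), Y)  # t(X) %*% Y: counts per (plant, class)
}

#' Principal component analysis via covariance eigendecomposition
#'
#' Columns are mean-centered (no variance scaling) and the sample covariance
#' matrix (divisor n - 1) is eigendecomposed.  Scores are the centered data
#' projected on the eigenvectors, so the sample variance of score j equals
#' eigenvalue j, scores are pairwise uncorrelated, and variances are
#' non-increasing.  Each eigenvector's sign is fixed so that its
#' largest-magnitude entry is positive, making the output deterministic.
#'
#' @param A numeric matrix, observations in rows (n >= 2).
#' @return object of class \code{jamu_pca} with \code{center} (column means),
#'   \code{values} (eigenvalues, descending), \code{vectors} (orthonormal
#'   eigenvector columns) and \code{scores}.
#' @export
fit_pca <- function(A) {
  A <- as.matrix(A)
  stopifnot(nrow(A) >= 2)
  center <- colMeans(A)
  Ac <- sweep(A, 2, center)
  V <- crossprod(Ac) / (nrow(A) - 1)
  e <- eigen(V, symmetric = TRUE)
  values <- pmax(e$values, 0)
  if (all(values == 0)) warning("constant input matrix: all eigenvalues are zero")
  vectors <- e$vectors
  for (j in seq_len(ncol(vectors))) {
    imax <- which.max(abs(vectors[, j]))
    if (vectors[imax, j] < 0) vectors[, j] <- -vectors[, j]
  }
  rownames(vectors) <- colnames(A)
  colnames(vectors) <- paste0("PC", seq_len(ncol(vectors)))
  scores <- Ac %*% vectors
  structure(list(center = center, values = values, vectors = vectors,
                 scores = scores),
            class = "jamu_pca")
}

#' Cumulative proportion of variance explained
#'
#' @param model a \code{\link{fit_pca}} fit.
#' @param n_components how many leading components to accumulate.
#' @return scalar in [0, 1].
#' @export
variance_explained <- function(model, n_components) {
  p <- length(model$values)
  stopifnot(n_components >= 1, n_components <= p)
  tot <- sum(model$values)
  if (tot == 0) stop("variance explained is undefined for an all-zero spectrum",
                     call. = FALSE)
  sum(model$values[seq_len(n_components)]) / tot
}

#' Two-dimensional biplot coordinates
#'
#' Returns observation points G and variable vectors H for the leading
#' \code{dims} components.  With \code{alpha = 0} (the "form" biplot) G holds
#' raw scores and H unit-length eigenvectors; with \code{alpha = 1} (the
#' "covariance" biplot) the singular values are moved onto H, so vector
#' lengths reflect column variability.  Either way \code{G \%*\% t(H)} is the
#' same rank-\code{dims} reconstruction of the centered data, so the
#' projection of a plant's point onto an efficacy axis predicts that plant's
#' (centered) usage frequency for the efficacy.
#'
#' @param model a \code{\link{fit_pca}} fit.
#' @param dims number of display dimensions (default 2).
#' @param alpha scaling exponent, 0 or 1.
#' @return list with \code{points} (n x dims), \code{vectors} (p x dims) and
#'   \code{alpha}.
#' @export
biplot_coords <- function(model, dims = 2, alpha = 0) {
  stopifnot(alpha %in% c(0, 1), dims >= 1,
            length(model$values) >= dims)
  idx <- seq_len(dims)
  lam <- model$values[idx]
  if (alpha == 0) {
    G <- model$scores[, idx, drop = FALSE]
    H <- model$vectors[, idx, drop = FALSE]
  } else {
    if (any(lam <= 0)) {
      stop("alpha = 1 scaling requires strictly positive eigenvalues in the requested dimensions",
           call. = FALSE)
    }
    G <- sweep(model$scores[, idx, drop = FALSE], 2, sqrt(lam), `/`)
    H <- sweep(model$vectors[, idx, drop = FALSE], 2, sqrt(lam), `*`)
  }
  list(points = G, vectors = H, alpha = alpha)
}
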