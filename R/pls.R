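# Two-block PLS regression (NIPALS) and the PLS-DA wrapper.

#' Fit a PLS2 regression by NIPALS
#'
#' Both blocks are column mean-centered (optionally autoscaled).  Components
#' are extracted one at a time: the inner iteration alternates
#' \code{w = X'u / |X'u|}, \code{t = Xw}, \code{q = Y't / t't},
#' \code{u = Yq / q'q} until the score vector stabilises, starting from the
#' largest-variance column of the current Y residual, which makes the fit
#' deterministic.
#'
#' Two deflation conventions are provided.  The default \code{"loadings"} is
#' classic NIPALS: X is deflated by \code{t p'} (p the X-loading) and Y by
#' \code{t q'}; scores are orthogonal and coefficients are computed through
#' the corrected weights \code{R = W (P'W)^{-1}} so that \code{B = R Q'} and
#' \code{T = Xc R} hold exactly.  The alternative \code{"weights"} deflates X
#' by \code{t w'} and re-regresses Y on all scores after each component; this
#' is the convention under which the trilinear model's projector-corrected
#' weight matrix reproduces the scores from the undeflated data, and it is
#' used by \code{\link{fit_npls}}.  The two conventions give identical fitted
#' values (and, for full-column-rank X, identical coefficients) but different
#' individual score vectors beyond the first component.
#'
#' @param X n x m predictor matrix.
#' @param Y n x p response matrix (a dummy matrix for PLS-DA).
#' @param ncomp number of components, \code{1 <= ncomp <= min(n - 1, m)}.
#' @param center,scale. preprocessing toggles (centering on, scaling off by
#'   default; scaling binary columns can inflate rare-plant influence).
#' @param deflation \code{"loadings"} (classic NIPALS) or \code{"weights"}.
#' @param tol,max_iter inner-iteration convergence control.
#' @return object of class \code{jamu_pls}: weights \code{W}, loadings
#'   \code{P}, Y-weights \code{Q}, scores \code{T}, corrected weights
#'   \code{R}, coefficients \code{B}, block means/scales, fitted values and
#'   residuals \code{E}, \code{F}.
#' @export
fit_pls <- function(X, Y, ncomp, center = TRUE, scale. = FALSE,
                    deflation = c("loadings", "weights"),
                    tol = 1e-12, max_iter = 500L) {
  deflation <- match.arg(deflation)
  X <- as.matrix(unclass(X)); Y <- as.matrix(unclass(Y))
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  n <- nrow(X); m <- ncol(X); p <- ncol(Y)
  stopifnot(nrow(Y) == n)
  if (ncomp < 1 || ncomp > min(n - 1, m)) {
    stop(sprintf("ncomp must lie in [1, %d]", min(n - 1, m)), call. = FALSE)
  }
  if (all(apply(Y, 2, stats::var) == 0)) {
    stop("Y has no variance; nothing to fit", call. = FALSE)
  }
  Xmeans <- if (center) colMeans(X) else rep(0, m)
  Ymeans <- if (center) colMeans(Y) else rep(0, p)
  Xscale <- if (scale.) apply(X, 2, stats::sd) else rep(1, m)
  Xscale[Xscale == 0] <- 1
  Xc <- sweep(sweep(X, 2, Xmeans), 2, Xscale, `/`)
  Yc <- sweep(Y, 2, Ymeans)

  Xr <- Xc; Yr <- Yc
  W <- matrix(0, m, ncomp); P <- matrix(0, m, ncomp)
  Q <- matrix(0, p, ncomp); Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    u <- Yr[, which.max(apply(Yr, 2, stats::var))]
    if (all(u == 0)) u <- Yr[, 1]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xr, u)
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop(sprintf("component %d: degenerate weight vector", a),
                        call. = FALSE)
      w <- w / nw
      t <- drop(Xr %*% w)
      q <- drop(crossprod(Yr, t)) / sum(t^2)
      u <- drop(Yr %*% q) / sum(q^2)
      if (sqrt(sum((t - t_old)^2)) <= tol * sqrt(sum(t^2)) || p == 1) break
      t_old <- t
    }
    pl <- drop(crossprod(Xr, t)) / sum(t^2)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q; Tm[, a] <- t
    if (deflation == "loadings") {
      Xr <- Xr - tcrossprod(t, pl)
      Yr <- Yr - tcrossprod(t, q)
    } else {
      Xr <- Xr - tcrossprod(t, w)
      Ti <- Tm[, seq_len(a), drop = FALSE]
      Yr <- Yc - Ti %*% solve(crossprod(Ti), crossprod(Ti, Yc))
    }
  }
  if (deflation == "loadings") {
    R <- W %*% solve(crossprod(P, W))   # corrected weights: T = Xc R exactly
    B <- tcrossprod(R, Q)
  } else {
    R <- build_corrected_weights(W)
    B_inner <- solve(crossprod(Tm), crossprod(Tm, Yc))
    B <- R %*% B_inner
  }
  dimnames(B) <- list(colnames(X), colnames(Y))
  fitted <- sweep(Xc %*% B, 2, Ymeans, `+`)
  colnames(fitted) <- colnames(Y)
  out <- list(ncomp = ncomp, deflation = deflation,
              W = W, P = P, Q = Q, T = Tm, R = R, B = B,
              Xmeans = Xmeans, Ymeans = Ymeans, Xscale = Xscale,
              fitted = fitted, E = Xr, F = Y - fitted,
              xnames = colnames(X), ynames = colnames(Y))
  class(out) <- "jamu_pls"
  out
}

#' Predict responses from a fitted PLS model
#'
#' \code{Y_hat = (X_new - X-means) B + Y-means} (Eq.-8-style prediction).
#'
#' @param object a \code{jamu_pls} fit.
#' @param newdata matrix with the same number of predictor columns.
#' @param ... ignored.
#' @return predicted response matrix.
#' @export
predict.jamu_pls <- function(object, newdata, ...) {
  newdata <- as.matrix(unclass(newdata))
  if (ncol(newdata) != length(object$Xmeans)) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(newdata), length(object$Xmeans)), call. = FALSE)
  }
  Xc <- sweep(sweep(newdata, 2, object$Xmeans), 2, object$Xscale, `/`)
  sweep(Xc %*% object$B, 2, object$Ymeans, `+`)
}

#' Assign classes from predicted dummy responses
#'
#' Each observation gets the class with the maximal predicted indicator
#' value; ties break toward the lower class index.
#'
#' @param Y_hat n x L matrix of predicted responses.
#' @param class_names ordered class set; defaults to \code{colnames(Y_hat)}.
#' @return factor of predicted labels.
#' @export
classify <- function(Y_hat, class_names = colnames(Y_hat)) {
  stopifnot(!is.null(class_names), ncol(Y_hat) == length(class_names))
  idx <- max.col(Y_hat, ties.method = "first")
  factor(class_names[idx], levels = class_names)
}

# ---- confusion matrix -------------------------------------------------------

#' Confusion matrix with per-class and overall percent correct
#'
#' @param observed,predicted label vectors of equal length; factor levels (or
#'   \code{class_names}) fix the row/column order.
#' @param class_names optional explicit class order.
#' @return a \code{confusion_matrix}: integer counts (rows = observed,
#'   columns = predicted), per-class percent correct and overall percent
#'   correct, both rounded to 1 decimal.
#' @export
confusion <- function(observed, predicted, class_names = NULL) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (is.null(class_names)) {
    class_names <- if (is.factor(observed)) levels(observed) else
      sort(unique(c(as.character(observed), as.character(predicted))))
  }
  bad <- setdiff(unique(c(as.character(observed), as.character(predicted))),
                 class_names)
  if (length(bad)) {
    stop(sprintf("label(s) outside the class set: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  counts <- table(factor(observed, class_names), factor(predicted, class_names))
  confusion_from_counts(unclass(counts), class_names)
}

#' Build a confusion-matrix summary from a printed count table
#'
#' Useful for re-deriving the percent-correct summaries of a published
#' confusion matrix from its raw counts.
#'
#' @param counts square L x L count matrix, rows = observed classes.
#' @param class_names class codes; default from dimnames.
#' @return a \code{confusion_matrix} object.
#' @export
confusion_from_counts <- function(counts, class_names = rownames(counts)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (is.null(class_names)) class_names <- paste0("C", seq_len(nrow(counts)))
  dimnames(counts) <- list(observed = class_names, predicted = class_names)
  row_tot <- rowSums(counts)
  per_class <- round(100 * diag(counts) / row_tot, 1)
  overall <- round(100 * sum(diag(counts)) / sum(counts), 1)
  structure(list(counts = counts, class_names = class_names,
                 row_totals = row_tot, col_totals = colSums(counts),
                 n = sum(counts), trace = sum(diag(counts)),
                 per_class_percent_correct = per_class,
                 overall_percent_correct = overall),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  tab <- cbind(x$counts, Total = x$row_totals, `%Correct` = x$per_class_percent_correct)
  tot <- c(x$col_totals, x$n, x$overall_percent_correct)
  tab <- rbind(tab, Total = tot)
  print(tab)
  invisible(x)
}

#' Write a confusion matrix as a delimited table (layout: observed rows,
#' predicted columns, Total row/column, \%Correct column)
#'
#' @param x a \code{confusion_matrix}.
#' @param path output path.
#' @param sep field separator.
#' @export
write_confusion <- function(x, path, sep = "\t") {
  tab <- cbind(x$counts, Total = x$row_totals,
               `%Correct` = x$per_class_percent_correct)
  tab <- rbind(tab, Total = c(x$col_totals, x$n, x$overall_percent_correct))
  utils::write.table(cbind(observed = rownames(tab), as.data.frame(tab, check.names = FALSE)),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read back a confusion table written by \code{\link{write_confusion}}
#'
#' @param path file path.
#' @param sep field separator.
#' @return a \code{confusion_matrix} rebuilt from the counts.
#' @export
read_confusion <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  L <- nrow(df) - 1
  counts <- as.matrix(df[seq_len(L), seq_len(L)])
  confusion_from_counts(counts, rownames(df)[seq_len(L)])
}

# ---- discriminant wrapper ---------------------------------------------------

#' PLS-DA: discriminant analysis of efficacy classes from plant usage
#'
#' Dummy-codes the labels over their factor levels and fits
#' \code{\link{fit_pls}} with the usage matrix as the X block.
#'
#' @param usage binary formula-by-plant matrix.
#' @param labels efficacy labels (factor; levels define the class order).
#' @param ncomp number of PLS components.
#' @param ... passed to \code{\link{fit_pls}}.
#' @return object of class \code{jamu_plsda} wrapping the PLS fit.
#' @export
fit_plsda <- function(usage, labels, ncomp, ...) {
  labels <- efficacy_labels(labels, formula_ids = rownames(usage))
  Y <- to_dummy(labels)
  fit <- fit_pls(usage, Y, ncomp, ...)
  structure(list(pls = fit, class_names = levels(labels), labels = labels),
            class = "jamu_plsda")
}

#' @export
predict.jamu_plsda <- function(object, newdata, type = c("class", "response"), ...) {
  type <- match.arg(type)
  Y_hat <- predict(object$pls, newdata)
  if (type == "response") return(Y_hat)
  classify(Y_hat, object$class_names)
}

#' Cross-validated PLS-DA classification accuracy
#'
#' Random K-fold cross-validation; the model (centering, components) is
#' refitted on each training split and accuracy is pooled over held-out
#' formulas.
#'
#' @param usage,labels training data.
#' @param ncomp components per fold.
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return list with \code{accuracy} (fraction correct), \code{percent}
#'   (rounded to 1 decimal) and the held-out \code{predicted} labels.
#' @export
cv_plsda <- function(usage, labels, ncomp, folds = 10, seed = 1) {
  labels <- efficacy_labels(labels, formula_ids = rownames(usage))
  n <- nrow(usage)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  for (f in seq_len(folds)) {
    hold <- fold == f
    fit <- fit_plsda(usage[!hold, , drop = FALSE], labels[!hold], ncomp)
    pred[hold] <- predict(fit, usage[hold, , drop = FALSE])
  }
  acc <- mean(pred == labels)
  list(accuracy = acc, percent = round(100 * acc, 1), predicted = pred)
}

#' Choose the number of PLS-DA components by cross-validation
#'
#' Scans \code{1..max_comp} and returns the smallest component count whose
#' cross-validated accuracy is within \code{one_se} of the best (default 0,
#' i.e. plain argmax with ties to the smaller model).
#'
#' @param usage,labels training data.
#' @param max_comp largest component count to try (capped at
#'   \code{min(n - 1, m, 15)}).
#' @param folds,seed cross-validation controls.
#' @return list with \code{ncomp} and the accuracy path.
#' @export
select_ncomp <- function(usage, labels, max_comp = 15, folds = 10, seed = 1) {
  max_comp <- min(max_comp, nrow(usage) - 1, ncol(usage))
  acc <- vapply(seq_len(max_comp), function(a) {
    cv_plsda(usage, labels, a, folds = folds, seed = seed)$accuracy
  }, numeric(1))
  list(ncomp = which.max(acc), accuracy = acc)
}
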