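# Trilinear N-PLS regression and N-PLS-DA on the formula x plant x activity
# tensor.
#
# Each component factorizes the three-way predictor array into an observation
# score t_c and unit weight vectors w^J_c (plants) and w^K_c (activities),
# chosen to maximize covariance with the response score.  Working on the
# activity-major unfolding, the score is t_c = X (w^K_c %x% w^J_c); X is
# deflated by t_c w_c' (w_c the Kronecker weight), so the projector-corrected
# weight matrix reproduces all scores directly from the undeflated data.

#' Deflation-corrected weight matrix
#'
#' Given unit-norm combined weight columns \code{w_1..w_C} extracted with
#' sequential \code{t w'} deflation, returns the matrix whose column c is
#' \code{(I - w_1 w_1') ... (I - w_{c-1} w_{c-1}') w_c}, so that the scores
#' can be computed in one step from the original centered unfolded matrix.
#'
#' @param W JK x C matrix of combined weights.
#' @return JK x C corrected weight matrix.
#' @export
build_corrected_weights <- function(W) {
  W <- as.matrix(W)
  Wt <- W
  for (cc in seq_len(ncol(W))[-1]) {
    v <- W[, cc]
    for (q in rev(seq_len(cc - 1))) {   # rightmost projector applies first
      v <- v - W[, q] * sum(W[, q] * v)
    }
    Wt[, cc] <- v
  }
  Wt
}

#' Fit a trilinear N-PLS(-DA) model
#'
#' For each component, with \code{u} the current unit Y-weight direction, the
#' J x K matrix \code{Z = reshape(X_unfolded' (Y_res u))} is formed and its
#' leading singular vector pair gives the plant weights \code{w^J} and
#' activity weights \code{w^K}; the observation score is
#' \code{t = X_unfolded (w^K \%x\% w^J)}, equal to the trilinear double sum
#' \code{sum_jk X[i,j,k] w^J_j w^K_k}.  \code{u} is re-estimated from the Y
#' residual and \code{t} until the score converges.  X is deflated by
#' \code{t w'}; after every component Y is re-regressed on all scores.  Final
#' coefficients are \code{B_NPLS = W_tilde B_inner} with \code{W_tilde} the
#' deflation-corrected weights, so predictions work directly from the
#' unfolded (centered) data.
#'
#' Signs are fixed so each \code{w^J} has a positive largest-magnitude entry,
#' with \code{w^K} flipped along to preserve the score.
#'
#' @param X3 I x J x K binary array (see \code{\link{build_tensor}}), or an
#'   already-unfolded I x JK matrix together with \code{dims}.
#' @param Y response matrix (dummy-coded classes for N-PLS-DA) or a factor of
#'   labels.
#' @param ncomp number of components.
#' @param dims optional \code{c(J, K)} when \code{X3} is already unfolded.
#' @param tol,max_iter inner-iteration control.
#' @return object of class \code{jamu_npls} with plant/activity weights
#'   \code{WJ}, \code{WK}, scores \code{T}, Y-scores \code{V}, Y-weights
#'   \code{U}, combined weights \code{W}, corrected weights \code{W_tilde},
#'   inner coefficients \code{B_inner}, final coefficients \code{B_npls},
#'   block means and residuals.
#' @export
fit_npls <- function(X3, Y, ncomp, dims = NULL, tol = 1e-12, max_iter = 500L) {
  if (is.array(X3) && length(dim(X3)) == 3) {
    dims <- dim(X3)[2:3]
    Xu <- matricize(X3)
  } else {
    Xu <- as.matrix(X3)
    if (is.null(dims)) stop("dims = c(J, K) required for pre-unfolded input", call. = FALSE)
  }
  J <- dims[1]; K <- dims[2]
  if (is.factor(Y) || is.character(Y)) Y <- to_dummy(Y)
  Y <- as.matrix(Y)
  I <- nrow(Xu); L <- ncol(Y)
  stopifnot(nrow(Y) == I, ncol(Xu) == J * K)
  if (ncomp < 1 || ncomp > min(I - 1, J * K)) {
    stop(sprintf("ncomp must lie in [1, %d]", min(I - 1, J * K)), call. = FALSE)
  }
  Xmeans <- colMeans(Xu); Ymeans <- colMeans(Y)
  Xc <- sweep(Xu, 2, Xmeans); Yc <- sweep(Y, 2, Ymeans)

  Xr <- Xc; Yr <- Yc
  WJ <- matrix(0, J, ncomp); WK <- matrix(0, K, ncomp)
  Wc <- matrix(0, J * K, ncomp)
  Tm <- matrix(0, I, ncomp); U <- matrix(0, L, ncomp); V <- matrix(0, I, ncomp)
  B_inner <- NULL
  for (a in seq_len(ncomp)) {
    u <- rep(0, L); u[which.max(apply(Yr, 2, stats::var))] <- 1
    t_old <- rep(Inf, I); conv <- FALSE
    for (it in seq_len(max_iter)) {
      y_u <- drop(Yr %*% u)
      Z <- matrix(drop(crossprod(Xr, y_u)), J, K)
      sv <- svd(Z, nu = 1, nv = 1)
      wJ <- sv$u[, 1]; wK <- sv$v[, 1]
      imax <- which.max(abs(wJ))
      if (wJ[imax] < 0) { wJ <- -wJ; wK <- -wK }
      w <- kronecker(wK, wJ)          # index (k-1)*J + j, matching matricize()
      t <- drop(Xr %*% w)
      uu <- drop(crossprod(Yr, t))
      nu_ <- sqrt(sum(uu^2))
      if (nu_ == 0) stop(sprintf("component %d: response residual orthogonal to score", a),
                         call. = FALSE)
      u <- uu / nu_
      if (sqrt(sum((t - t_old)^2)) <= tol * sqrt(sum(t^2)) || L == 1) { conv <- TRUE; break }
      t_old <- t
    }
    if (!conv) stop(sprintf("component %d did not converge in %d iterations", a, max_iter),
                    call. = FALSE)
    WJ[, a] <- wJ; WK[, a] <- wK; Wc[, a] <- w
    Tm[, a] <- t; U[, a] <- u; V[, a] <- drop(Yr %*% u)
    Xr <- Xr - tcrossprod(t, w)
    Ti <- Tm[, seq_len(a), drop = FALSE]
    B_inner <- solve(crossprod(Ti), crossprod(Ti, Yc))
    Yr <- Yc - Ti %*% B_inner
  }
  W_tilde <- build_corrected_weights(Wc)
  B_npls <- W_tilde %*% B_inner
  dn <- dimnames(X3)
  if (is.array(X3) && length(dim(X3)) == 3 && !is.null(dn)) {
    rownames(WJ) <- dn[[2]]; rownames(WK) <- dn[[3]]
  }
  colnames(WJ) <- colnames(WK) <- paste0("C", seq_len(ncomp))
  dimnames(B_npls) <- list(colnames(Xu), colnames(Y))
  fitted <- sweep(Xc %*% B_npls, 2, Ymeans, `+`)
  structure(list(ncomp = ncomp, J = J, K = K,
                 WJ = WJ, WK = WK, W = Wc, W_tilde = W_tilde,
                 T = Tm, U = U, V = V, B_inner = B_inner, B_npls = B_npls,
                 Xmeans = Xmeans, Ymeans = Ymeans,
                 fitted = fitted, E = Xr, F = Y - fitted,
                 ynames = colnames(Y)),
            class = "jamu_npls")
}

#' Predict responses from a fitted N-PLS model
#'
#' \code{Y_hat = (unfold(X3_new) - X-means) B_NPLS + Y-means}.
#'
#' @param object a \code{jamu_npls} fit.
#' @param newdata I' x J x K array (or I' x JK matrix) with the training
#'   plant/activity dimensions.
#' @param ... ignored.
#' @return predicted response matrix.
#' @export
predict.jamu_npls <- function(object, newdata, ...) {
  Xu <- if (is.array(newdata) && length(dim(newdata)) == 3) matricize(newdata)
        else as.matrix(newdata)
  if (ncol(Xu) != object$J * object$K) {
    stop(sprintf("newdata unfolds to %d columns; model expects %d",
                 ncol(Xu), object$J * object$K), call. = FALSE)
  }
  sweep(sweep(Xu, 2, object$Xmeans) %*% object$B_npls, 2, object$Ymeans, `+`)
}

#' Activity-by-efficacy significance from N-PLS-DA activity weights
#'
#' Fits one binary-response N-PLS model per efficacy class (one-vs-rest, the
#' default) or a single joint model, and declares activity k significant for
#' class l when the evidence \code{max_c |w^K_kc|} reaches the threshold.
#' The 0.3 default follows the common rule of thumb that absolute weights of
#' 0.3 or above are significant for sample sizes of 350 or more; a warning is
#' emitted below that regime.
#'
#' @param X3 I x J x K usage tensor.
#' @param labels efficacy labels (factor) or a dummy response matrix.
#' @param ncomp components per significance model (default 2).
#' @param threshold absolute-weight cutoff (inclusive; default 0.3).
#' @param mode \code{"ovr"} (one-vs-rest, default) or \code{"joint"}.  In
#'   joint mode evidence is attributed as \code{max_c |w^K_kc u_lc|}, a
#'   heuristic since a joint model does not give a clean activity-to-class
#'   attribution.
#' @return a \code{significance_matrix}: binary K x L matrix \code{S},
#'   \code{evidence} values and the threshold.
#' @export
activity_significance <- function(X3, labels, ncomp = 2, threshold = 0.3,
                                  mode = c("ovr", "joint")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0)
  Y <- if (is.factor(labels) || is.character(labels)) to_dummy(labels) else as.matrix(labels)
  I <- dim(X3)[1]; K <- dim(X3)[3]; L <- ncol(Y)
  if (I < 350) {
    warning(sprintf(
      "the |weight| >= %.2f significance rule is calibrated for sample sizes of 350 or more (I = %d)",
      threshold, I))
  }
  evidence <- matrix(0, K, L, dimnames = list(dimnames(X3)[[3]], colnames(Y)))
  if (mode == "ovr") {
    for (l in seq_len(L)) {
      fit <- fit_npls(X3, Y[, l, drop = FALSE], ncomp)
      evidence[, l] <- apply(abs(fit$WK), 1, max)
    }
  } else {
    fit <- fit_npls(X3, Y, ncomp)
    for (l in seq_len(L)) {
      evidence[, l] <- apply(abs(fit$WK) * rep(abs(fit$U[l, ]), each = K), 1, max)
    }
  }
  structure(list(S = (evidence >= threshold) * 1, evidence = evidence,
                 threshold = threshold, mode = mode, ncomp = ncomp),
            class = "significance_matrix")
}
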