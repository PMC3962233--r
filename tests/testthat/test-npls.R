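test_that("trilinear double sum equals the Kronecker path on random tensors", {
  set.seed(1)
  for (r in 1:10) {
    I <- sample(4:9, 1); J <- sample(2:5, 1); K <- sample(2:5, 1)
    X3 <- random_tensor(I, J, K)
    wJ <- rnorm(J); wJ <- wJ / sqrt(sum(wJ^2))
    wK <- rnorm(K); wK <- wK / sqrt(sum(wK^2))
    t12 <- vapply(seq_len(I), function(i) sum(X3[i, , ] * outer(wJ, wK)), numeric(1))
    t13 <- drop(matricize(X3) %*% kronecker(wK, wJ))
    expect_equal(t12, t13, tolerance = 1e-10)
  }
})

test_that("corrected weights reproduce sequentially deflated scores", {
  W <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  expect_identical(build_corrected_weights(W[, 1, drop = FALSE]), W[, 1, drop = FALSE])
  expect_equal(build_corrected_weights(W), W, tolerance = 1e-12)  # orthogonal case
  set.seed(2)
  X3 <- random_tensor(12, 4, 3)
  Y <- matrix(rnorm(24), 12, 2)
  fit <- fit_npls(X3, Y, 3)
  Xu <- matricize(X3); Xc <- sweep(Xu, 2, colMeans(Xu))
  expect_lt(max(abs(fit$T - Xc %*% fit$W_tilde)), 1e-8)
  expect_equal(fit$B_npls, fit$W_tilde %*% fit$B_inner, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("unit-norm weights, deterministic signs, monotone Y-residual", {
  set.seed(3)
  X3 <- random_tensor(15, 5, 4)
  Y <- matrix(rnorm(30), 15, 2)
  fit <- fit_npls(X3, Y, 3)
  expect_equal(colSums(fit$WJ^2), rep(1, 3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(colSums(fit$WK^2), rep(1, 3), tolerance = 1e-10, ignore_attr = TRUE)
  for (a in 1:3) expect_gt(fit$WJ[which.max(abs(fit$WJ[, a])), a], 0)
  norms <- vapply(1:3, function(a) sum(fit_npls(X3, Y, a)$F^2), numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
  refit <- fit_npls(X3, Y, 3)
  expect_identical(fit$WJ, refit$WJ)
})

test_that("a noiseless rank-1 tensor is recovered by one component", {
  set.seed(4)
  I <- 20; J <- 6; K <- 5
  a <- rnorm(J); a <- a / sqrt(sum(a^2))
  b <- rnorm(K); b <- b / sqrt(sum(b^2))
  t <- rnorm(I)
  X3 <- outer(outer(t, a), b)
  y <- matrix(t)
  fit <- fit_npls(X3, y, 1)
  expect_gte(abs(sum(fit$WJ[, 1] * a)), 1 - 1e-8)
  expect_gte(abs(sum(fit$WK[, 1] * b)), 1 - 1e-8)
  expect_lt(max(abs(fit$F)), 1e-8)
})

test_that("K = 1 reduces to two-way PLS", {
  set.seed(5)
  X <- matrix(rnorm(14 * 5), 14, 5)
  Y <- matrix(rnorm(14 * 3), 14, 3)
  X3 <- array(X, c(14, 5, 1))
  a <- fit_npls(X3, Y, 3)
  b <- fit_pls(X, Y, 3, deflation = "weights")
  cl <- fit_pls(X, Y, 3)
  expect_equal(a$T, b$T, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(abs(drop(a$WJ)), abs(b$W), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(a$fitted, cl$fitted, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(a$B_npls, cl$B, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("prediction is consistent with the inner regression and centering", {
  set.seed(6)
  X3 <- random_tensor(12, 4, 3, binary = TRUE)
  Y <- to_dummy(factor(sample(c("a", "b"), 12, replace = TRUE)))
  fit <- fit_npls(X3, Y, 2)
  expect_equal(predict(fit, X3),
               fit$T %*% fit$B_inner + rep(colMeans(Y), each = 12),
               tolerance = 1e-8, ignore_attr = TRUE)
  zero_row <- array(0, c(1, 4, 3))
  expect_equal(drop(predict(fit, zero_row)),
               drop(colMeans(Y) - colMeans(matricize(X3)) %*% fit$B_npls),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(predict(fit, array(0, c(1, 4, 2))), "expects")
  expect_error(fit_npls(X3, Y, 40), "ncomp")
})

test_that("separable synthetic data classifies perfectly through the tensor model", {
  sim <- simulate_formulary(tiny_config(p_main = 1, p_support = 0,
                                        p_activity_noise = 0, I = 90, seed = 7))
  X3 <- build_tensor(sim$usage, sim$activity)
  fit <- fit_npls(X3, to_dummy(sim$labels), 2)
  pred <- classify(predict(fit, X3), levels(sim$labels))
  expect_identical(as.character(pred), as.character(sim$labels))
})

test_that("activity significance recovers the specific/general two-group structure", {
  sim <- simulate_formulary(tiny_config(I = 400, seed = 8))
  X3 <- build_tensor(sim$usage, sim$activity)
  sm <- activity_significance(X3, sim$labels, ncomp = 2)
  for (cl in names(sim$truth$specific_activities)) {
    expect_true(all(sm$S[sim$truth$specific_activities[[cl]], cl] == 1))
  }
  gen_hits <- rowSums(sm$S[sim$truth$general_activities, , drop = FALSE])
  expect_true(all(gen_hits >= 2))
  # inclusive threshold: evidence exactly at the cutoff is significant
  ev <- max(sm$evidence)
  sm_at <- activity_significance(X3, sim$labels, ncomp = 2, threshold = ev)
  expect_identical(max(sm_at$S[sm_at$evidence == ev]), 1)
  # warning below the stated validity regime
  expect_warning(activity_significance(build_tensor(sim$usage[1:100, ], sim$activity),
                                       sim$labels[1:100], ncomp = 1),
                 "350")
})
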