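test_that("first component matches the closed-form weight for a single y", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4); y <- matrix(rnorm(10))
  fit <- fit_pls(X, y, 1)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  w <- crossprod(Xc, yc); w <- w / sqrt(sum(w^2))
  expect_equal(unname(fit$W[, 1]), drop(w), tolerance = 1e-12)
  expect_equal(unname(fit$T[, 1]), drop(Xc %*% w), tolerance = 1e-12)
})

test_that("full-component PLS reproduces OLS and exact linear maps", {
  set.seed(2)
  for (r in 1:5) {
    n <- sample(8:15, 1); m <- sample(3:6, 1); p <- sample(1:3, 1)
    X <- matrix(rnorm(n * m), n, m); Y <- matrix(rnorm(n * p), n, p)
    fit <- fit_pls(X, Y, m)
    expect_equal(fit$fitted, ols_fitted(X, Y), tolerance = 1e-8, ignore_attr = TRUE)
  }
  # noiseless linear response is fitted exactly at full rank
  X <- matrix(rnorm(60), 12, 5)
  Y <- X %*% matrix(rnorm(10), 5, 2)
  fit <- fit_pls(X, Y, 5)
  expect_lt(max(abs(fit$F)), 1e-8)
})

test_that("NIPALS invariants: orthogonal scores, two coefficient paths, monotone residual", {
  set.seed(3)
  X <- matrix(rnorm(120), 20, 6); Y <- matrix(rnorm(60), 20, 3)
  fit <- fit_pls(X, Y, 5)
  G <- crossprod(fit$T)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * sum(diag(G)))
  # corrected-weight coefficients vs accumulated per-component regressions
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  expect_equal(Xc %*% fit$R, fit$T, tolerance = 1e-10, ignore_attr = TRUE)
  acc <- matrix(0, nrow(X), 3)
  for (a in 1:5) acc <- acc + fit$T[, a] %*% t(fit$Q[, a])
  expect_equal(Xc %*% fit$B, acc, tolerance = 1e-10, ignore_attr = TRUE)
  # Y-residual norm never increases with more components
  norms <- vapply(1:5, function(a) {
    f <- fit_pls(X, Y, a); sqrt(sum((sweep(f$fitted, 2, colMeans(Y)) - Yc)^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
  # training predictions equal T Q' + Y-means under classic deflation
  expect_equal(predict(fit, X),
               fit$T %*% t(fit$Q) + rep(colMeans(Y), each = 20),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("deflation conventions agree on fitted values but not score paths", {
  set.seed(4)
  X <- matrix(rnorm(90), 15, 6); Y <- matrix(rnorm(45), 15, 3)
  a <- fit_pls(X, Y, 3, deflation = "loadings")
  b <- fit_pls(X, Y, 3, deflation = "weights")
  expect_equal(a$fitted, b$fitted, tolerance = 1e-8)
  expect_equal(a$B, b$B, tolerance = 1e-8)        # X has full column rank
  expect_gt(max(abs(a$T[, 3] - b$T[, 3])), 1e-6)  # the paths genuinely differ
})

test_that("prediction centers correctly and checks shapes", {
  set.seed(5)
  X <- matrix(rnorm(50), 10, 5); Y <- matrix(rnorm(20), 10, 2)
  fit <- fit_pls(X, Y, 2)
  expect_equal(drop(predict(fit, matrix(colMeans(X), 1))), colMeans(Y),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(predict(fit, X[, 1:3]), "columns")
  expect_error(fit_pls(X, Y, 20), "ncomp")
  expect_error(fit_pls(X, matrix(1, 10, 2), 2), "variance")
})

test_that("classify takes the row argmax with ties to the lower index", {
  Yh <- rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0.0))
  colnames(Yh) <- c("a", "b", "c")
  expect_identical(as.character(classify(Yh)), c("b", "a"))
})

test_that("separable synthetic data is classified perfectly in training", {
  sim <- simulate_formulary(tiny_config(p_main = 1, p_support = 0, I = 90, seed = 6))
  fit <- fit_plsda(sim$usage, sim$labels, 2)
  expect_identical(as.character(predict(fit, sim$usage)), as.character(sim$labels))
})

test_that("confusion matrices compute per-class and overall percents", {
  cm <- confusion_from_counts(diag(c(3, 4, 5)), c("a", "b", "c"))
  expect_true(all(cm$per_class_percent_correct == 100))
  expect_equal(cm$overall_percent_correct, 100)
  obs <- factor(c("a", "a", "b", "b"), levels = c("a", "b"))
  prd <- factor(c("a", "b", "b", "b"), levels = c("a", "b"))
  cm2 <- confusion(obs, prd)
  expect_identical(unname(cm2$counts["a", ]), c(1L, 1L))
  expect_equal(cm2$overall_percent_correct, 75)
  expect_error(confusion(obs, prd[1:3]), "equal length")
  expect_error(confusion(obs, factor(c("a", "z", "b", "b"))), "outside")
  # round trip through the table layout
  path <- withr::local_tempfile(fileext = ".tsv")
  write_confusion(cm2, path)
  back <- read_confusion(path)
  expect_equal(back$counts, cm2$counts, ignore_attr = TRUE)
  expect_equal(back$overall_percent_correct, cm2$overall_percent_correct)
})

test_that("cross-validation and component selection run deterministically", {
  sim <- simulate_formulary(tiny_config(I = 120, seed = 7))
  a <- cv_plsda(sim$usage, sim$labels, 2, folds = 4, seed = 3)
  b <- cv_plsda(sim$usage, sim$labels, 2, folds = 4, seed = 3)
  expect_identical(a$accuracy, b$accuracy)
  sel <- select_ncomp(sim$usage, sim$labels, max_comp = 3, folds = 4, seed = 3)
  expect_true(sel$ncomp %in% 1:3)
  expect_equal(sel$accuracy[sel$ncomp], max(sel$accuracy))
})
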