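test_that("a single proportional feature is fit exactly with one component", {
  set.seed(1)
  x <- runif(20, 1, 3)
  y <- 4 * x
  m <- plsFit(cbind(x), y, 1)
  expect_equal(plsPredict(m, cbind(x)), y, tolerance = 1e-10)
  expect_equal(r2(y, plsPredict(m, cbind(x))), 1, tolerance = 1e-10)
})

test_that("full-component PLS equals ordinary least squares", {
  set.seed(2)
  X <- matrix(rnorm(20 * 5), 20)
  y <- rnorm(20)
  m <- plsFit(X, y, 5)
  ols <- lm(y ~ X)
  expect_equal(plsPredict(m, X), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("pure-noise responses cross-validate near zero R-squared", {
  set.seed(3)
  X <- matrix(rnorm(200 * 8), 200)
  y <- rnorm(200)
  sel <- selectNLv(X, y, max_lv = 1, folds = 10, seed = 4)
  expect_lt(r2(y, sel$cv_pred), 0.1)
})

test_that("prediction is the stored affine map of standardized inputs", {
  set.seed(5)
  X <- matrix(rnorm(25 * 6), 25)
  y <- rnorm(25)
  m <- plsFit(X, y, 3)
  ## rows at the training means predict exactly the training y mean
  expect_equal(plsPredict(m, rbind(m@x_mean, m@x_mean)),
               rep(mean(y), 2), tolerance = 1e-10)
  ## explicit matrix-product oracle
  Xs <- sweep(sweep(X, 2, m@x_mean), 2, m@x_std, "/")
  expect_equal(plsPredict(m, X),
               drop(m@y_mean + m@y_std * Xs %*% m@coefficients),
               tolerance = 1e-12)
  ## repeated application is bit-stable
  expect_identical(plsPredict(m, X), plsPredict(m, X))
  expect_error(plsPredict(m, X[, 1:4]), "expects")
})

test_that("kernel PLS from cross-products matches NIPALS and OLS limits", {
  set.seed(6)
  X <- matrix(rnorm(30 * 10), 30)
  y <- rnorm(30)
  xs <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, xs, "/")
  ys <- (y - mean(y)) / sd(y)
  XtX <- crossprod(Xs); Xty <- drop(crossprod(Xs, ys))
  for (a in c(1, 3)) {
    m <- plsFit(X, y, a)
    expect_equal(plsFromCrossproducts(XtX, Xty, a), m@coefficients,
                 tolerance = 1e-8)
  }
  ## full component count reduces to the normal-equation solve
  expect_equal(plsFromCrossproducts(XtX, Xty, 10),
               drop(solve(XtX, Xty)), tolerance = 1e-8)
  ## orthonormal design, one component: coefficients proportional to Xty
  b1 <- plsFromCrossproducts(diag(4), c(2, 1, 0, -1), 1)
  expect_equal(b1 / sqrt(sum(b1^2)), c(2, 1, 0, -1) / sqrt(6),
               tolerance = 1e-10)
  expect_error(plsFromCrossproducts(matrix(rnorm(16), 4), Xty[1:4], 1),
               "symmetric")
})

test_that("RMSECV selects the generating rank and ties go small", {
  set.seed(7)
  n <- 80
  T2 <- matrix(rnorm(n * 2), n)          # two latent factors
  P <- matrix(rnorm(2 * 12), 2)
  X <- T2 %*% P + matrix(rnorm(n * 12, 0, 0.05), n)
  y <- T2 %*% c(1, -2) + rnorm(n, 0, 0.2)
  sel <- selectNLv(X, drop(y), max_lv = 6, folds = 10, seed = 8)
  expect_equal(sel$n_lv, 2L)
  expect_true(all(sel$rmsecv >= 0))

  ## perfect one-factor data: RMSECV at 1 LV is ~0 and 1 is selected
  x1 <- runif(30, 1, 2)
  sel1 <- selectNLv(cbind(x1, 2 * x1), 5 * x1, max_lv = 2, folds = 5,
                    seed = 9)
  expect_equal(sel1$n_lv, 1L)
  expect_lt(sel1$rmsecv[1], 1e-8)
})

test_that("fit validates ranks, variance and dimensions", {
  set.seed(10)
  X <- matrix(rnorm(10 * 4), 10)
  expect_error(plsFit(X, rnorm(10), 11), "exceeds")
  Xz <- X; Xz[, 3] <- 2
  expect_error(plsFit(Xz, rnorm(10), 2), "column 3 has zero variance")
  expect_error(selectNLv(X, rnorm(10), max_lv = 9, folds = 5), "infeasible")
})

test_that("predictions scale with the response and scores are orthogonal", {
  set.seed(11)
  X <- matrix(rnorm(30 * 8), 30)
  y <- rnorm(30)
  m1 <- plsFit(X, y, 3)
  m2 <- plsFit(X, 10 * y, 3)
  expect_equal(plsPredict(m2, X), 10 * plsPredict(m1, X), tolerance = 1e-9)

  ## deflation orthogonality of the extracted score vectors
  xs <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, xs, "/")
  fit <- nircal:::nipalsCore(Xs, (y - mean(y)) / sd(y), 4)
  E <- Xs
  Tm <- matrix(0, 30, fit$n_lv)
  for (a in seq_len(fit$n_lv)) {
    Tm[, a] <- E %*% fit$W[, a]
    E <- E - tcrossprod(Tm[, a], fit$P[, a])
  }
  G <- crossprod(Tm)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})
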