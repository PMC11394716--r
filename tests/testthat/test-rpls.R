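test_that("the initial state reproduces the offline PLS model", {
  set.seed(1)
  X <- matrix(rnorm(30 * 6), 30)
  y <- rnorm(30)
  st <- rplsInit(X, y, n_lv = 3)
  expect_equal(st@N, 30L)
  m_off <- plsFit(X, y, 3)
  m_rec <- rplsCoefficients(st)
  expect_equal(m_rec@coefficients, m_off@coefficients, tolerance = 1e-8)
  expect_equal(plsPredict(m_rec, X), plsPredict(m_off, X), tolerance = 1e-8)

  ## single feature proportional to y: both cross-products equal N - 1
  x1 <- runif(12, 1, 2)
  st1 <- rplsInit(cbind(x1), 3 * x1, n_lv = 1)
  expect_equal(drop(st1@XtX), 11, tolerance = 1e-10)
  expect_equal(st1@Xty, 11, tolerance = 1e-10)
})

test_that("the mean recursion tracks the batch mean exactly at every step", {
  set.seed(2)
  X <- matrix(rnorm(10 * 4), 10)
  y <- rnorm(10)
  st <- rplsInit(X[1:4, ], y[1:4], n_lv = 2)
  for (t in 5:10) {
    st <- rplsUpdate(st, X[t, ], y[t])
    expect_equal(st@x_mean, colMeans(X[1:t, ]), tolerance = 1e-12)
    expect_equal(st@y_mean, mean(y[1:t]), tolerance = 1e-12)
    expect_equal(st@N, t)
  }
})

test_that("frozen-moment recursion at lambda 1 equals batch cross-products", {
  set.seed(3)
  Xc <- matrix(rnorm(20 * 5), 20)
  yc <- rnorm(20)
  st <- rplsInit(Xc, yc, n_lv = 2, lam = 1)
  Xnew <- matrix(rnorm(7 * 5), 7)
  ynew <- rnorm(7)
  st2 <- st
  for (t in 1:7) st2 <- rplsUpdate(st2, Xnew[t, ], ynew[t],
                                   freeze_moments = TRUE)
  ## oracle: stack the new block standardized with the frozen moments
  Xs <- sweep(sweep(Xnew, 2, st@x_mean), 2, st@x_std, "/")
  ys <- (ynew - st@y_mean) / st@y_std
  expect_equal(st2@XtX, st@XtX + crossprod(Xs), tolerance = 1e-12)
  expect_equal(st2@Xty, st@Xty + drop(crossprod(Xs, ys)), tolerance = 1e-12)
  expect_equal(st2@N, 27L)
})

test_that("forgetting weights history by the unrolled geometric sum", {
  set.seed(4)
  Xc <- matrix(rnorm(15 * 4), 15)
  yc <- rnorm(15)
  lam <- 0.5
  st <- rplsInit(Xc, yc, n_lv = 2, lam = lam)
  XtX0 <- st@XtX; Xty0 <- st@Xty
  Xnew <- matrix(rnorm(6 * 4), 6)
  ynew <- rnorm(6)
  st2 <- st
  for (t in 1:6) st2 <- rplsUpdate(st2, Xnew[t, ], ynew[t],
                                   freeze_moments = TRUE)
  Xs <- sweep(sweep(Xnew, 2, st@x_mean), 2, st@x_std, "/")
  ys <- (ynew - st@y_mean) / st@y_std
  XtX_or <- lam^6 * XtX0
  Xty_or <- lam^6 * Xty0
  for (t in 1:6) {
    XtX_or <- XtX_or + lam^(6 - t) * tcrossprod(Xs[t, ])
    Xty_or <- Xty_or + lam^(6 - t) * Xs[t, ] * ys[t]
  }
  expect_equal(st2@XtX, XtX_or, tolerance = 1e-10)
  expect_equal(st2@Xty, Xty_or, tolerance = 1e-10)

  ## near-total forgetting: one update leaves essentially only the new sample
  sttiny <- rplsInit(Xc, yc, n_lv = 2, lam = 1e-9)
  sttiny <- rplsUpdate(sttiny, Xnew[1, ], ynew[1], freeze_moments = TRUE)
  expect_equal(sttiny@XtX, tcrossprod(Xs[1, ]), tolerance = 1e-6)
  ## and lambda outside (0, 1] is rejected
  expect_error(rplsInit(Xc, yc, n_lv = 2, lam = 0), "\\(0, 1\\]")
  expect_error(rplsInit(Xc, yc, n_lv = 2, lam = 1.1), "\\(0, 1\\]")
})

test_that("replaying the calibration block doubles into the same model", {
  set.seed(5)
  Xc <- matrix(rnorm(18 * 5), 18)
  yc <- rnorm(18)
  st <- rplsInit(Xc, yc, n_lv = 2, lam = 1)
  for (t in 1:18) st <- rplsUpdate(st, Xc[t, ], yc[t], freeze_moments = TRUE)
  m_double <- plsFit(rbind(Xc, Xc), c(yc, yc), 2)
  m_state <- rplsCoefficients(st)
  expect_equal(plsPredict(m_state, Xc), plsPredict(m_double, Xc),
               tolerance = 1e-8)
})

test_that("the printed variance recursion differs from the exact one as documented", {
  set.seed(6)
  X <- matrix(rnorm(12 * 3), 12)
  y <- rnorm(12)
  ex <- rplsInit(X[1:6, ], y[1:6], n_lv = 1, exact_variance = TRUE)
  pr <- rplsInit(X[1:6, ], y[1:6], n_lv = 1, exact_variance = FALSE)
  for (t in 7:12) {
    ex <- rplsUpdate(ex, X[t, ], y[t])
    pr <- rplsUpdate(pr, X[t, ], y[t])
    ## exact mode reproduces the batch sample standard deviation
    expect_equal(ex@x_std, apply(X[1:t, ], 2, sd), tolerance = 1e-12)
    expect_equal(ex@y_std, sd(y[1:t]), tolerance = 1e-12)
  }
  ## the as-printed recursion overstates the spread (1/(N-1) innovation term)
  expect_true(all(pr@x_std > ex@x_std))
})

test_that("updates validate dimensions and finiteness", {
  set.seed(7)
  st <- rplsInit(matrix(rnorm(20), 10), rnorm(10), n_lv = 1)
  expect_error(rplsUpdate(st, c(1, 2, 3), 1), "features")
  expect_error(rplsUpdate(st, c(1, NA), 1), "non-finite")
  expect_error(rplsUpdate(st, c(1, 2), Inf), "non-finite")
  st2 <- rplsUpdate(st, c(1, 2), 1)
  expect_equal(st2@update_log$N, 11L)
  m <- rplsCoefficients(st2)
  expect_true(all(is.finite(plsPredict(m, matrix(rnorm(10), 5)))))
})

test_that("online coefficients approach the batch refit on a drift-free stream", {
  set.seed(8)
  n <- 100; p <- 6
  B <- rnorm(p)
  X <- matrix(rnorm(n * p), n)
  y <- drop(X %*% B) + rnorm(n, 0, 0.1)
  st <- rplsInit(X[1:30, ], y[1:30], n_lv = p, lam = 1)
  dist <- function(st, t) {
    mb <- plsFit(X[1:t, ], y[1:t], p)
    ms <- rplsCoefficients(st)
    sqrt(sum((plsPredict(ms, X) - plsPredict(mb, X))^2))
  }
  d10 <- NULL; d70 <- NULL
  for (t in 31:100) {
    st <- rplsUpdate(st, X[t, ], y[t])
    if (t == 40) d10 <- dist(st, t)
    if (t == 100) d70 <- dist(st, t)
  }
  expect_lt(d70, d10)
})
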