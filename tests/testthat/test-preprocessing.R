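test_that("the MSC reference is the per-channel arithmetic mean", {
  one <- randomSpectra(1, 20)
  ref <- mscFit(one)
  expect_equal(ref@mean_spectrum, as.numeric(absorbance(one)))
  expect_equal(ref@n, 1L)

  v <- rnorm(20)
  sym <- SpectraSet(rbind(v, -v), seq(900, 1700, length.out = 20))
  expect_equal(mscFit(sym)@mean_spectrum, rep(0, 20))

  X <- absorbance(randomSpectra(10, 20, seed = 3))
  ## direct-summation oracle
  oracle <- vapply(1:20, function(j) sum(X[, j]) / 10, numeric(1))
  expect_equal(mscFit(randomSpectra(10, 20, seed = 3))@mean_spectrum, oracle,
               tolerance = 1e-12)
})

test_that("MSC correction inverts exact affine scatter", {
  ref <- mscFit(randomSpectra(5, 30, seed = 4))
  refv <- ref@mean_spectrum
  grid <- seq(900, 1700, length.out = 30)

  ## identical to the reference: a = 1, b = 0, unchanged
  r1 <- mscCorrect(SpectraSet(refv, grid), ref)
  expect_equal(r1$params$slope, 1, tolerance = 1e-12)
  expect_equal(r1$params$intercept, 0, tolerance = 1e-12)
  expect_equal(as.numeric(absorbance(r1$corrected)), refv, tolerance = 1e-12)

  ## exact affine case recovers a = 2, b = 3 and corrects back to the mean
  r2 <- mscCorrect(SpectraSet(2 * refv + 3, grid), ref)
  expect_equal(r2$params$slope, 2, tolerance = 1e-12)
  expect_equal(r2$params$intercept, 3, tolerance = 1e-12)
  expect_equal(as.numeric(absorbance(r2$corrected)), refv, tolerance = 1e-12)
})

test_that("MSC slopes and intercepts match the closed-form OLS oracle", {
  set <- randomSpectra(5, 30, seed = 9)
  ref <- mscFit(set)
  res <- mscCorrect(set, ref)
  for (i in 1:5) {
    ab <- olsOracle(absorbance(set)[i, ], ref@mean_spectrum)
    expect_equal(res$params$slope[i], unname(ab["a"]), tolerance = 1e-10)
    expect_equal(res$params$intercept[i], unname(ab["b"]), tolerance = 1e-10)
    expect_equal(absorbance(res$corrected)[i, ],
                 (absorbance(set)[i, ] - ab["b"]) / ab["a"],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("MSC refuses a constant reference and flags near-zero slopes", {
  grid <- seq(900, 1700, length.out = 10)
  const_ref <- ReferenceSpectrum(rep(1, 10), 3)
  expect_error(mscCorrect(randomSpectra(2, 10), const_ref), "constant")
  ## a constant sample has zero covariance with any reference: slope ~ 0
  ref <- mscFit(randomSpectra(4, 10, seed = 2))
  expect_warning(res <- mscCorrect(SpectraSet(rep(5, 10), grid), ref),
                 "flagged")
  expect_true(res$params$flagged[1])
  expect_equal(as.numeric(absorbance(res$corrected)), rep(5, 10))
})

test_that("OMSC update has the running-mean fixed point", {
  ref <- mscFit(randomSpectra(6, 25, seed = 5))
  up <- omscUpdate(ref, ref@mean_spectrum)
  expect_equal(up$reference@mean_spectrum, ref@mean_spectrum, tolerance = 1e-12)
  expect_equal(up$reference@n, 7L)
  expect_equal(up$params$slope, 1, tolerance = 1e-12)
  expect_equal(up$params$intercept, 0, tolerance = 1e-12)
  expect_equal(up$corrected, ref@mean_spectrum, tolerance = 1e-12)
})

test_that("streaming the reference reproduces the batch mean exactly", {
  set.seed(8)
  X <- matrix(rnorm(12 * 40), 12)
  ref <- ReferenceSpectrum(X[1, ], 1)
  for (i in 2:12) ref <- omscUpdate(ref, X[i, ])$reference
  expect_equal(ref@mean_spectrum, colMeans(X), tolerance = 1e-13)
  expect_equal(ref@n, 12L)
})

test_that("every reference shift obeys the pairwise-deviation bound", {
  set.seed(13)
  X <- matrix(rnorm(30 * 20), 30)
  ## brute-force E: max absolute deviation over all sample pairs and channels
  E <- 0
  for (i in 1:29) for (j in (i + 1):30)
    E <- max(E, max(abs(X[i, ] - X[j, ])))
  ref <- ReferenceSpectrum(X[1, ], 1)
  for (i in 2:30) {
    up <- omscUpdate(ref, X[i, ])
    expect_lt(up$reference_shift, E / (ref@n + 1))
    ref <- up$reference
  }
})

test_that("OMSC correction converges to batch MSC as the stream grows", {
  set.seed(17)
  p <- 40
  mu <- sin(seq(0, 3, length.out = p)) + 2
  draw <- function(n) mu[col(matrix(0, n, p))] + matrix(rnorm(n * p, 0, .05), n)
  probe <- mu + rnorm(p, 0, 0.05)
  gaps <- vapply(c(10, 100, 1000), function(n) {
    X <- draw(n)
    ref <- ReferenceSpectrum(probe, 1)      # initialized off the probe
    for (i in seq_len(n)) ref <- omscUpdate(ref, X[i, ])$reference
    omsc <- omscUpdate(ref, probe)$corrected
    ## batch MSC of the probe against the plain stream mean
    ab <- olsOracle(probe, colMeans(X))
    batch <- (probe - ab["b"]) / ab["a"]
    max(abs(omsc - batch))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))          # monotone-decreasing envelope
  expect_lt(gaps[3], gaps[1] / 10)          # decays like O(1/n), not slower
})

test_that("Savitzky-Golay smoothing reproduces polynomials and is linear", {
  grid <- seq(900, 1700, length.out = 50)
  expect_equal(sgSmooth(rep(2, 50), 11, 2), rep(2, 50), tolerance = 1e-12)
  q <- 0.01 * (1:50)^2 - 3 * (1:50) + 7
  expect_equal(sgSmooth(q, 11, 2), q, tolerance = 1e-10)
  u <- rnorm(50); v <- rnorm(50)
  expect_equal(sgSmooth(2 * u - 3 * v, 11, 2),
               2 * sgSmooth(u, 11, 2) - 3 * sgSmooth(v, 11, 2),
               tolerance = 1e-10)
})

test_that("interior smoothing equals a sliding-window least-squares fit", {
  set.seed(23)
  x <- rnorm(60)
  sm <- sgSmooth(x, 11, 2)
  for (i in 6:55) {
    idx <- (i - 5):(i + 5)
    fit <- lm(x[idx] ~ idx + I(idx^2))
    expect_equal(sm[i], unname(predict(fit, data.frame(idx = i))),
                 tolerance = 1e-10)
  }
  ## per-sample independence: smoothing a set equals smoothing each row
  set <- randomSpectra(3, 60, seed = 23)
  smset <- sgSmooth(set, 11, 2)
  for (i in 1:3)
    expect_equal(absorbance(smset)[i, ], sgSmooth(absorbance(set)[i, ], 11, 2))
})

test_that("Savitzky-Golay validates window and order", {
  x <- rnorm(30)
  expect_error(sgSmooth(x, 10, 2), "odd")
  expect_error(sgSmooth(x, 5, 5), "exceed")
  expect_error(sgSmooth(x, 31, 2), "channel count")
})
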