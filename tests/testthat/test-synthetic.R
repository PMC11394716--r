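test_that("component library peaks land where requested", {
  cfg <- oneComponentConfig()
  lib <- generateComponentLibrary(cfg)
  expect_equal(dim(lib$library), c(1L, 64L))
  expect_equal(which.max(lib$library[1, ]),
               which.min(abs(lib$wavelengths - 1200)))
  ## the analyte's informative bands sit within one sd of the peak
  expect_true(all(abs(lib$wavelengths[lib$informative_bands] - 1200) <= 30))
})

test_that("component library rejects degenerate peak definitions", {
  expect_error(generateComponentLibrary(
    oneComponentConfig(peak_widths = list(0))), "widths must be > 0")
  expect_error(generateComponentLibrary(
    oneComponentConfig(peak_centers = list(2000))), "outside")
})

test_that("generation is bit-identical under one seed", {
  cfg <- smallConfig(seed = 7L)
  expect_identical(generateComponentLibrary(cfg),
                   generateComponentLibrary(cfg))
  s1 <- generateStudy(cfg)
  s2 <- generateStudy(cfg)
  expect_identical(absorbance(s1@offline), absorbance(s2@offline))
  expect_identical(absorbance(s1@online_stream), absorbance(s2@online_stream))
  expect_identical(s1@truth, s2@truth)
  ## a different seed changes the draw
  expect_false(identical(absorbance(s1@offline),
                         absorbance(generateStudy(smallConfig(seed = 8L))@offline)))
})

test_that("noise-free spectra equal concentrations x library plus baseline", {
  cfg <- oneComponentConfig(scatter_slope_sd = 0, scatter_offset_sd = 0,
                            noise_sd_base = 0, noise_sd_highband = 0)
  b <- generateBatch(cfg, 6L, seed = 3L)
  ## with all randomness off, observed == ideal (a = 1, b = 0, no noise)
  expect_identical(absorbance(b$spectra), b$ideal)
  expect_true(all(b$truth$a == 1) && all(b$truth$b == 0))
  ## single component: spectrum differences are exactly proportional to the
  ## analyte difference times the component spectrum
  K <- generateComponentLibrary(cfg)$library[1, ]
  y <- refValues(b$spectra)
  X <- absorbance(b$spectra)
  expect_equal(X[1, ] - X[2, ], (y[1] - y[2]) / 100 * K, tolerance = 1e-12)
})

test_that("per-sample regression on the ideal spectrum recovers the scatter truth", {
  cfg <- smallConfig(noise_sd_base = 0, noise_sd_highband = 0)
  b <- generateBatch(cfg, 8L, seed = 5L)
  for (i in 1:8) {
    fit <- lm(absorbance(b$spectra)[i, ] ~ b$ideal[i, ])
    expect_equal(unname(coef(fit)[2]), b$truth$a[i], tolerance = 1e-8)
    expect_equal(unname(coef(fit)[1]), b$truth$b[i], tolerance = 1e-8)
  }
})

test_that("analyte signal sits on the true fat bands and follows y", {
  cfg <- smallConfig(noise_sd_base = 0, noise_sd_highband = 0,
                     scatter_slope_sd = 0, scatter_offset_sd = 0)
  b <- generateBatch(cfg, 200L, seed = 11L)
  bands <- generateComponentLibrary(cfg)$informative_bands
  sig <- rowMeans(absorbance(b$spectra)[, bands, drop = FALSE])
  expect_gt(cor(refValues(b$spectra), sig), 0.99)
  ## permuting y across samples destroys the association
  set.seed(42)
  expect_lt(abs(cor(sample(refValues(b$spectra)), sig)), 0.2)
})

test_that("default study mirrors the 120 offline / 75 online design", {
  study <- generateStudy(simConfig(seed = 2L))
  expect_equal(nSamples(study@offline), 120L)
  expect_equal(nSamples(study@online_stream), 75L)
  expect_equal(nChannels(study@offline), 512L)
  expect_identical(wavelengths(study@offline), wavelengths(study@online_stream))
  expect_equal(nrow(study@truth$online), 75L)
})

test_that("zero drift draws offline and online from one distribution", {
  cfg <- smallConfig()
  b1 <- generateBatch(cfg, 500L, drift = NULL, seed = 21L)
  b2 <- generateBatch(cfg, 500L, drift = driftNone(), seed = 22L)
  ## Monte-Carlo agreement of channel means and analyte means at n = 500
  se <- apply(absorbance(b1$spectra), 2L, sd) / sqrt(500)
  gap <- abs(colMeans(absorbance(b1$spectra)) - colMeans(absorbance(b2$spectra)))
  expect_true(all(gap < 5 * se))
  expect_lt(abs(mean(refValues(b1$spectra)) - mean(refValues(b2$spectra))), 1)
})

test_that("batch generation validates its inputs", {
  cfg <- smallConfig()
  expect_error(generateBatch(cfg, 0L), ">= 1")
  expect_error(simConfig(scatter_slope_sd = -1), ">= 0")
  expect_error(simConfig(y_range = c(70, 55)), "y_range")
  expect_error(simConfig(wl_min = 1800, wl_max = 1700), "wl_min")
})

test_that("the drifted stream is progressive and the new batch is end-stage", {
  cfg <- smallConfig(seed = 31L)
  study <- generateStudy(cfg)
  g <- study@truth$online$g
  ## ramp: later samples carry more drift
  expect_gt(mean(g[11:20]), mean(g[1:10]))
  nb <- generateNewBatch(cfg, 10L)
  expect_true(all(nb$truth$g >= 1.6 & nb$truth$g <= 2.0))
})
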