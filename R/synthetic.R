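#' Configure the synthetic NIR study generator
#'
#' Builds a \linkS4class{SimConfig} describing a simulated NIR experiment:
#' a wavelength grid, a small library of pure absorbers (one of which is the
#' analyte, "fat"), the analyte range, per-sample multiplicative/additive
#' scatter, heteroscedastic detector noise concentrated toward the
#' long-wavelength end, and a systematic drift applied to the online stream.
#'
#' Spectra follow a Beer-Lambert-style mixture: ideal absorbance is the
#' concentration-weighted sum of Gaussian-peak component spectra plus a smooth
#' low-order polynomial baseline; the observed spectrum is
#' \code{a_i * ideal + b_i + noise} with per-sample scatter slope
#' \code{a_i ~ 1 + N(0, scatter_slope_sd)} and offset
#' \code{b_i ~ N(0, scatter_offset_sd)}. Noise sd is \code{noise_sd_base}
#' below \code{highband_start} nm and \code{noise_sd_highband} at or above it.
#'
#' @param n_channels number of wavelength channels (default 512).
#' @param wl_min,wl_max grid limits in nm (defaults 900, 1700).
#' @param peak_centers,peak_widths,peak_amplitudes lists, one numeric vector
#'   per component: Gaussian centers (nm), standard deviations (nm), heights.
#' @param fat_component which component carries the analyte signal.
#' @param y_range analyte range, % by mass.
#' @param scatter_slope_sd,scatter_offset_sd scatter magnitudes.
#' @param noise_sd_base,noise_sd_highband,highband_start noise model.
#' @param batch_drift list(baseline_shift, baseline_tilt, slope_shift,
#'   offset_shift, y_shift): additive baseline shift (flat and linearly
#'   increasing across the grid, absorbance units), shifts of the scatter
#'   slope/offset means, and an additive shift of the analyte distribution
#'   (% by mass) for the online stream.
#' @param n_offline,n_online default study sizes (120 and 75).
#' @param seed master seed; all generator randomness derives from it.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1)
#' study <- generateStudy(cfg)
#' @export
simConfig <- function(n_channels = 512L, wl_min = 900, wl_max = 1700,
                      peak_centers = list(c(1210, 1360), c(970, 1460),
                                          c(1020, 1540), c(1100, 1620)),
                      peak_widths = list(c(20, 20), c(25, 30),
                                         c(30, 30), c(40, 40)),
                      peak_amplitudes = list(c(0.9, 0.7), c(0.08, 0.12),
                                             c(0.06, 0.08), c(0.05, 0.06)),
                      fat_component = 1L,
                      y_range = c(55, 75),
                      scatter_slope_sd = 0.08, scatter_offset_sd = 0.03,
                      noise_sd_base = 0.004, noise_sd_highband = 0.01,
                      highband_start = 1500,
                      batch_drift = driftDefault(),
                      n_offline = 120L, n_online = 75L, seed = 1L) {
  cfg <- new("SimConfig",
    n_channels = assertCount(n_channels, "n_channels", min = 2L),
    wl_min = assertScalar(wl_min, "wl_min"),
    wl_max = assertScalar(wl_max, "wl_max"),
    n_components = length(peak_centers),
    peak_centers = lapply(peak_centers, as.numeric),
    peak_widths = lapply(peak_widths, as.numeric),
    peak_amplitudes = lapply(peak_amplitudes, as.numeric),
    fat_component = assertCount(fat_component, "fat_component"),
    y_range = as.numeric(y_range),
    scatter_slope_sd = assertScalar(scatter_slope_sd, "scatter_slope_sd", 0),
    scatter_offset_sd = assertScalar(scatter_offset_sd, "scatter_offset_sd", 0),
    noise_sd_base = assertScalar(noise_sd_base, "noise_sd_base", 0),
    noise_sd_highband = assertScalar(noise_sd_highband, "noise_sd_highband", 0),
    highband_start = assertScalar(highband_start, "highband_start"),
    batch_drift = batch_drift,
    n_offline = assertCount(n_offline, "n_offline"),
    n_online = assertCount(n_online, "n_online"),
    seed = assertCount(seed, "seed", min = 0L))
  validObject(cfg)
  cfg
}

#' Batch-drift structures
#'
#' \code{driftDefault} is the study default: a flat + tilted baseline shift,
#' a shift of the scatter-parameter means and a downward shift of the analyte
#' distribution, together strong enough that a frozen offline model visibly
#' degrades on the online stream. \code{driftNone} disables all drift.
#'
#' @return A named list understood by \code{generateBatch}.
#' @export
driftDefault <- function() {
  list(baseline_shift = 0.20, baseline_tilt = 0.70, baseline_curve = 2.20,
       slope_shift = 0.12, offset_shift = 0.05, y_shift = -2,
       spread = 0.2)
}

#' @rdname driftDefault
#' @export
driftNone <- function() {
  list(baseline_shift = 0, baseline_tilt = 0, baseline_curve = 0,
       slope_shift = 0, offset_shift = 0, y_shift = 0, spread = 0)
}

simGrid <- function(config) {
  seq(config@wl_min, config@wl_max, length.out = config@n_channels)
}

## Smooth background absorbance common to all samples; u in [0, 1].
## A low-order polynomial plus broad static matrix-absorption bands: in
## diffuse-reflectance NIR the bulk sample matrix dominates the mean
## spectrum, and analyte-driven deviations ride on top of it. The dominant
## static structure also keeps the MSC slope estimate from turning into a
## spurious analyte proxy (see the methods vignette).
simBaseline <- function(u) {
  wl <- 900 + 800 * u
  0.4 + 0.2 * u +
    1.0 * exp(-(wl - 1150)^2 / (2 * 150^2)) +
    0.8 * exp(-(wl - 1650)^2 / (2 * 100^2)) +
    0.6 * exp(-(wl - 950)^2 / (2 * 80^2))
}

#' Pure-component spectra library
#'
#' Each component spectrum is a sum of Gaussian peaks on the wavelength grid.
#' The component designated \code{fat_component} is the analyte; the channels
#' within one peak standard deviation of each of its peak centers are the
#' study's true informative bands.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A list with \code{library} (components x channels matrix),
#'   \code{wavelengths}, and \code{informative_bands} (integer indices).
#' @export
generateComponentLibrary <- function(config) {
  stopifnot(is(config, "SimConfig"))
  wl <- simGrid(config)
  K <- matrix(0, config@n_components, config@n_channels)
  for (c in seq_len(config@n_components)) {
    centers <- config@peak_centers[[c]]
    widths <- config@peak_widths[[c]]
    amps <- config@peak_amplitudes[[c]]
    stopIfNot(length(centers) == length(widths) &&
              length(centers) == length(amps),
              sprintf("component %d: centers, widths, amplitudes differ in length", c))
    stopIfNot(all(widths > 0),
              sprintf("component %d: peak widths must be > 0", c))
    stopIfNot(all(centers >= config@wl_min & centers <= config@wl_max),
              sprintf("component %d: peak center outside [%g, %g] nm",
                      c, config@wl_min, config@wl_max))
    for (k in seq_along(centers))
      K[c, ] <- K[c, ] + amps[k] * exp(-(wl - centers[k])^2 / (2 * widths[k]^2))
  }
  fat <- config@fat_component
  bands <- sort(unique(unlist(lapply(seq_along(config@peak_centers[[fat]]),
    function(k) which(abs(wl - config@peak_centers[[fat]][k]) <=
                      config@peak_widths[[fat]][k])))))
  list(library = K, wavelengths = wl, informative_bands = as.integer(bands))
}

#' Generate one batch of synthetic spectra with known truth
#'
#' Draws analyte levels uniformly in \code{y_range} (shifted by
#' \code{drift$y_shift}), composes ideal spectra from the component library
#' plus the smooth baseline (plus any baseline drift), applies per-sample
#' multiplicative/additive scatter and heteroscedastic noise.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param n number of samples (>= 1).
#' @param drift a drift list as in \code{\link{driftDefault}}, or NULL.
#' @param seed integer seed for this batch.
#' @param g optional per-sample drift-stage multipliers (length n); by
#'   default drawn uniformly over [0, 2], a snapshot across the campaign's
#'   storage/aging stages. Both the spectral drift shape and the analyte
#'   shift scale with g.
#' @return list(spectra = SpectraSet with y, truth = data.frame(a, b, g)).
#' @export
generateBatch <- function(config, n, drift = NULL, seed = config@seed,
                          g = NULL) {
  stopifnot(is(config, "SimConfig"))
  n <- assertCount(n, "n")
  drift <- if (is.null(drift)) driftNone() else mergeConfig(driftNone(), drift)
  lib <- generateComponentLibrary(config)
  wl <- lib$wavelengths
  u <- (wl - config@wl_min) / (config@wl_max - config@wl_min)
  base <- simBaseline(u)
  ## drift shape: flat + tilted + curved (broad mid-grid band) baseline
  ## change; the curved term is deliberately non-collinear with the mean
  ## spectrum so an affine fit against a stale reference cannot absorb it
  dshape <- drift$baseline_shift + drift$baseline_tilt * u +
    drift$baseline_curve * exp(-(wl - 1300)^2 / (2 * 130^2))
  nc <- config@n_components
  drift_on <- any(c(drift$baseline_shift, drift$baseline_tilt,
                    drift$baseline_curve, drift$y_shift) != 0)
  withSeed(seed, {
    ## heterogeneous drift: each sample carries its own drift stage g
    ## (storage time / origin), emulating batch-to-batch variability; a
    ## perfectly homogeneous shape shift would be absorbed by any affine
    ## scatter correction and would understate the problem drift poses
    if (is.null(g)) g <- if (drift_on) runif(n, 0, 2) else rep(0, n)
    stopIfNot(length(g) == n, "'g' must have one entry per sample")
    y <- runif(n, config@y_range[1], config@y_range[2]) + g * drift$y_shift
    conc <- matrix(0, n, nc)
    conc[, config@fat_component] <- y / 100
    ## non-analyte constituents: substantial sample-to-sample variability,
    ## uncorrelated with y (real nuisance chemistry masks scatter-correction
    ## artifacts; without it the MSC slope becomes a spurious analyte proxy)
    other <- setdiff(seq_len(nc), config@fat_component)
    for (c in other) conc[, c] <- runif(n, 0.05, 0.35)
    ideal <- conc %*% lib$library + matrix(base, n, config@n_channels,
                                           byrow = TRUE) +
      g * matrix(dshape, n, config@n_channels, byrow = TRUE)
    a <- 1 + g * drift$slope_shift + rnorm(n, 0, config@scatter_slope_sd)
    b <- g * drift$offset_shift + rnorm(n, 0, config@scatter_offset_sd)
    noise_sd <- ifelse(wl >= config@highband_start,
                       config@noise_sd_highband, config@noise_sd_base)
    noise <- matrix(rnorm(n * config@n_channels), n) *
      matrix(noise_sd, n, config@n_channels, byrow = TRUE)
    obs <- ideal * a + b + noise
    list(spectra = SpectraSet(obs, wl, y),
         truth = data.frame(a = a, b = b, g = g),
         ideal = ideal)
  })
}

#' Generate a full synthetic study: offline set plus drifted online stream
#'
#' The offline set (default 120 samples) is drawn without drift; the online
#' stream (default 75 samples) is drawn with \code{config@batch_drift}
#' applied progressively — the drift stage g ramps from 0 to 2 along the
#' stream (plus per-sample jitter of half-width \code{drift$spread}),
#' emulating sequential arrival of batches whose storage/origin conditions
#' trend away from the offline campaign. Deterministic given the config
#' seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{NIRStudy}.
#' @export
generateStudy <- function(config) {
  stopifnot(is(config, "SimConfig"))
  off <- generateBatch(config, config@n_offline, drift = NULL,
                       seed = deriveSeed(config@seed, 1L))
  drift <- config@batch_drift
  g_ramp <- withSeed(deriveSeed(config@seed, 4L),
    pmax(0, seq(0, 2, length.out = config@n_online) +
            runif(config@n_online, -drift$spread, drift$spread)))
  on <- generateBatch(config, config@n_online, drift = drift,
                      seed = deriveSeed(config@seed, 2L), g = g_ramp)
  bands <- generateComponentLibrary(config)$informative_bands
  new("NIRStudy", offline = off$spectra, online_stream = on$spectra,
      truth = list(offline = off$truth, online = on$truth,
                   informative_bands = bands),
      config = config)
}

#' Generate a held-out batch at the newest campaign stage
#'
#' Draws a batch whose drift stage sits at the end of the online campaign's
#' ramp (g uniform in \code{stage}), representing the newest incoming
#' samples an online model is deployed against. Used as the prediction set
#' of a streaming session.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param n batch size (default 15).
#' @param stage length-2 range of the drift stage (default c(1.6, 2)).
#' @return list(spectra, truth) as \code{\link{generateBatch}}.
#' @export
generateNewBatch <- function(config, n = 15L, stage = c(1.6, 2.0)) {
  stopifnot(is(config, "SimConfig"))
  g <- withSeed(deriveSeed(config@seed, 5L), runif(n, stage[1], stage[2]))
  generateBatch(config, n, drift = config@batch_drift,
                seed = deriveSeed(config@seed, 3L), g = g)
}
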