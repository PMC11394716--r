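#' SpectraSet: a set of NIR absorbance spectra on a common wavelength grid
#'
#' Container for a samples x channels absorbance matrix together with its
#' wavelength grid (nm) and, optionally, a per-sample reference value
#' (e.g. fat content in % by mass) used as the regression target.
#'
#' @slot wavelengths numeric, strictly increasing wavelength grid in nm.
#' @slot absorbance numeric matrix, samples in rows, channels in columns.
#' @slot y numeric, per-sample reference values; length 0 when absent.
#' @export
setClass("SpectraSet",
  representation(wavelengths = "numeric", absorbance = "matrix", y = "numeric"),
  validity = function(object) {
    msg <- character()
    wl <- object@wavelengths
    if (length(wl) < 1L) msg <- c(msg, "wavelength grid is empty")
    if (length(wl) > 1L && any(diff(wl) <= 0))
      msg <- c(msg, "wavelengths must be strictly increasing")
    if (ncol(object@absorbance) != length(wl))
      msg <- c(msg, "absorbance column count must equal grid length")
    if (length(object@y) && length(object@y) != nrow(object@absorbance))
      msg <- c(msg, "y length must equal sample count")
    if (length(msg)) msg else TRUE
  })

#' ReferenceSpectrum: running mean spectrum for (O)MSC
#'
#' The dynamic reference of online multiplicative scatter correction: the
#' running per-channel mean spectrum together with the number of samples it
#' summarizes. No raw spectra are retained, matching the online-learning
#' premise that the original dataset need not stay available.
#'
#' @slot mean_spectrum numeric, per-channel mean absorbance.
#' @slot n integer, number of samples summarized (>= 1).
#' @export
setClass("ReferenceSpectrum",
  representation(mean_spectrum = "numeric", n = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    if (!length(object@mean_spectrum)) msg <- c(msg, "mean spectrum is empty")
    if (anyNA(object@mean_spectrum)) msg <- c(msg, "mean spectrum contains NA")
    if (length(msg)) msg else TRUE
  })

#' UVEResult: uninformative-variable-elimination stability scores
#'
#' Per-wavelength stability statistic C = mean(b)/sd(b) over cross-validation
#' coefficient vectors, for the real wavelengths and for the appended
#' artificial-noise block, plus the selected top-k index subset.
#'
#' @slot stability numeric, C per real variable.
#' @slot noise_stability numeric, C per artificial noise variable.
#' @slot selected integer, selected column indices into the real variables
#'   (empty until \code{uveSelect} is applied).
#' @slot k integer, selection size (0 until selection).
#' @export
setClass("UVEResult",
  representation(stability = "numeric", noise_stability = "numeric",
                 selected = "integer", k = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@selected) != object@k)
      msg <- c(msg, "length(selected) must equal k")
    if (anyDuplicated(object@selected))
      msg <- c(msg, "selected indices must be unique")
    if (length(object@selected) &&
        (min(object@selected) < 1L ||
         max(object@selected) > length(object@stability)))
      msg <- c(msg, "selected indices out of range")
    if (length(msg)) msg else TRUE
  })

#' PLSModel: a fitted partial least squares regression model
#'
#' Stores the autoscaling vectors, the regression coefficients on the
#' standardized scale, the latent-variable count and the columns of the full
#' wavelength grid the model uses.
#'
#' @slot x_mean,x_std numeric, per-feature centering and scaling.
#' @slot y_mean,y_std numeric scalars for the response.
#' @slot coefficients numeric, standardized-scale regression vector.
#' @slot n_lv integer, number of latent variables.
#' @slot feature_indices integer, columns of the full grid used by the model.
#' @export
setClass("PLSModel",
  representation(x_mean = "numeric", x_std = "numeric",
                 y_mean = "numeric", y_std = "numeric",
                 coefficients = "numeric", n_lv = "integer",
                 feature_indices = "integer"),
  validity = function(object) {
    msg <- character()
    p <- length(object@coefficients)
    if (length(object@x_mean) != p || length(object@x_std) != p)
      msg <- c(msg, "x_mean/x_std length must match coefficients")
    if (any(object@x_std <= 0)) msg <- c(msg, "x_std entries must be > 0")
    if (object@n_lv < 1L) msg <- c(msg, "n_lv must be >= 1")
    if (length(object@feature_indices) != p)
      msg <- c(msg, "feature_indices length must match coefficients")
    if (length(msg)) msg else TRUE
  })

#' RPLSState: the recursive PLS online-model state
#'
#' Holds the forgetting-factor-weighted cross-products XtX(t) and Xty(t), the
#' running standardization moments, the sample count, the forgetting factor
#' and the current feature subset. Updated one sample at a time by
#' \code{rplsUpdate}; regression coefficients are refreshed on demand by
#' \code{rplsCoefficients}.
#'
#' @slot XtX numeric matrix, feature x feature cross-products.
#' @slot Xty numeric, feature-length cross-product vector.
#' @slot x_mean,x_std numeric, running per-feature moments.
#' @slot y_mean,y_std numeric scalars, running response moments.
#' @slot N integer, running sample count.
#' @slot lam numeric, forgetting factor in (0, 1].
#' @slot n_lv integer, latent-variable count frozen at initialization.
#' @slot feature_indices integer, current band subset on the full grid.
#' @slot exact_variance logical, use the exact running-variance recursion
#'   instead of the printed form (see the methods vignette).
#' @slot update_log data.frame, one row per update (N after update, lambda).
#' @export
setClass("RPLSState",
  representation(XtX = "matrix", Xty = "numeric",
                 x_mean = "numeric", x_std = "numeric",
                 y_mean = "numeric", y_std = "numeric",
                 N = "integer", lam = "numeric", n_lv = "integer",
                 feature_indices = "integer", exact_variance = "logical",
                 update_log = "data.frame"),
  validity = function(object) {
    msg <- character()
    p <- length(object@Xty)
    if (nrow(object@XtX) != p || ncol(object@XtX) != p)
      msg <- c(msg, "XtX dimensions must match Xty length")
    if (max(abs(object@XtX - t(object@XtX))) > 1e-8 * max(abs(object@XtX), 1))
      msg <- c(msg, "XtX must be symmetric")
    if (object@lam <= 0 || object@lam > 1)
      msg <- c(msg, "forgetting factor must be in (0, 1]")
    if (any(object@x_std <= 0)) msg <- c(msg, "x_std entries must be > 0")
    if (object@N < 1L) msg <- c(msg, "N must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' SimConfig: configuration of the synthetic NIR study generator
#'
#' Defines the wavelength grid, the pure-component absorption library, the
#' analyte range, per-sample scatter and noise magnitudes, and the systematic
#' drift applied to the online sample stream.
#'
#' @slot n_channels,wl_min,wl_max grid definition (channels, nm).
#' @slot n_components integer, number of pure absorbers.
#' @slot peak_centers,peak_widths list of numeric vectors, one per component:
#'   Gaussian peak centers (nm) and standard deviations (nm).
#' @slot peak_amplitudes list of numeric vectors, peak heights (absorbance).
#' @slot fat_component integer, which component is the analyte.
#' @slot y_range numeric length-2, analyte range (% by mass).
#' @slot scatter_slope_sd,scatter_offset_sd numeric, per-sample multiplicative
#'   and additive scatter spread.
#' @slot noise_sd_base,noise_sd_highband numeric, absorbance noise below /
#'   at-and-above the high-noise cutoff wavelength.
#' @slot highband_start numeric, nm, start of the high-noise band.
#' @slot batch_drift list with elements baseline_shift, baseline_tilt,
#'   slope_shift, offset_shift, y_shift describing the online-stream drift.
#' @slot n_offline,n_online integer, default study sizes.
#' @slot seed integer, master seed.
#' @export
setClass("SimConfig",
  representation(n_channels = "integer", wl_min = "numeric", wl_max = "numeric",
                 n_components = "integer", peak_centers = "list",
                 peak_widths = "list", peak_amplitudes = "list",
                 fat_component = "integer", y_range = "numeric",
                 scatter_slope_sd = "numeric", scatter_offset_sd = "numeric",
                 noise_sd_base = "numeric", noise_sd_highband = "numeric",
                 highband_start = "numeric", batch_drift = "list",
                 n_offline = "integer", n_online = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@n_channels < 2L) msg <- c(msg, "n_channels must be >= 2")
    if (object@wl_min >= object@wl_max) msg <- c(msg, "wl_min must be < wl_max")
    if (length(object@y_range) != 2L || object@y_range[1] >= object@y_range[2])
      msg <- c(msg, "y_range must be (low, high) with low < high")
    sds <- c(object@scatter_slope_sd, object@scatter_offset_sd,
             object@noise_sd_base, object@noise_sd_highband)
    if (any(sds < 0)) msg <- c(msg, "sd parameters must be >= 0")
    if (length(object@peak_centers) != object@n_components ||
        length(object@peak_widths) != object@n_components ||
        length(object@peak_amplitudes) != object@n_components)
      msg <- c(msg, "one peak_centers/widths/amplitudes vector per component")
    if (object@fat_component < 1L || object@fat_component > object@n_components)
      msg <- c(msg, "fat_component out of range")
    if (length(msg)) msg else TRUE
  })

#' NIRStudy: a synthetic offline + online NIR study with known truth
#'
#' @slot offline SpectraSet, the offline modeling set (no drift).
#' @slot online_stream SpectraSet, the sequential online stream (drifted).
#' @slot truth list with per-sample true scatter parameters
#'   (\code{offline}, \code{online}: data.frames with columns a, b) and the
#'   true informative band indices (\code{informative_bands}).
#' @slot config SimConfig used to generate the study.
#' @export
setClass("NIRStudy",
  representation(offline = "SpectraSet", online_stream = "SpectraSet",
                 truth = "list", config = "SimConfig"),
  validity = function(object) {
    msg <- character()
    if (!identical(object@offline@wavelengths, object@online_stream@wavelengths))
      msg <- c(msg, "offline and online sets must share one wavelength grid")
    if (nrow(object@truth$offline) != nrow(object@offline@absorbance))
      msg <- c(msg, "offline truth rows must align with samples")
    if (nrow(object@truth$online) != nrow(object@online_stream@absorbance))
      msg <- c(msg, "online truth rows must align with samples")
    if (length(msg)) msg else TRUE
  })

#' SessionReport: per-iteration record of an online RPLS session
#'
#' @slot iterations data.frame with columns iteration, n_processed, rmsep,
#'   r2, r2_paper (one row per processed batch, plus iteration 0 = the
#'   frozen offline model).
#' @slot flagged_bands list of integer vectors, per-iteration top monitored
#'   bands (full-grid indices).
#' @slot final_model PLSModel, coefficients after the last update.
#' @export
setClass("SessionReport",
  representation(iterations = "data.frame", flagged_bands = "list",
                 final_model = "PLSModel"),
  validity = function(object) {
    need <- c("iteration", "n_processed", "rmsep", "r2", "r2_paper")
    if (!all(need %in% names(object@iterations)))
      return("iterations must have iteration, n_processed, rmsep, r2, r2_paper")
    if (any(!is.finite(object@iterations$rmsep)))
      return("RMSEP values must be finite")
    TRUE
  })
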