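#' Fit the MSC reference spectrum
#'
#' Multiplicative scatter correction regresses every spectrum on a reference
#' spectrum; the reference is the per-channel arithmetic mean of the
#' calibration set.
#'
#' @param spectra a \linkS4class{SpectraSet} with at least one sample.
#' @return A \linkS4class{ReferenceSpectrum} with \code{n} = sample count.
#' @export
mscFit <- function(spectra) {
  stopifnot(is(spectra, "SpectraSet"))
  stopIfNot(nSamples(spectra) >= 1L, "cannot fit MSC reference on an empty set")
  ReferenceSpectrum(colMeans(absorbance(spectra)), nSamples(spectra))
}

## OLS of x on ref: x = a * ref + b. Returns c(a, b).
scatterFit <- function(x, ref) {
  mref <- mean(ref)
  vref <- sum((ref - mref)^2)
  if (vref == 0)
    stop("reference spectrum is constant; MSC slope is undefined", call. = FALSE)
  a <- sum((ref - mref) * (x - mean(x))) / vref
  c(a = a, b = mean(x) - a * mref)
}

#' Apply multiplicative scatter correction
#'
#' For each sample, fits \code{x_i = a_i * ref + b_i} by least squares and
#' corrects to \code{(x_i - b_i) / a_i}. Samples whose fitted slope falls
#' below \code{slope_floor} in magnitude are flagged and returned uncorrected
#' (dividing by a near-zero slope would blow up).
#'
#' @param spectra a \linkS4class{SpectraSet}.
#' @param reference a \linkS4class{ReferenceSpectrum} on the same grid.
#' @param slope_floor minimum |a_i| for which correction is applied.
#' @return list(corrected = SpectraSet, params = data.frame(slope, intercept,
#'   flagged)).
#' @export
mscCorrect <- function(spectra, reference, slope_floor = 1e-6) {
  stopifnot(is(spectra, "SpectraSet"), is(reference, "ReferenceSpectrum"))
  ref <- reference@mean_spectrum
  stopIfNot(length(ref) == nChannels(spectra),
            "reference grid length does not match the spectra")
  X <- absorbance(spectra)
  out <- X
  ab <- t(apply(X, 1L, scatterFit, ref = ref))
  flagged <- abs(ab[, "a"]) < slope_floor
  for (i in seq_len(nrow(X)))
    if (!flagged[i]) out[i, ] <- (X[i, ] - ab[i, "b"]) / ab[i, "a"]
  if (any(flagged))
    warning(sprintf("%d sample(s) flagged: |slope| below %g, left uncorrected",
                    sum(flagged), slope_floor))
  list(corrected = SpectraSet(out, wavelengths(spectra), refValues(spectra)),
       params = data.frame(slope = ab[, "a"], intercept = ab[, "b"],
                           flagged = flagged))
}

#' One online MSC (OMSC) update
#'
#' Folds a newly arrived spectrum into the dynamic reference
#' (\code{ref_new = (ref * n + x) / (n + 1)}), fits the new spectrum on the
#' updated reference by least squares, and corrects it. Only the running
#' mean and its count are retained, so correction never needs the original
#' calibration spectra.
#'
#' @param reference the current \linkS4class{ReferenceSpectrum}.
#' @param new_spectrum numeric vector on the same grid.
#' @param slope_floor minimum |a| for which correction is applied.
#' @return list(corrected = numeric, params = data.frame(slope, intercept,
#'   flagged), reference = updated ReferenceSpectrum, reference_shift =
#'   max-norm of the reference update).
#' @export
omscUpdate <- function(reference, new_spectrum, slope_floor = 1e-6) {
  stopifnot(is(reference, "ReferenceSpectrum"))
  x <- as.numeric(new_spectrum)
  stopIfNot(length(x) == length(reference@mean_spectrum),
            "new spectrum length does not match the reference grid")
  stopIfNot(all(is.finite(x)), "new spectrum contains non-finite values")
  n <- reference@n
  ref_new <- (reference@mean_spectrum * n + x) / (n + 1)
  shift <- max(abs(ref_new - reference@mean_spectrum))
  ab <- scatterFit(x, ref_new)
  flagged <- abs(ab["a"]) < slope_floor
  corrected <- if (flagged) {
    warning(sprintf("sample flagged: |slope| below %g, left uncorrected",
                    slope_floor))
    x
  } else (x - ab["b"]) / ab["a"]
  list(corrected = unname(corrected),
       params = data.frame(slope = unname(ab["a"]),
                           intercept = unname(ab["b"]), flagged = flagged),
       reference = ReferenceSpectrum(ref_new, n + 1L),
       reference_shift = shift)
}

#' Savitzky-Golay smoothing of a spectra set
#'
#' Replaces every spectrum by its Savitzky-Golay smoothed version: a local
#' least-squares polynomial fit of degree \code{polyorder} in a centered
#' window of \code{window} channels. Each sample is smoothed independently.
#' At the grid edges the full-window polynomial fit is evaluated off-center
#' (the usual filter-matrix treatment); the interior equals the textbook
#' sliding-window fit.
#'
#' @param spectra a \linkS4class{SpectraSet} (or a numeric vector, smoothed
#'   directly).
#' @param window odd window length, in channels.
#' @param polyorder polynomial degree, < window.
#' @return Smoothed object of the same type as the input.
#' @export
sgSmooth <- function(spectra, window = 11L, polyorder = 2L) {
  window <- assertCount(window, "window")
  polyorder <- assertCount(polyorder, "polyorder", min = 0L)
  stopIfNot(window %% 2L == 1L, "'window' must be odd")
  stopIfNot(window > polyorder, "'window' must exceed 'polyorder'")
  if (is.numeric(spectra) && !is.matrix(spectra)) {
    stopIfNot(window <= length(spectra),
              "'window' must not exceed the channel count")
    return(as.numeric(signal::sgolayfilt(spectra, p = polyorder, n = window)))
  }
  stopifnot(is(spectra, "SpectraSet"))
  stopIfNot(window <= nChannels(spectra),
            "'window' must not exceed the channel count")
  X <- absorbance(spectra)
  sm <- t(apply(X, 1L, function(r)
    signal::sgolayfilt(r, p = polyorder, n = window)))
  SpectraSet(sm, wavelengths(spectra), refValues(spectra))
}
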