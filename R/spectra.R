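#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix, samples in rows, channels in columns.
#'   A vector is treated as a single spectrum.
#' @param wavelengths numeric, strictly increasing grid in nm.
#' @param y optional numeric, one reference value per sample (e.g. % fat).
#' @return A \linkS4class{SpectraSet}.
#' @examples
#' s <- SpectraSet(matrix(rnorm(40), 4), seq(900, 1700, length.out = 10))
#' nSamples(s)
#' @export
SpectraSet <- function(absorbance, wavelengths, y = NULL) {
  if (!is.matrix(absorbance)) absorbance <- matrix(absorbance, nrow = 1L)
  storage.mode(absorbance) <- "double"
  new("SpectraSet", wavelengths = as.numeric(wavelengths),
      absorbance = absorbance,
      y = if (is.null(y)) numeric(0) else as.numeric(y))
}

#' @rdname SpectraSet-class
#' @export
setMethod("wavelengths", "SpectraSet", function(x) x@wavelengths)

#' @rdname SpectraSet-class
#' @export
setMethod("absorbance", "SpectraSet", function(x) x@absorbance)

#' @rdname SpectraSet-class
#' @export
setMethod("refValues", "SpectraSet",
          function(x) if (length(x@y)) x@y else NULL)

#' @rdname SpectraSet-class
#' @export
setMethod("nSamples", "SpectraSet", function(x) nrow(x@absorbance))

#' @rdname SpectraSet-class
#' @export
setMethod("nChannels", "SpectraSet", function(x) length(x@wavelengths))

#' @rdname SpectraSet-class
#' @param i sample indices; @param j channel indices.
#' @param j,...,drop see \code{[}; \code{drop} is ignored.
#' @export
setMethod("[", "SpectraSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSamples(x))
  if (missing(j)) j <- seq_len(nChannels(x))
  SpectraSet(x@absorbance[i, j, drop = FALSE], x@wavelengths[j],
             if (length(x@y)) x@y[i] else NULL)
})

setMethod("show", "SpectraSet", function(object) {
  wl <- object@wavelengths
  cat(sprintf("SpectraSet: %d samples x %d channels (%.1f-%.1f nm)%s\n",
              nSamples(object), nChannels(object), min(wl), max(wl),
              if (length(object@y)) ", with reference values" else ""))
})

#' Construct a ReferenceSpectrum
#'
#' @param mean_spectrum numeric, per-channel mean absorbance.
#' @param n count of samples the mean summarizes.
#' @return A \linkS4class{ReferenceSpectrum}.
#' @export
ReferenceSpectrum <- function(mean_spectrum, n) {
  new("ReferenceSpectrum", mean_spectrum = as.numeric(mean_spectrum),
      n = assertCount(n, "n"))
}

setMethod("show", "ReferenceSpectrum", function(object) {
  cat(sprintf("ReferenceSpectrum: %d channels, running mean of %d sample%s\n",
              length(object@mean_spectrum), object@n,
              if (object@n == 1L) "" else "s"))
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d features, %d latent variable%s\n",
              length(object@coefficients), object@n_lv,
              if (object@n_lv == 1L) "" else "s"))
})

setMethod("show", "UVEResult", function(object) {
  cat(sprintf(
    "UVEResult: %d real + %d noise variables%s\n",
    length(object@stability), length(object@noise_stability),
    if (object@k > 0L) sprintf(", top-%d selected", object@k)
    else " (no selection applied)"))
})

setMethod("show", "RPLSState", function(object) {
  cat(sprintf(
    "RPLSState: %d features, N = %d, lambda = %g, %d latent variables\n",
    length(object@Xty), object@N, object@lam, object@n_lv))
})

setMethod("show", "NIRStudy", function(object) {
  cat(sprintf(
    "NIRStudy: offline %d + online %d samples, %d channels, %d true bands\n",
    nSamples(object@offline), nSamples(object@online_stream),
    nChannels(object@offline), length(object@truth$informative_bands)))
})

setMethod("show", "SessionReport", function(object) {
  it <- object@iterations
  cat(sprintf("SessionReport: %d iterations (RMSEP %.4f -> %.4f)\n",
              nrow(it) - 1L, it$rmsep[1], it$rmsep[nrow(it)]))
})
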