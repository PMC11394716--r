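## Shared fixtures: small, fast synthetic configurations used across tests.

## A reduced grid keeps unit tests quick; peak geometry mirrors the defaults.
smallConfig <- function(seed = 1L, ...) {
  simConfig(n_channels = 64L, n_offline = 40L, n_online = 20L,
            seed = seed, ...)
}

## One analyte, one peak: the simplest study whose ideal spectra have a
## closed construction (used by noise-free oracles).
oneComponentConfig <- function(seed = 1L, peak_centers = list(1200),
                               peak_widths = list(30),
                               peak_amplitudes = list(0.9), ...) {
  simConfig(n_channels = 64L, peak_centers = peak_centers,
            peak_widths = peak_widths, peak_amplitudes = peak_amplitudes,
            fat_component = 1L, seed = seed, ...)
}

randomSpectra <- function(n, p, seed = 1L, with_y = FALSE) {
  set.seed(seed)
  SpectraSet(matrix(rnorm(n * p), n), seq(900, 1700, length.out = p),
             y = if (with_y) runif(n, 40, 80) else NULL)
}

## Closed-form per-sample OLS of x on ref (covariance / variance form).
olsOracle <- function(x, ref) {
  a <- sum((ref - mean(ref)) * (x - mean(x))) / sum((ref - mean(ref))^2)
  c(a = a, b = mean(x) - a * mean(ref))
}
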