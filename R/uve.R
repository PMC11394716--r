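#' UVE stability scoring of spectral variables
#'
#' Uninformative variable elimination appends an artificial random-noise
#' block with the same column count as X (uniform draws scaled to
#' \code{noise_scale}, small enough not to perturb the fit of the real
#' variables), fits cross-validated PLS of y on \code{[X | noise]} on the
#' centered scale, stacks the per-fold coefficient vectors into a matrix B,
#' and scores every column by the stability statistic
#' \code{C_i = mean(B[, i]) / sd(B[, i])}. Real-variable and noise-variable
#' stabilities are returned separately; bands whose |C| does not clearly
#' exceed the noise block's are uninformative.
#'
#' @param X numeric matrix, samples x wavelengths (preprocessed features).
#' @param y numeric response.
#' @param n_lv latent variables used in each fold's PLS fit.
#' @param noise_scale magnitude of the noise block; default
#'   \code{1e-10 * mean(abs(X))}.
#' @param folds number of cross-validation folds; default leave-one-out.
#' @param seed seed for the noise block and fold assignment.
#' @return A \linkS4class{UVEResult} without a selection applied.
#' @export
uveStability <- function(X, y, n_lv = 5L, noise_scale = NULL,
                         folds = nrow(X), seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopIfNot(n == length(y), "X rows and y length differ")
  folds <- assertCount(folds, "folds", min = 2L)
  stopIfNot(folds <= n, "more folds than samples")
  n_lv <- assertCount(n_lv, "n_lv")
  if (is.null(noise_scale)) noise_scale <- 1e-10 * mean(abs(X))
  stopIfNot(noise_scale > 0, "'noise_scale' must be positive")
  B <- withSeed(seed, {
    noise <- matrix(runif(n * p), n) * noise_scale
    XN <- cbind(X, noise)
    assign_fold <- if (folds == n) seq_len(n)
                   else sample(rep_len(seq_len(folds), n))
    t(vapply(seq_len(folds), function(f) {
      idx <- which(assign_fold == f)
      Xtr <- XN[-idx, , drop = FALSE]
      ytr <- y[-idx]
      Xc <- sweep(Xtr, 2L, colMeans(Xtr))      # centered, not scaled:
      fit <- nipalsCore(Xc, ytr - mean(ytr),   # keeps the noise block tiny
                        min(n_lv, nrow(Xtr) - 1L))
      fit$coefs[, fit$n_lv]
    }, numeric(2L * p)))
  })
  C <- vapply(seq_len(2L * p), function(i) {
    m <- mean(B[, i]); s <- sd(B[, i])
    if (s == 0) {
      warning(sprintf("column %d: zero coefficient spread; C set to %s",
                      i, if (m == 0) "0" else "signed Inf"))
      if (m == 0) 0 else sign(m) * Inf
    } else m / s
  }, numeric(1))
  new("UVEResult", stability = C[seq_len(p)],
      noise_stability = C[p + seq_len(p)],
      selected = integer(0), k = 0L)
}

#' Select the top-k most stable variables
#'
#' Keeps the k real variables with the largest |C|, ties broken by the lower
#' index. The study defaults are k = 70 for the offline model and k = 100
#' for the online model (feature-set expansion).
#'
#' @param result a \linkS4class{UVEResult} from \code{uveStability}.
#' @param k selection size, 1 <= k <= number of real variables.
#' @return The result with \code{selected} (in decreasing stability order)
#'   and \code{k} filled in.
#' @export
uveSelect <- function(result, k) {
  stopifnot(is(result, "UVEResult"))
  k <- assertCount(k, "k")
  p <- length(result@stability)
  stopIfNot(k <= p, sprintf("k = %d exceeds the %d real variables", k, p))
  ord <- order(-abs(result@stability), seq_len(p))
  initialize(result, selected = as.integer(ord[seq_len(k)]), k = k)
}

#' Classic UVE cutoff diagnostic
#'
#' The traditional UVE rule retains variables with
#' \code{|C| > max |C_noise|}; the study replaces it with a fixed top-k rule
#' but the cutoff remains a useful diagnostic.
#'
#' @param result a \linkS4class{UVEResult}.
#' @return Integer indices of real variables passing the classic cutoff.
#' @export
uveClassicCutoff <- function(result) {
  stopifnot(is(result, "UVEResult"))
  which(abs(result@stability) > max(abs(result@noise_stability)))
}

#' Eigenvalue-based monitoring of the selected feature bands
#'
#' Diagnoses which bands currently carry the model weight: the symmetric
#' eigendecomposition of the running standardized cross-product matrix is
#' taken, and each feature is scored by its aggregate loading weight on the
#' leading eigenvectors, \code{sum_j lambda_j * Gamma[i, j]^2} over the
#' top-m eigenvalues. The default m = 30 monitors the bands behind the 30
#' largest eigenvalues.
#'
#' @param XtX symmetric cross-product matrix over the current feature subset.
#' @param m number of leading eigenvalues to monitor (<= feature count).
#' @param tol relative symmetry tolerance; asymmetry beyond it is an error.
#' @return list(eigenvalues = top-m eigenvalues, descending;
#'   flagged_bands = all features ranked by aggregate weight, descending,
#'   ties broken by the lower index; weights = the per-feature scores).
#' @export
monitorTopFeatures <- function(XtX, m = 30L, tol = 1e-8) {
  S <- assertSymmetric(as.matrix(XtX), "XtX", tol = tol)
  m <- assertCount(m, "m")
  p <- nrow(S)
  stopIfNot(m <= p, sprintf("m = %d exceeds the %d features", m, p))
  eig <- eigen(S, symmetric = TRUE)
  vals <- pmax(eig$values, 0)       # clamp fp-negative tail of a PSD matrix
  top <- seq_len(m)
  w <- drop(eig$vectors[, top, drop = FALSE]^2 %*% vals[top])
  list(eigenvalues = vals[top],
       flagged_bands = as.integer(order(-w, seq_len(p))),
       weights = w)
}
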