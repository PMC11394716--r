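#' Initialize the recursive PLS state from calibration data
#'
#' Computes the calibration moments (mean and sd per feature, and for y),
#' autoscales the calibration block and stores its cross-products
#' \code{XtX(0) = Xs'Xs} and \code{Xty(0) = Xs'ys} (sample-sd convention,
#' i.e. for a single feature exactly proportional to y both equal N - 1).
#' Coefficients recovered from this state equal the offline
#' \code{plsFit} model on the same data.
#'
#' @param X_cal numeric matrix of UVE-selected calibration features.
#' @param y_cal numeric calibration response.
#' @param n_lv latent-variable count (frozen into the state).
#' @param lam forgetting factor in (0, 1]; default 1 (no forgetting).
#' @param feature_indices integer labels of the features on the full grid.
#' @param exact_variance use the exact running-variance recursion instead of
#'   the printed recursive form (see the methods vignette).
#' @return An \linkS4class{RPLSState}.
#' @export
rplsInit <- function(X_cal, y_cal, n_lv, lam = 1,
                     feature_indices = seq_len(ncol(X_cal)),
                     exact_variance = FALSE) {
  X <- as.matrix(X_cal); y <- as.numeric(y_cal)
  dimnames(X) <- NULL
  stopIfNot(nrow(X) >= 2L, "calibration data must have at least 2 samples")
  stopIfNot(nrow(X) == length(y), "X_cal rows and y_cal length differ")
  lam <- assertScalar(lam, "lam")
  stopIfNot(lam > 0 && lam <= 1, "forgetting factor must be in (0, 1]")
  xs <- autoscaleCheck(X, "X_cal")
  xm <- colMeans(X)
  ym <- mean(y); ysd <- sd(y)
  stopIfNot(ysd > 0, "calibration y has zero variance")
  Xs <- sweep(sweep(X, 2L, xm), 2L, xs, "/")
  ys <- (y - ym) / ysd
  new("RPLSState", XtX = crossprod(Xs), Xty = drop(crossprod(Xs, ys)),
      x_mean = xm, x_std = xs, y_mean = ym, y_std = ysd,
      N = nrow(X), lam = lam, n_lv = assertCount(n_lv, "n_lv"),
      feature_indices = as.integer(feature_indices),
      exact_variance = isTRUE(exact_variance),
      update_log = data.frame(N = integer(0), lam = numeric(0)))
}

#' One recursive PLS update
#'
#' Folds a single new sample into the state: the running means are updated
#' by the exact recursion \code{xbar(t) = (N-1)/N xbar(t-1) + x(t)/N}; the
#' running variances by the recursive form
#' \code{d2(t) = (N-2)/(N-1) d2(t-1) + (x(t) - xbar(t-1))^2 / (N-1)}
#' (or, with \code{exact_variance}, the Welford form with \code{1/N} on the
#' innovation, which reproduces the batch sample variance exactly); the
#' sample is standardized with the updated moments and accumulated onto the
#' forgetting-factor-weighted cross-products
#' \code{XtX <- lam * XtX + xhat xhat'}, \code{Xty <- lam * Xty + xhat yhat}.
#'
#' @param state an \linkS4class{RPLSState}.
#' @param x_t numeric feature vector (length = current feature count).
#' @param y_t scalar response.
#' @param freeze_moments keep the standardization moments fixed (diagnostic
#'   mode used by the batch-equivalence oracle; N still advances).
#' @return The updated state.
#' @export
rplsUpdate <- function(state, x_t, y_t, freeze_moments = FALSE) {
  stopifnot(is(state, "RPLSState"))
  x <- as.numeric(x_t)
  p <- length(state@Xty)
  stopIfNot(length(x) == p,
            sprintf("x_t has length %d; the state has %d features",
                    length(x), p))
  stopIfNot(all(is.finite(x)) && length(y_t) == 1L && is.finite(y_t),
            "non-finite update inputs")
  y <- as.numeric(y_t)
  N <- state@N + 1L
  xm <- state@x_mean; ym <- state@y_mean
  xsd <- state@x_std; ysd <- state@y_std
  if (!freeze_moments) {
    xm_new <- (N - 1) / N * xm + x / N
    ym_new <- (N - 1) / N * ym + y / N
    denom <- if (state@exact_variance) N else N - 1
    xvar <- (N - 2) / (N - 1) * xsd^2 + (x - xm)^2 / denom
    yvar <- (N - 2) / (N - 1) * ysd^2 + (y - ym)^2 / denom
    stopIfNot(all(xvar > 0), "a running feature variance hit zero")
    stopIfNot(yvar > 0, "the running response variance hit zero")
    xm <- xm_new; ym <- ym_new
    xsd <- sqrt(xvar); ysd <- sqrt(yvar)
  }
  xhat <- (x - xm) / xsd
  yhat <- (y - ym) / ysd
  initialize(state,
             XtX = state@lam * state@XtX + tcrossprod(xhat),
             Xty = state@lam * state@Xty + xhat * yhat,
             x_mean = xm, x_std = xsd, y_mean = ym, y_std = ysd, N = N,
             update_log = rbind(state@update_log,
                                data.frame(N = N, lam = state@lam)))
}

#' Extract a predict-ready model from an RPLS state
#'
#' Refreshes the regression coefficients from the current cross-products via
#' kernel PLS and wraps them with the state's current standardization
#' moments into a \linkS4class{PLSModel}.
#'
#' @param state an \linkS4class{RPLSState}.
#' @return A \linkS4class{PLSModel}.
#' @export
rplsCoefficients <- function(state) {
  stopifnot(is(state, "RPLSState"))
  beta <- plsFromCrossproducts(state@XtX, state@Xty, state@n_lv)
  new("PLSModel", x_mean = state@x_mean, x_std = state@x_std,
      y_mean = state@y_mean, y_std = state@y_std,
      coefficients = beta, n_lv = state@n_lv,
      feature_indices = state@feature_indices)
}
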