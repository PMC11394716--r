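## NIPALS PLS1 on a pre-centered (optionally scaled) X, y.
## Per component the score direction is iterated to convergence (a single
## response converges immediately, but the loop keeps the implementation
## honest for degenerate inputs). Returns W, P, q and the coefficient matrix
## for 1..A components on the same scale as the inputs.
nipalsCore <- function(Xs, ys, A, tol = 1e-12, maxit = 500L) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  E <- Xs; f <- ys
  used <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break        # no covariance left to model
    w <- w / nw
    for (it in seq_len(maxit)) {
      tvec <- drop(E %*% w)
      w_new <- drop(crossprod(E, f))
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sum((w_new - w)^2) < tol^2) { w <- w_new; break }
      w <- w_new
    }
    tvec <- drop(E %*% w)
    tt <- sum(tvec^2)
    if (tt < 1e-14) break
    pvec <- drop(crossprod(E, tvec)) / tt
    qa <- sum(f * tvec) / tt
    E <- E - tcrossprod(tvec, pvec)
    f <- f - tvec * qa
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa
    used <- a
  }
  stopIfNot(used >= 1L, "NIPALS extracted no components (X'y is zero)")
  coefs <- matrix(0, p, used)
  for (a in seq_len(used)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    coefs[, a] <- drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
  }
  list(W = W[, seq_len(used), drop = FALSE],
       P = P[, seq_len(used), drop = FALSE],
       q = q[seq_len(used)], coefs = coefs, n_lv = used)
}

autoscaleCheck <- function(X, what = "X") {
  s <- apply(X, 2L, sd)
  bad <- which(s == 0)
  stopIfNot(length(bad) == 0L,
            sprintf("%s column %d has zero variance", what, bad[1]))
  s
}

#' Fit a PLS regression model (NIPALS)
#'
#' Autoscales X (center, unit variance) and y, extracts \code{n_lv} latent
#' variables by NIPALS and stores the regression coefficients on the
#' standardized scale.
#'
#' @param X numeric matrix, samples x features.
#' @param y numeric response vector.
#' @param n_lv number of latent variables (<= min(samples - 1, features)).
#' @param feature_indices optional integer labels recording which columns of
#'   a wider grid \code{X} represents (bookkeeping only).
#' @return A \linkS4class{PLSModel}.
#' @export
plsFit <- function(X, y, n_lv, feature_indices = seq_len(ncol(X))) {
  X <- as.matrix(X); y <- as.numeric(y)
  dimnames(X) <- NULL
  n_lv <- assertCount(n_lv, "n_lv")
  stopIfNot(nrow(X) == length(y), "X rows and y length differ")
  stopIfNot(n_lv <= min(nrow(X) - 1L, ncol(X)),
            sprintf("n_lv = %d exceeds min(samples - 1, features) = %d",
                    n_lv, min(nrow(X) - 1L, ncol(X))))
  xs <- autoscaleCheck(X)
  xm <- colMeans(X)
  ym <- mean(y); ysd <- sd(y)
  stopIfNot(ysd > 0, "response y has zero variance")
  Xs <- sweep(sweep(X, 2L, xm), 2L, xs, "/")
  fit <- nipalsCore(Xs, (y - ym) / ysd, n_lv)
  new("PLSModel", x_mean = xm, x_std = xs, y_mean = ym, y_std = ysd,
      coefficients = fit$coefs[, fit$n_lv], n_lv = fit$n_lv,
      feature_indices = as.integer(feature_indices))
}

#' Predict from a PLSModel
#'
#' \code{yhat = y_mean + y_std * (standardized X \%*\% coefficients)}.
#'
#' @param model a \linkS4class{PLSModel}.
#' @param X numeric matrix whose columns match the model's features.
#' @return Numeric vector of predictions.
#' @export
plsPredict <- function(model, X) {
  stopifnot(is(model, "PLSModel"))
  X <- as.matrix(X)
  stopIfNot(ncol(X) == length(model@coefficients),
            sprintf("X has %d columns; the model expects %d",
                    ncol(X), length(model@coefficients)))
  Xs <- sweep(sweep(X, 2L, model@x_mean), 2L, model@x_std, "/")
  drop(model@y_mean + model@y_std * (Xs %*% model@coefficients))
}

#' PLS coefficients from cross-product matrices (kernel PLS)
#'
#' Extracts PLS components using only \code{X'X} and \code{X'y}
#' (Dayal-MacGregor improved kernel algorithm). This is the form the
#' recursive online model needs: for exact cross-products of autoscaled data
#' the coefficients equal \code{plsFit}'s. Coefficients are invariant to a
#' common positive rescaling of both cross-products, so the (N-1) sample
#' normalization convention is immaterial.
#'
#' @param XtX symmetric positive semi-definite feature x feature matrix.
#' @param Xty feature-length vector.
#' @param n_lv number of latent variables.
#' @return Numeric coefficient vector on the scale of the data behind the
#'   cross-products.
#' @export
plsFromCrossproducts <- function(XtX, Xty, n_lv) {
  n_lv <- assertCount(n_lv, "n_lv")
  Xty <- as.numeric(Xty)
  S <- assertSymmetric(as.matrix(XtX), "XtX")
  stopIfNot(nrow(S) == length(Xty), "XtX and Xty dimensions differ")
  s <- Xty
  p <- length(s)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); q <- numeric(n_lv)
  used <- 0L
  for (a in seq_len(n_lv)) {
    nw <- sqrt(sum(s^2))
    if (nw < 1e-14) break
    w <- s / nw
    tt <- drop(crossprod(w, S %*% w))   # t't of the implicit score vector
    if (tt < 1e-14) break
    pvec <- drop(S %*% w) / tt
    qa <- sum(s * w) / tt
    S <- S - tt * tcrossprod(pvec)
    s <- s - tt * qa * pvec
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa
    used <- a
  }
  stopIfNot(used >= 1L, "no component extractable (Xty is zero)")
  Wa <- W[, seq_len(used), drop = FALSE]
  Pa <- P[, seq_len(used), drop = FALSE]
  drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(used)]))
}

#' Choose the latent-variable count by cross-validated RMSECV
#'
#' k-fold cross-validation of \code{plsFit} over 1..max_lv components;
#' returns the count minimizing RMSECV (ties go to the smaller count)
#' together with the full curve.
#'
#' @param X,y training data.
#' @param max_lv largest latent-variable count to consider.
#' @param folds number of folds (>= 2).
#' @param seed seed for the fold assignment.
#' @return list(n_lv, rmsecv = numeric curve, cv_pred = cross-validated
#'   predictions at the chosen count).
#' @export
selectNLv <- function(X, y, max_lv, folds = 10L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- assertCount(folds, "folds", min = 2L)
  stopIfNot(folds <= n, "more folds than samples")
  max_lv <- assertCount(max_lv, "max_lv")
  min_train <- n - ceiling(n / folds)
  stopIfNot(max_lv <= min(min_train - 1L, ncol(X)),
            sprintf("max_lv = %d infeasible for %d samples in %d folds",
                    max_lv, n, folds))
  assign_fold <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
  preds <- matrix(NA_real_, n, max_lv)
  for (f in seq_len(folds)) {
    idx <- which(assign_fold == f)
    Xtr <- X[-idx, , drop = FALSE]; ytr <- y[-idx]
    xs <- autoscaleCheck(Xtr)
    xm <- colMeans(Xtr); ym <- mean(ytr); ysd <- sd(ytr)
    Xs <- sweep(sweep(Xtr, 2L, xm), 2L, xs, "/")
    fit <- nipalsCore(Xs, (ytr - ym) / ysd, max_lv)
    Xv <- sweep(sweep(X[idx, , drop = FALSE], 2L, xm), 2L, xs, "/")
    for (a in seq_len(fit$n_lv))
      preds[idx, a] <- ym + ysd * drop(Xv %*% fit$coefs[, a])
    if (fit$n_lv < max_lv)   # rank-deficient fold: reuse the last model
      for (a in seq(fit$n_lv + 1L, max_lv))
        preds[idx, a] <- preds[idx, fit$n_lv]
  }
  curve <- sqrt(colMeans((preds - y)^2))
  n_lv <- which.min(curve)   # ties resolve to the smaller count
  list(n_lv = as.integer(n_lv), rmsecv = curve, cv_pred = preds[, n_lv])
}
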