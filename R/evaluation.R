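#' Root mean square error
#'
#' \code{sqrt(mean((y_true - y_pred)^2))}; called RMSECV on cross-validation
#' folds and RMSEP on a held-out prediction set.
#'
#' @param y_true,y_pred numeric vectors of equal nonzero length.
#' @return Non-negative scalar in the units of y.
#' @export
rmse <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  stopIfNot(length(y_true) >= 1L && length(y_true) == length(y_pred),
            "y_true and y_pred must have equal nonzero length")
  sqrt(mean((y_true - y_pred)^2))
}

#' Coefficient of determination, standard and as-printed variants
#'
#' The standard variant is \code{1 - SSres / SStot} with
#' \code{SStot = sum((y - mean(y))^2)}. The \code{"paper"} variant is the
#' ratio \code{sum((yhat - y)^2) / sum((yhat - mean(y))^2)}, a formula some
#' chemometrics reports print; note it is 0 (not 1) for perfect
#' predictions, so the standard variant is the reported default.
#'
#' @param y_true,y_pred numeric vectors, length >= 2; y_true non-constant.
#' @param variant "standard" (default) or "paper".
#' @return Scalar.
#' @export
r2 <- function(y_true, y_pred, variant = c("standard", "paper")) {
  variant <- match.arg(variant)
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  stopIfNot(length(y_true) >= 2L && length(y_true) == length(y_pred),
            "need equal lengths >= 2")
  ybar <- mean(y_true)
  sstot <- sum((y_true - ybar)^2)
  stopIfNot(sstot > 0, "y_true is constant; R2 is undefined")
  if (variant == "standard") {
    1 - sum((y_true - y_pred)^2) / sstot
  } else {
    sum((y_pred - y_true)^2) / sum((y_pred - ybar)^2)
  }
}

#' Summary metrics for a prediction set
#'
#' @param y_true,y_pred numeric vectors.
#' @return list(rmse, r2_standard, r2_paper, n).
#' @export
evaluatePredictions <- function(y_true, y_pred) {
  list(rmse = rmse(y_true, y_pred),
       r2_standard = r2(y_true, y_pred, "standard"),
       r2_paper = r2(y_true, y_pred, "paper"),
       n = length(y_true))
}

#' Split samples into calibration and prediction sets
#'
#' Random split at the given ratio (default 2:1) constrained so that the
#' samples attaining the minimum and maximum reference value land in the
#' calibration set, guaranteeing that the calibration range covers the
#' prediction range.
#'
#' @param y numeric reference values (>= 3 samples).
#' @param ratio length-2 numeric, calibration : prediction (default 2:1).
#' @param seed seed for the random assignment.
#' @return list(calibration, prediction): disjoint, exhaustive, sorted
#'   integer index vectors.
#' @export
splitCalibrationPrediction <- function(y, ratio = c(2, 1), seed = 1L) {
  y <- as.numeric(y)
  n <- length(y)
  stopIfNot(n >= 3L, "need at least 3 samples to split")
  stopIfNot(length(ratio) == 2L && all(ratio > 0), "ratio must be 2 positives")
  n_cal <- round(n * ratio[1] / sum(ratio))
  stopIfNot(n_cal >= 2L && n_cal < n,
            "ratio leaves too few samples in one of the sets")
  pinned <- unique(c(which.min(y), which.max(y)))
  stopIfNot(n_cal >= length(pinned),
            "calibration set too small to hold the range extremes")
  pool <- setdiff(seq_len(n), pinned)
  ## index into pool explicitly: sample(x, k) on a length-1 x would resample 1:x
  extra <- withSeed(seed, pool[sample.int(length(pool), n_cal - length(pinned))])
  cal <- sort(c(pinned, extra))
  list(calibration = cal, prediction = setdiff(seq_len(n), cal))
}
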