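## Correct one raw spectrum against a fixed reference (no reference update).
correctOne <- function(x, reference, slope_floor = 1e-6) {
  ab <- scatterFit(x, reference@mean_spectrum)
  if (abs(ab["a"]) < slope_floor) return(unname(x))
  unname((x - ab["b"]) / ab["a"])
}

## Preprocess a raw prediction set with the current reference: MSC against
## the reference (no update), then S-G smoothing, then feature slicing.
preprocessFor <- function(spectra, reference, feature_indices,
                          sg_window, sg_order, slope_floor = 1e-6) {
  X <- absorbance(spectra)
  out <- matrix(0, nrow(X), length(feature_indices))
  for (i in seq_len(nrow(X))) {
    xc <- correctOne(X[i, ], reference, slope_floor)
    xs <- sgSmooth(xc, sg_window, sg_order)
    out[i, ] <- xs[feature_indices]
  }
  out
}

#' Run a streaming online-calibration session
#'
#' Emulates deployment: stream samples arrive one at a time, are
#' scatter-corrected (with the dynamic OMSC reference by default, which the
#' sample then updates; or against the frozen initial reference in
#' \code{"static"} mode), Savitzky-Golay smoothed, sliced to the model's
#' feature bands, and folded into the recursive PLS state. After every batch
#' (default 5 samples) the refreshed model is evaluated on the held-out
#' prediction set — preprocessed with the \emph{current} reference, so the
#' reported RMSEP reflects the deployed preprocessing — and the top
#' monitored bands are recorded. Iteration 0 is the frozen offline model.
#'
#' @param state an initialized \linkS4class{RPLSState} (features on the full
#'   grid given by \code{state@feature_indices}).
#' @param stream raw \linkS4class{SpectraSet} with reference values,
#'   processed in row order.
#' @param prediction_set raw held-out \linkS4class{SpectraSet} with
#'   reference values, on the same grid.
#' @param reference the initial \linkS4class{ReferenceSpectrum} (from the
#'   offline calibration set).
#' @param batch_size samples per iteration (default 5).
#' @param sg_window,sg_order Savitzky-Golay settings.
#' @param monitor_m leading eigenvalues monitored per iteration (default 30).
#' @param reference_mode "dynamic" (OMSC) or "static" (frozen reference MSC).
#' @param offline_model optional \linkS4class{PLSModel} used for the
#'   iteration-0 evaluation; defaults to the state's own initial
#'   coefficients.
#' @param slope_floor minimum |MSC slope| for which correction is applied.
#' @return A \linkS4class{SessionReport}; flagged bands are reported as
#'   full-grid channel indices.
#' @export
runOnlineSession <- function(state, stream, prediction_set, reference,
                             batch_size = 5L, sg_window = 11L, sg_order = 2L,
                             monitor_m = 30L,
                             reference_mode = c("dynamic", "static"),
                             offline_model = NULL, slope_floor = 1e-6) {
  stopifnot(is(state, "RPLSState"), is(stream, "SpectraSet"),
            is(prediction_set, "SpectraSet"),
            is(reference, "ReferenceSpectrum"))
  reference_mode <- match.arg(reference_mode)
  batch_size <- assertCount(batch_size, "batch_size")
  stopIfNot(!is.null(refValues(prediction_set)),
            "prediction set must carry reference values")
  n_stream <- nSamples(stream)
  if (n_stream > 0L) {
    stopIfNot(!is.null(refValues(stream)),
              "stream must carry reference values")
    stopIfNot(identical(wavelengths(stream), wavelengths(prediction_set)),
              "stream and prediction set must share the model's grid")
  }
  if (is.null(offline_model)) offline_model <- rplsCoefficients(state)
  fi <- state@feature_indices
  m_eff <- min(monitor_m, length(fi))

  evalNow <- function(model, it, n_done) {
    Xp <- preprocessFor(prediction_set, reference, fi, sg_window, sg_order,
                        slope_floor)
    ev <- evaluatePredictions(refValues(prediction_set), plsPredict(model, Xp))
    data.frame(iteration = it, n_processed = n_done, rmsep = ev$rmse,
               r2 = ev$r2_standard, r2_paper = ev$r2_paper)
  }

  rows <- evalNow(offline_model, 0L, 0L)
  flagged <- list(fi[monitorTopFeatures(state@XtX, m_eff)$flagged_bands[
    seq_len(m_eff)]])
  Xs <- absorbance(stream)
  ys <- refValues(stream)
  done_in_batch <- 0L
  it <- 0L
  for (i in seq_len(n_stream)) {
    if (reference_mode == "dynamic") {
      up <- omscUpdate(reference, Xs[i, ], slope_floor)
      reference <- up$reference
      xc <- up$corrected
    } else {
      xc <- correctOne(Xs[i, ], reference, slope_floor)
    }
    xf <- sgSmooth(xc, sg_window, sg_order)[fi]
    state <- rplsUpdate(state, xf, ys[i])
    done_in_batch <- done_in_batch + 1L
    if (done_in_batch == batch_size || i == n_stream) {
      it <- it + 1L
      model <- rplsCoefficients(state)
      rows <- rbind(rows, evalNow(model, it, i))
      flagged <- c(flagged, list(fi[monitorTopFeatures(state@XtX,
        m_eff)$flagged_bands[seq_len(m_eff)]]))
      done_in_batch <- 0L
    }
  }
  new("SessionReport", iterations = rows, flagged_bands = flagged,
      final_model = if (n_stream > 0L) rplsCoefficients(state)
                    else offline_model)
}

#' Build the offline calibration model
#'
#' The full offline workflow: 2:1 calibration/prediction split with the
#' range-coverage rule, MSC (reference fitted on the calibration set),
#' Savitzky-Golay smoothing, UVE band selection (top-k), cross-validated
#' latent-variable choice, and the final NIPALS PLS fit, with RMSECV/RMSEP
#' and both R-squared variants.
#'
#' @param spectra raw \linkS4class{SpectraSet} with reference values.
#' @param k number of UVE-selected bands (default 70).
#' @param sg_window,sg_order Savitzky-Golay settings.
#' @param uve_n_lv latent variables inside the UVE cross-validation.
#' @param uve_folds folds for UVE (default leave-one-out).
#' @param max_lv largest latent-variable count considered.
#' @param cv_folds folds for RMSECV selection.
#' @param seed master seed (split, UVE noise, CV folds).
#' @return list(model = \linkS4class{PLSModel}, reference, uve, split,
#'   n_lv, rmsecv curve, metrics, sg_window, sg_order).
#' @export
buildOfflineModel <- function(spectra, k = 70L, sg_window = 11L,
                              sg_order = 2L, uve_n_lv = 5L,
                              uve_folds = NULL, max_lv = 10L,
                              cv_folds = 10L, seed = 1L) {
  stopifnot(is(spectra, "SpectraSet"))
  y <- refValues(spectra)
  stopIfNot(!is.null(y), "spectra must carry reference values")
  split <- splitCalibrationPrediction(y, seed = deriveSeed(seed, 11L))
  cal <- spectra[split$calibration, ]
  prd <- spectra[split$prediction, ]
  reference <- mscFit(cal)
  cal_c <- sgSmooth(mscCorrect(cal, reference)$corrected, sg_window, sg_order)
  Xc <- absorbance(cal_c)
  if (is.null(uve_folds)) uve_folds <- nSamples(cal)
  uve <- uveSelect(uveStability(Xc, refValues(cal), n_lv = uve_n_lv,
                                folds = uve_folds,
                                seed = deriveSeed(seed, 12L)), k)
  sel <- sort(uve@selected)
  lv <- selectNLv(Xc[, sel, drop = FALSE], refValues(cal), max_lv = max_lv,
                  folds = cv_folds, seed = deriveSeed(seed, 13L))
  model <- plsFit(Xc[, sel, drop = FALSE], refValues(cal), lv$n_lv,
                  feature_indices = sel)
  Xp <- preprocessFor(prd, reference, sel, sg_window, sg_order)
  pred <- plsPredict(model, Xp)
  metrics <- list(
    rmsecv = lv$rmsecv[lv$n_lv],
    r2_cal = r2(refValues(cal), lv$cv_pred),
    rmsep = rmse(refValues(prd), pred),
    r2_pred = r2(refValues(prd), pred),
    r2_pred_paper = r2(refValues(prd), pred, "paper"))
  list(model = model, reference = reference, uve = uve, split = split,
       n_lv = lv$n_lv, rmsecv = lv$rmsecv, metrics = metrics,
       sg_window = sg_window, sg_order = sg_order)
}

#' Initialize the online model from the offline calibration data
#'
#' Re-runs UVE on the offline calibration set with the expanded feature
#' count (default 100) and builds a fresh \linkS4class{RPLSState} at those
#' bands, freezing the offline model's latent-variable count.
#'
#' @param spectra raw offline \linkS4class{SpectraSet} with reference values.
#' @param offline result of \code{\link{buildOfflineModel}} on the same set.
#' @param k_online expanded band count (default 100).
#' @param lam forgetting factor.
#' @param seed seed for the UVE re-run.
#' @return list(state = \linkS4class{RPLSState}, uve, selected).
#' @export
buildOnlineState <- function(spectra, offline, k_online = 100L, lam = 1,
                             seed = 1L) {
  cal <- spectra[offline$split$calibration, ]
  cal_c <- sgSmooth(mscCorrect(cal, offline$reference)$corrected,
                    offline$sg_window, offline$sg_order)
  Xc <- absorbance(cal_c)
  uve <- uveSelect(uveStability(Xc, refValues(cal),
                                seed = deriveSeed(seed, 12L)), k_online)
  sel <- sort(uve@selected)
  state <- rplsInit(Xc[, sel, drop = FALSE], refValues(cal),
                    n_lv = offline$n_lv, lam = lam, feature_indices = sel)
  list(state = state, uve = uve, selected = sel)
}

#' Run a complete synthetic calibration study end to end
#'
#' Convenience wrapper over the whole workflow on a simulated study:
#' generate the offline set and drifted online stream, build the offline
#' model (MSC + smoothing + UVE top-k + cross-validated PLS), initialize the
#' expanded-feature-set online state, and run the streaming session against
#' a held-out batch drawn at the newest campaign stage.
#'
#' @param config a \linkS4class{SimConfig}; its seed drives everything.
#' @param k_offline,k_online UVE selection sizes (defaults 70, 100).
#' @param lam forgetting factor for the online state.
#' @param reference_mode "dynamic" (OMSC) or "static" (frozen-reference MSC).
#' @param batch_size,monitor_m session settings.
#' @param n_prediction held-out new-batch size (default 15).
#' @return list(study, offline = buildOfflineModel result, online_state,
#'   session = \linkS4class{SessionReport}, uve_truth_coverage).
#' @export
runSyntheticStudy <- function(config, k_offline = 70L, k_online = 100L,
                              lam = 1, reference_mode = "dynamic",
                              batch_size = 5L, monitor_m = 30L,
                              n_prediction = 15L) {
  study <- generateStudy(config)
  off <- buildOfflineModel(study@offline, k = k_offline, seed = config@seed)
  onl <- buildOnlineState(study@offline, off, k_online = k_online, lam = lam,
                          seed = config@seed)
  pred <- generateNewBatch(config, n_prediction)$spectra
  session <- runOnlineSession(onl$state, study@online_stream, pred,
                              off$reference, batch_size = batch_size,
                              sg_window = off$sg_window,
                              sg_order = off$sg_order, monitor_m = monitor_m,
                              reference_mode = reference_mode)
  list(study = study, offline = off, online_state = onl, session = session,
       uve_truth_coverage = mean(study@truth$informative_bands %in%
                                   off$uve@selected))
}
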