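#' Default run configuration
#'
#' The full default parameter set of the pipeline, mirroring the study's
#' printed choices: 70 offline / 100 online UVE features, batch size 5,
#' 30 monitored eigenvalues, 2:1 calibration/prediction split.
#'
#' @return A nested named list (see the config file written by
#'   \code{\link{writeRunConfig}} for the schema).
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    log_level = "info",
    preprocessing = list(sg_window = 11L, sg_order = 2L, omsc = TRUE,
                         slope_floor = 1e-6),
    uve = list(k_offline = 70L, k_online = 100L, folds = NULL,
               n_lv = 5L, noise_scale = NULL),
    pls = list(max_lv = 10L, folds = 10L),
    rpls = list(lam = 1.0, batch_size = 5L, monitor_m = 30L,
                exact_variance = FALSE),
    split = list(ratio = c(2, 1)),
    simulator = list(n_channels = 512L, wl_min = 900, wl_max = 1700,
                     n_offline = 120L, n_online = 75L,
                     y_range = c(55, 75),
                     scatter_slope_sd = 0.08, scatter_offset_sd = 0.03,
                     noise_sd_base = 0.004, noise_sd_highband = 0.01,
                     highband_start = 1500,
                     drift = driftDefault()))
}

validateRunConfig <- function(cfg) {
  assertCount(cfg$seed, "seed", min = 0L)
  assertCount(cfg$preprocessing$sg_window, "preprocessing$sg_window")
  assertCount(cfg$preprocessing$sg_order, "preprocessing$sg_order", min = 0L)
  stopIfNot(cfg$preprocessing$sg_window %% 2L == 1L,
            "preprocessing$sg_window must be odd")
  stopIfNot(cfg$preprocessing$sg_window > cfg$preprocessing$sg_order,
            "preprocessing$sg_window must exceed sg_order")
  assertCount(cfg$uve$k_offline, "uve$k_offline")
  assertCount(cfg$uve$k_online, "uve$k_online")
  assertCount(cfg$pls$max_lv, "pls$max_lv")
  assertCount(cfg$pls$folds, "pls$folds", min = 2L)
  lam <- assertScalar(cfg$rpls$lam, "rpls$lam")
  stopIfNot(lam > 0 && lam <= 1, "rpls$lam must be in (0, 1]")
  assertCount(cfg$rpls$batch_size, "rpls$batch_size")
  assertCount(cfg$rpls$monitor_m, "rpls$monitor_m")
  stopIfNot(length(cfg$split$ratio) == 2L && all(cfg$split$ratio > 0),
            "split$ratio must be two positive numbers")
  sim <- cfg$simulator
  assertCount(sim$n_channels, "simulator$n_channels", min = 2L)
  stopIfNot(sim$wl_min < sim$wl_max, "simulator wl_min must be < wl_max")
  stopIfNot(length(sim$y_range) == 2L && sim$y_range[1] < sim$y_range[2],
            "simulator$y_range must be (low, high)")
  stopIfNot(all(c(sim$scatter_slope_sd, sim$scatter_offset_sd,
                  sim$noise_sd_base, sim$noise_sd_highband) >= 0),
            "simulator sd parameters must be >= 0")
  invisible(cfg)
}

## Recursively overlay user values onto the defaults.
mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read / write the run configuration file (YAML)
#'
#' \code{readRunConfig} overlays the file's values onto
#' \code{\link{defaultRunConfig}} and validates every numeric field against
#' its module's preconditions.
#'
#' @param path config file path; NULL returns the defaults.
#' @return The validated config list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    stopIfNot(file.exists(path), sprintf("config file not found: %s", path))
    cfg <- mergeConfig(cfg, yaml::read_yaml(path))
  }
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a config list.
#' @export
writeRunConfig <- function(cfg, path) {
  validateRunConfig(cfg)
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}

#' Build a SimConfig from the simulator section of a run config
#'
#' @param cfg a run config list (see \code{\link{defaultRunConfig}}).
#' @return A \linkS4class{SimConfig}.
#' @export
simConfigFromRunConfig <- function(cfg) {
  sim <- cfg$simulator
  simConfig(n_channels = sim$n_channels, wl_min = sim$wl_min,
            wl_max = sim$wl_max, y_range = as.numeric(sim$y_range),
            scatter_slope_sd = sim$scatter_slope_sd,
            scatter_offset_sd = sim$scatter_offset_sd,
            noise_sd_base = sim$noise_sd_base,
            noise_sd_highband = sim$noise_sd_highband,
            highband_start = sim$highband_start,
            batch_drift = mergeConfig(driftNone(), sim$drift),
            n_offline = sim$n_offline, n_online = sim$n_online,
            seed = cfg$seed)
}
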