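fmtNum <- function(x) sprintf("%.17g", x)

ioHeader <- function(command, units) {
  c(sprintf("# nircal %s; produced by %s",
            as.character(packageVersion("nircal")), command),
    sprintf("# %s", units))
}

#' Write a SpectraSet to the delimited spectra format
#'
#' Comma-separated text: comment lines ("#") naming units and the producing
#' command, a header row of wavelengths in nm (plus a final "y" column when
#' reference values are present), one row per sample, full double precision
#' so that write-read round-trips are lossless.
#'
#' @param set a \linkS4class{SpectraSet}.
#' @param path output file.
#' @param command label recorded in the file header.
#' @export
writeSpectra <- function(set, path, command = "write-spectra") {
  stopifnot(is(set, "SpectraSet"))
  y <- refValues(set)
  header <- c(ioHeader(command,
                       "columns: wavelength nm (absorbance AU per cell)"),
              paste(c(fmtNum(wavelengths(set)), if (!is.null(y)) "y"),
                    collapse = ","))
  X <- absorbance(set)
  rows <- vapply(seq_len(nrow(X)), function(i)
    paste(c(fmtNum(X[i, ]), if (!is.null(y)) fmtNum(y[i])), collapse = ","),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a SpectraSet from the delimited spectra format
#'
#' @param path input file written by \code{\link{writeSpectra}} (or any
#'   delimited file with a strictly increasing wavelength header row and an
#'   optional final "y" column).
#' @return A \linkS4class{SpectraSet}.
#' @export
readSpectra <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  stopIfNot(length(lines) >= 2L,
            sprintf("%s: need a header row and at least one sample", path))
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_y <- identical(trimws(hdr[length(hdr)]), "y")
  wl_str <- if (has_y) hdr[-length(hdr)] else hdr
  wl <- suppressWarnings(as.numeric(wl_str))
  bad <- which(is.na(wl))
  stopIfNot(length(bad) == 0L,
            sprintf("%s: non-numeric wavelength in header column %d",
                    path, bad[1]))
  stopIfNot(all(diff(wl) > 0),
            sprintf("%s: wavelength header is not strictly increasing", path))
  ncolumns <- length(hdr)
  n <- length(lines) - 1L
  X <- matrix(NA_real_, n, length(wl))
  y <- if (has_y) numeric(n) else NULL
  for (i in seq_len(n)) {
    cells <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    stopIfNot(length(cells) == ncolumns,
              sprintf("%s: row %d has %d fields, expected %d",
                      path, i, length(cells), ncolumns))
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals))
    stopIfNot(length(bad) == 0L,
              sprintf("%s: non-numeric cell at row %d, column %d",
                      path, i, bad[1]))
    X[i, ] <- vals[seq_along(wl)]
    if (has_y) y[i] <- vals[ncolumns]
  }
  SpectraSet(X, wl, y)
}

#' Check two spectra files share one wavelength grid
#'
#' @param a,b two \linkS4class{SpectraSet}s.
#' @param name_a,name_b labels (file names) used in the error message.
#' @return TRUE invisibly, or an error naming both inputs.
#' @export
checkSameGrid <- function(a, b, name_a = "first input",
                          name_b = "second input") {
  stopIfNot(identical(wavelengths(a), wavelengths(b)),
            sprintf("wavelength grids of %s and %s differ", name_a, name_b))
  invisible(TRUE)
}

#' Write a delimited table with a unit-bearing header
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param command producing command recorded in the header.
#' @param units one-line description of columns and units.
#' @export
writeTable <- function(df, path, command, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(ioHeader(command, units), con)
  ## full precision keeps repeated runs bit-identical and round-trippable
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmtNum)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a table written by \code{writeTable}
#'
#' @param path input file.
#' @return data.frame.
#' @export
readTable <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  utils::read.csv(path, comment.char = "#")
}

#' Serialize the UVE result to a delimited table
#'
#' Columns: wavelength (nm), stability C, selected flag, plus the noise-block
#' stabilities in a trailing block flagged by \code{is_noise}.
#'
#' @param result a \linkS4class{UVEResult}.
#' @param wavelengths grid for the real variables.
#' @param path output file.
#' @export
writeUVETable <- function(result, wavelengths, path) {
  stopifnot(is(result, "UVEResult"))
  p <- length(result@stability)
  df <- data.frame(
    wavelength = c(wavelengths, rep(NA_real_, p)),
    stability = c(result@stability, result@noise_stability),
    selected = c(seq_len(p) %in% result@selected, rep(FALSE, p)),
    is_noise = rep(c(FALSE, TRUE), each = p))
  writeTable(df, path, "select-features",
             "columns: wavelength nm, stability C, selected flag, noise flag")
}

#' Write / read the online model bundle
#'
#' A versioned plain-text (YAML) serialization of everything needed to
#' resume or deploy the online model: the RPLS state, the dynamic reference
#' spectrum, the wavelength grid and the smoothing settings.
#'
#' @param state an \linkS4class{RPLSState}.
#' @param reference a \linkS4class{ReferenceSpectrum}.
#' @param grid numeric wavelength grid.
#' @param sg_window,sg_order smoothing settings.
#' @param path file path.
#' @return \code{readOnlineModel} returns list(state, reference, grid,
#'   sg_window, sg_order).
#' @export
writeOnlineModel <- function(state, reference, grid, sg_window, sg_order,
                             path) {
  stopifnot(is(state, "RPLSState"), is(reference, "ReferenceSpectrum"))
  obj <- list(
    format = "nircal-online-model", version = 1L,
    package_version = as.character(packageVersion("nircal")),
    sg_window = as.integer(sg_window), sg_order = as.integer(sg_order),
    grid = grid,
    reference = list(mean_spectrum = reference@mean_spectrum,
                     n = reference@n),
    state = list(XtX = as.numeric(state@XtX), Xty = state@Xty,
                 x_mean = state@x_mean, x_std = state@x_std,
                 y_mean = state@y_mean, y_std = state@y_std,
                 N = state@N, lam = state@lam, n_lv = state@n_lv,
                 feature_indices = state@feature_indices,
                 exact_variance = state@exact_variance))
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname writeOnlineModel
#' @export
readOnlineModel <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  obj <- yaml::read_yaml(path)
  stopIfNot(identical(obj$format, "nircal-online-model"),
            sprintf("%s is not an online-model file", path))
  s <- obj$state
  p <- length(s$Xty)
  state <- new("RPLSState",
               XtX = matrix(as.numeric(s$XtX), p, p), Xty = as.numeric(s$Xty),
               x_mean = as.numeric(s$x_mean), x_std = as.numeric(s$x_std),
               y_mean = as.numeric(s$y_mean), y_std = as.numeric(s$y_std),
               N = as.integer(s$N), lam = as.numeric(s$lam),
               n_lv = as.integer(s$n_lv),
               feature_indices = as.integer(s$feature_indices),
               exact_variance = isTRUE(s$exact_variance),
               update_log = data.frame(N = integer(0), lam = numeric(0)))
  list(state = state,
       reference = ReferenceSpectrum(as.numeric(obj$reference$mean_spectrum),
                                     obj$reference$n),
       grid = as.numeric(obj$grid),
       sg_window = obj$sg_window, sg_order = obj$sg_order)
}

#' Write a session report iteration table
#'
#' @param report a \linkS4class{SessionReport}.
#' @param path output file.
#' @export
writeSessionTable <- function(report, path) {
  stopifnot(is(report, "SessionReport"))
  writeTable(report@iterations, path, "run-online",
             "columns: iteration, n_processed, RMSEP (% mass), R2, R2_paper")
}
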