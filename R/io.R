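## File formats. CSV dialect is fixed across the package: comma separator,
## "." decimal point, UTF-8, mandatory header row. Images are 16-bit
## single-channel TIFF; masks are 8-bit labeled TIFF (0 background,
## 1 nucleus, 2 nucleoli); ground truth travels in JSON sidecars.

#' Write / read an autocorrelation curve as CSV
#'
#' Columns \code{lag_s,g} and, when per-lag errors are present,
#' \code{sem}.
#'
#' @param curve an [ACFCurve-class].
#' @param path file path.
#' @return \code{readACFCsv} returns an [ACFCurve-class];
#'   \code{writeACFCsv} returns \code{path} invisibly.
#' @export
writeACFCsv <- function(curve, path) {
  stopifnot(is(curve, "ACFCurve"))
  df <- data.frame(lag_s = curve@lags, g = curve@g)
  if (length(curve@sem)) df$sem <- curve@sem
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeACFCsv
#' @export
readACFCsv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("lag_s", "g")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ACF CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  acfCurve(df$lag_s, df$g,
           if ("sem" %in% names(df)) df$sem else numeric(0))
}

#' Write / read a photon-count trace as CSV
#'
#' Columns \code{bin,counts}; the sampling rate travels either as an
#' argument on read or in a JSON sidecar \code{<path>.json} holding
#' \code{{"rate_hz": <Hz>}} written alongside.
#'
#' @param trace an [IntensityTrace-class].
#' @param path file path.
#' @param sidecar write the rate sidecar (default TRUE).
#' @param rateHz sampling rate on read; \code{NULL} reads the sidecar.
#' @return \code{readTraceCsv} returns an [IntensityTrace-class].
#' @export
writeTraceCsv <- function(trace, path, sidecar = TRUE) {
  stopifnot(is(trace, "IntensityTrace"))
  utils::write.csv(data.frame(bin = seq_along(trace@counts) - 1L,
                              counts = trace@counts),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  if (sidecar)
    jsonlite::write_json(list(rate_hz = 1 / trace@binWidth),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path, rateHz = NULL) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  miss <- setdiff(c("bin", "counts"), names(df))
  if (length(miss))
    stop("trace CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(rateHz)) {
    sc <- paste0(path, ".json")
    if (!file.exists(sc))
      stop("no rateHz given and no sidecar found at ", sc)
    rateHz <- jsonlite::read_json(sc)$rate_hz
  }
  intensityTrace(df$counts, rateHz)
}

#' Serialize a fit result to JSON
#'
#' Canonical field names: \code{n_molecules, f_diff, tau_diff_s, omega,
#' f_short, tau_short_s, f_long, tau_long_s, koff_short_s-1,
#' koff_long_s-1, converged, residual_norm} (plus \code{offset} when a
#' baseline was fitted).
#'
#' @param fit a [FitResult-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeFitResultJson <- function(fit, path) {
  stopifnot(is(fit, "FitResult"))
  p <- fit@params
  out <- list(
    n_molecules = p@nMolecules, f_diff = p@fDiff, tau_diff_s = p@tauDiff,
    omega = p@omega, f_short = p@fShort, tau_short_s = p@tauShort,
    f_long = p@fLong, tau_long_s = p@tauLong,
    `koff_short_s-1` = fit@koffShort, `koff_long_s-1` = fit@koffLong,
    converged = fit@converged, residual_norm = fit@residualNorm)
  if (fit@offset != 0) out$offset <- fit@offset
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a synthetic nucleus scene
#'
#' The image goes to \code{<prefix>_img.tif} (16-bit single-channel
#' TIFF), the masks to \code{<prefix>_mask.tif} (8-bit labeled TIFF:
#' 0 background, 1 nucleus, 2 nucleoli) and the ground truth (foci list,
#' phase, pixel size, background, seed) to \code{<prefix>_truth.json}.
#'
#' @param scene a [NucleusScene-class].
#' @param prefix path prefix (directory must exist).
#' @return \code{readScene} returns a [NucleusScene-class];
#'   \code{writeScene} the three file paths, invisibly.
#' @export
writeScene <- function(scene, prefix) {
  stopifnot(is(scene, "NucleusScene"))
  imgPath <- paste0(prefix, "_img.tif")
  maskPath <- paste0(prefix, "_mask.tif")
  truthPath <- paste0(prefix, "_truth.json")
  img16 <- pmin(round(scene@image), 65535) / 65535
  EBImage::writeImage(img16, imgPath, type = "tiff",
                      bits.per.sample = 16L, compression = "none")
  lab <- matrix(0, nrow(scene@image), ncol(scene@image))
  lab[scene@nucleusMask] <- 1
  lab[scene@nucleoliMask] <- 2
  EBImage::writeImage(lab / 255, maskPath, type = "tiff",
                      bits.per.sample = 8L, compression = "none")
  truth <- list(
    foci = scene@fociTruth, phase = scene@phaseTruth,
    pixel_size_um = scene@pixelSize, background = scene@background,
    seed = scene@seed)
  jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(image = imgPath, mask = maskPath, truth = truthPath))
}

#' @rdname writeScene
#' @export
readScene <- function(prefix) {
  img <- round(EBImage::imageData(EBImage::readImage(
    paste0(prefix, "_img.tif"))) * 65535)
  lab <- round(EBImage::imageData(EBImage::readImage(
    paste0(prefix, "_mask.tif"))) * 255)
  bad <- setdiff(unique(as.vector(lab)), c(0, 1, 2))
  if (length(bad))
    stop("mask TIFF contains invalid label(s): ",
         paste(bad, collapse = ", "))
  tr <- jsonlite::read_json(paste0(prefix, "_truth.json"),
                            simplifyVector = TRUE)
  foci <- as.data.frame(tr$foci)
  if (nrow(foci) == 0L)
    foci <- data.frame(x = numeric(0), y = numeric(0),
                       radius = numeric(0), amplitude = numeric(0))
  new("NucleusScene", image = img, nucleusMask = lab >= 1,
      nucleoliMask = lab == 2, fociTruth = foci,
      phaseTruth = if (is.null(tr$phase)) NA_character_ else tr$phase,
      pixelSize = tr$pixel_size_um, background = tr$background,
      seed = as.integer(tr$seed))
}

#' Write / read a colony DAPI table as CSV
#'
#' @param tab data.frame as produced by [makeColonyTable()].
#' @param path file path.
#' @return \code{readColonyCsv} returns the data.frame.
#' @export
writeColonyCsv <- function(tab, path) {
  stopifnot(all(c("colony_id", "cell_id", "integrated_dapi") %in%
                  names(tab)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeColonyCsv
#' @export
readColonyCsv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  miss <- setdiff(c("colony_id", "cell_id", "integrated_dapi"), names(df))
  if (length(miss))
    stop("colony CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Validate a data file against one of the package dialects
#'
#' Strict parsing with field-level diagnostics for the CSV/TIFF/JSON
#' dialects used across the package.
#'
#' @param path file path.
#' @param kind one of \code{"acf"}, \code{"trace"}, \code{"colony"},
#'   \code{"mask"}, \code{"truth"}.
#' @return the parsed object, or an error whose message names the
#'   offending column, label or field.
#' @export
validateIO <- function(path, kind = c("acf", "trace", "colony", "mask",
                                      "truth")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(kind,
    acf = {
      crv <- readACFCsv(path)
      validObject(crv)
      crv
    },
    trace = {
      df <- utils::read.csv(path, fileEncoding = "UTF-8")
      miss <- setdiff(c("bin", "counts"), names(df))
      if (length(miss))
        stop("trace CSV is missing required column(s): ",
             paste(miss, collapse = ", "))
      if (!is.numeric(df$counts) || any(!is.finite(df$counts)) ||
          any(df$counts < 0))
        stop("column 'counts' must hold nonnegative finite numbers")
      df
    },
    colony = {
      df <- readColonyCsv(path)
      if (any(!is.finite(df$integrated_dapi)) ||
          any(df$integrated_dapi <= 0))
        stop("column 'integrated_dapi' must hold positive finite numbers")
      df
    },
    mask = {
      lab <- round(EBImage::imageData(EBImage::readImage(path)) * 255)
      bad <- setdiff(unique(as.vector(lab)), c(0, 1, 2))
      if (length(bad))
        stop("mask TIFF contains invalid label(s): ",
             paste(bad, collapse = ", "))
      lab
    },
    truth = {
      tr <- jsonlite::read_json(path, simplifyVector = TRUE)
      need <- c("foci", "phase", "pixel_size_um", "background", "seed")
      miss <- setdiff(need, names(tr))
      if (length(miss))
        stop("truth JSON is missing required field(s): ",
             paste(miss, collapse = ", "))
      tr
    })
}
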