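#' Construct an FCS parameter set
#'
#' @param nMolecules mean molecules in the confocal volume (> 0).
#' @param fDiff,fShort,fLong amplitude fractions; must sum to 1.
#' @param tauDiff diffusion time, s.
#' @param omega axial/radial waist ratio (> 1).
#' @param tauShort,tauLong residence times, s, with tauShort < tauLong.
#' @return an [FCSParams-class] object.
#' @examples
#' p <- fcsParams(nMolecules = 2, fDiff = 0.5, tauDiff = 1e-3, omega = 5,
#'                fShort = 0.3, tauShort = 0.1, fLong = 0.2, tauLong = 2)
#' @export
fcsParams <- function(nMolecules, fDiff, tauDiff, omega = 5,
                      fShort = 0, tauShort = 0.01,
                      fLong = 0, tauLong = 1) {
  new("FCSParams", nMolecules = as.numeric(nMolecules),
      fDiff = as.numeric(fDiff), tauDiff = as.numeric(tauDiff),
      omega = as.numeric(omega), fShort = as.numeric(fShort),
      tauShort = as.numeric(tauShort), fLong = as.numeric(fLong),
      tauLong = as.numeric(tauLong))
}

#' Construct an autocorrelation curve
#'
#' @param lags lag times, s, strictly increasing.
#' @param g correlation amplitude per lag.
#' @param sem optional per-lag standard errors.
#' @return an [ACFCurve-class] object.
#' @export
acfCurve <- function(lags, g, sem = numeric(0)) {
  new("ACFCurve", lags = as.numeric(lags), g = as.numeric(g),
      sem = as.numeric(sem))
}

#' Construct a binned photon-count trace
#'
#' @param counts nonnegative counts per bin.
#' @param rateHz sampling rate in Hz; the bin width is \code{1/rateHz}.
#' @return an [IntensityTrace-class] object.
#' @export
intensityTrace <- function(counts, rateHz = 50000) {
  stopifnot(is.numeric(rateHz), length(rateHz) == 1L, rateHz > 0)
  new("IntensityTrace", counts = as.integer(round(counts)),
      binWidth = 1 / rateHz)
}

## ---- accessors ------------------------------------------------------------

#' @describeIn acfCurve lag times of a curve (seconds).
#' @param x an object.
#' @export
lags <- function(x) x@lags

#' @describeIn acfCurve correlation amplitudes of a curve.
#' @export
gValues <- function(x) x@g

#' @describeIn acfCurve per-lag standard errors (length 0 when absent).
#' @export
semValues <- function(x) x@sem

#' @describeIn intensityTrace counts per bin.
#' @export
counts <- function(x) x@counts

#' @describeIn intensityTrace bin width in seconds.
#' @export
binWidth <- function(x) x@binWidth

#' @describeIn intensityTrace trace duration in seconds.
#' @export
duration <- function(x) length(x@counts) * x@binWidth

#' Fitted parameters of a fit result
#'
#' @param x a [FitResult-class].
#' @return the fitted [FCSParams-class].
#' @export
fittedParams <- function(x) x@params

#' FCS parameters as a named numeric vector
#'
#' Uses the canonical serialization names (times in seconds).
#'
#' @param params an [FCSParams-class].
#' @return named numeric vector.
#' @export
paramsAsVector <- function(params) {
  c(n_molecules = params@nMolecules, f_diff = params@fDiff,
    tau_diff_s = params@tauDiff, omega = params@omega,
    f_short = params@fShort, tau_short_s = params@tauShort,
    f_long = params@fLong, tau_long_s = params@tauLong)
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "FCSParams", function(object) {
  cat("FCSParams (diffusion + two binding populations)\n")
  cat(sprintf("  N = %.4g, omega = %.3g\n", object@nMolecules, object@omega))
  cat(sprintf("  diffusion: f = %.3f, tau_D = %.4g s\n",
              object@fDiff, object@tauDiff))
  cat(sprintf("  short-lived sites: f = %.3f, tau = %.4g s (koff = %.4g /s)\n",
              object@fShort, object@tauShort, 1 / object@tauShort))
  cat(sprintf("  long-lived sites:  f = %.3f, tau = %.4g s (koff = %.4g /s)\n",
              object@fLong, object@tauLong, 1 / object@tauLong))
})

setMethod("show", "ACFCurve", function(object) {
  cat(sprintf("ACFCurve: %d lags spanning [%.3g, %.3g] s%s\n",
              length(object@lags), min(object@lags), max(object@lags),
              if (length(object@sem)) " (with per-lag sem)" else ""))
})

setMethod("show", "IntensityTrace", function(object) {
  cat(sprintf(
    "IntensityTrace: %d bins of %.3g s (%.4g s, mean %.3g counts/bin)\n",
    length(object@counts), object@binWidth,
    length(object@counts) * object@binWidth, mean(object@counts)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s, wSSR = %.4g, %d evaluations)\n",
              if (object@converged) "converged" else "NOT converged",
              object@residualNorm, object@nEvaluations))
  show(object@params)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d particles in %.3g um box, D = %.3g um^2/s, %g Hz x %g s\n",
    object@nParticles, object@boxSize, object@dFree, object@rateHz,
    object@durationS))
  cat(sprintf("  waists %.3g x %.3g um (omega %.3g), brightness %.3g cps\n",
              object@wXY, object@wZ, object@wZ / object@wXY,
              object@brightness))
  cat(sprintf("  kon/koff short = %.3g/%.3g, long = %.3g/%.3g /s, seed %d\n",
              object@konShort, object@koffShort, object@konLong,
              object@koffLong, object@seed))
})

setMethod("show", "SimOutput", function(object) {
  cat("SimOutput\n  ")
  show(object@trace)
  cat(sprintf("  occupancy free/short/long = %.3f/%.3f/%.3f\n",
              object@occupancy["free"], object@occupancy["short"],
              object@occupancy["long"]))
})

setMethod("show", "NucleusScene", function(object) {
  cat(sprintf(
    "NucleusScene %dx%d px (%.3g um/px), phase %s, %d truth foci\n",
    nrow(object@image), ncol(object@image), object@pixelSize,
    object@phaseTruth, nrow(object@fociTruth)))
})

setMethod("show", "FociReport", function(object) {
  cat(sprintf("FociReport: CV = %.4g, nFoci = %d, iRFoci = %s\n",
              object@cv, object@nFoci,
              if (is.na(object@iRFoci)) "NA" else
                sprintf("%.4g", object@iRFoci)))
})

setMethod("show", "PCNAFeatures", function(object) {
  cat(sprintf(
    "PCNAFeatures: %d foci (interior %d / boundary %d), mean area %.3g px^2\n",
    object@nFoci, object@interiorCount, object@boundaryCount,
    object@meanFocusArea))
})

setMethod("show", "PhaseCall", function(object) {
  cat(sprintf("PhaseCall: %s (rule %s)\n", object@label, object@ruleFired))
})
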