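#' @import methods
NULL

## Central S4 containers. Validity methods enforce the model conventions so
## that downstream numerics never have to re-check them.

#' FCS diffusion-and-binding model parameters
#'
#' Parameter set of the autocorrelation model combining free 3D diffusion
#' through a Gaussian confocal volume with binding to two populations of
#' immobile chromatin sites:
#' \deqn{G(\tau) = \frac{f_D}{2^{3/2} N}\,
#'   \left(1+\frac{\tau}{\tau_D}\right)^{-1}
#'   \left(1+\frac{\tau}{\omega^2 \tau_D}\right)^{-1/2}
#'   + f_{short}\, e^{-\tau/\tau_{short}}
#'   + f_{long}\, e^{-\tau/\tau_{long}}}
#'
#' The three amplitude fractions are stored under the sum-to-one convention
#' \code{fDiff + fShort + fLong = 1}, and the two exponential timescales are
#' kept ordered (\code{tauShort < tauLong}) to remove the label-swap
#' degeneracy of the two binding terms.
#'
#' @slot nMolecules mean number of fluorescent molecules in the confocal
#'   volume (dimensionless, > 0).
#' @slot fDiff freely diffusing amplitude fraction in [0, 1].
#' @slot tauDiff characteristic diffusion time, seconds (> 0).
#' @slot omega axial-to-radial waist ratio of the observation volume (> 1).
#' @slot fShort,fLong amplitude fractions bound to short-/long-lived sites.
#' @slot tauShort,tauLong residence times at short-/long-lived sites,
#'   seconds; \code{tauShort < tauLong}.
#'
#' @seealso [fcsParams()] for the user-facing constructor, [evalACFModel()],
#'   [fitACF()].
#' @export
setClass("FCSParams",
  representation(
    nMolecules = "numeric",
    fDiff      = "numeric",
    tauDiff    = "numeric",
    omega      = "numeric",
    fShort     = "numeric",
    tauShort   = "numeric",
    fLong      = "numeric",
    tauLong    = "numeric"
  )
)

setValidity("FCSParams", function(object) {
  v <- c(object@nMolecules, object@fDiff, object@tauDiff, object@omega,
         object@fShort, object@tauShort, object@fLong, object@tauLong)
  if (length(v) != 8L || any(!is.finite(v)))
    return("all eight parameters must be finite scalars")
  if (object@nMolecules <= 0) return("nMolecules must be > 0")
  if (object@tauDiff <= 0 || object@tauShort <= 0 || object@tauLong <= 0)
    return("all characteristic times must be > 0")
  if (object@omega <= 1) return("omega must be > 1")
  f <- c(object@fDiff, object@fShort, object@fLong)
  if (any(f < 0) || any(f > 1))
    return("amplitude fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9)
    return("fDiff + fShort + fLong must equal 1 (within 1e-9)")
  if (object@tauShort >= object@tauLong)
    return("tauShort must be < tauLong (ordering convention)")
  TRUE
})

#' Autocorrelation curve
#'
#' A fluorescence autocorrelation function sampled at strictly increasing
#' lag times, optionally with a per-lag standard error (as produced by
#' [segmentACF()]); the fit target of [fitACF()].
#'
#' @slot lags lag times in seconds, strictly increasing, >= 0.
#' @slot g correlation amplitude at each lag (dimensionless, finite).
#' @slot sem optional per-lag standard error (same length as \code{lags},
#'   nonnegative), or \code{numeric(0)} when absent.
#'
#' @seealso [acfCurve()], [directACF()], [multitauACF()], [segmentACF()].
#' @export
setClass("ACFCurve",
  representation(lags = "numeric", g = "numeric", sem = "numeric")
)

setValidity("ACFCurve", function(object) {
  n <- length(object@lags)
  if (n == 0L) return("curve must contain at least one lag")
  if (any(!is.finite(object@lags)) || any(object@lags < 0))
    return("lags must be finite and >= 0")
  if (is.unsorted(object@lags, strictly = TRUE))
    return("lags must be strictly increasing")
  if (length(object@g) != n) return("g must match lags in length")
  if (any(!is.finite(object@g))) return("g must be finite")
  if (length(object@sem) > 0L) {
    if (length(object@sem) != n) return("sem must match lags in length")
    if (any(!is.finite(object@sem)) || any(object@sem < 0))
      return("sem must be finite and nonnegative")
  }
  TRUE
})

#' Binned photon-count intensity trace
#'
#' Photon counts per sampling bin from a single-point FCS acquisition
#' (typically 50 kHz sampling over minutes), the input of the correlator.
#'
#' @slot counts nonnegative integer counts per bin.
#' @slot binWidth bin width in seconds (reciprocal of the sampling rate).
#'
#' @seealso [intensityTrace()], [directACF()], [simulateTrace()].
#' @export
setClass("IntensityTrace",
  representation(counts = "integer", binWidth = "numeric")
)

setValidity("IntensityTrace", function(object) {
  if (length(object@counts) < 2L) return("trace must have >= 2 bins")
  if (anyNA(object@counts) || any(object@counts < 0L))
    return("counts must be nonnegative and non-missing")
  if (length(object@binWidth) != 1L || !is.finite(object@binWidth) ||
      object@binWidth <= 0)
    return("binWidth must be a positive scalar (seconds)")
  TRUE
})

#' Result of fitting the FCS model to an autocorrelation curve
#'
#' @slot params fitted [FCSParams-class].
#' @slot paramErrors named numeric vector of per-parameter standard errors
#'   (NA for parameters held fixed).
#' @slot residualNorm weighted sum of squared residuals at the optimum.
#' @slot converged logical; \code{FALSE} when the optimizer stalled.
#' @slot nEvaluations number of model evaluations used by the optimizer.
#' @slot koffShort,koffLong dissociation rates 1/tauShort and 1/tauLong
#'   (s^-1); the reciprocal of a residence time is the dissociation rate.
#' @slot offset fitted additive baseline (0 when not fitted); absorbs the
#'   small lag-independent offset that finite-record mean normalization
#'   leaves on estimated curves.
#'
#' @seealso [fitACF()], [koffFromResidence()].
#' @export
setClass("FitResult",
  representation(
    params       = "FCSParams",
    paramErrors  = "numeric",
    residualNorm = "numeric",
    converged    = "logical",
    nEvaluations = "integer",
    koffShort    = "numeric",
    koffLong     = "numeric",
    offset       = "numeric"
  ),
  prototype(offset = 0)
)

setValidity("FitResult", function(object) {
  if (!is.finite(object@residualNorm) || object@residualNorm < 0)
    return("residualNorm must be finite and >= 0")
  if (abs(object@koffShort - 1 / object@params@tauShort) > 0 ||
      abs(object@koffLong - 1 / object@params@tauLong) > 0)
    return("koff slots must equal the exact reciprocals of the residence times")
  TRUE
})

#' Configuration of the FCS Brownian dynamics simulator
#'
#' Describes a periodic box of point fluorophores diffusing through a 3D
#' Gaussian observation volume and exchanging with two classes of immobile
#' binding sites (pseudo-first-order kinetics, no direct short/long
#' exchange), emitting Poisson photon counts per sampling bin.
#'
#' @slot nParticles number of fluorophores in the box.
#' @slot boxSize periodic cube edge, micrometres (>= 10 radial waists).
#' @slot dFree free diffusion coefficient, um^2/s.
#' @slot wXY,wZ radial and axial 1/e^2 waists, um (omega = wZ/wXY).
#' @slot brightness counts per second per molecule at beam centre.
#' @slot rateHz sampling rate (default 50000, the standard acquisition
#'   regime; 25000 is used for dimmer, slower constructs).
#' @slot durationS trace duration, seconds (default 162, i.e. 2.7 min).
#' @slot konShort,koffShort,konLong,koffLong pseudo-first-order binding and
#'   unbinding rates, s^-1.
#' @slot seed integer seed; fully determines the output.
#'
#' @seealso [simConfig()], [simulateTrace()], [expectedParamsFromConfig()].
#' @export
setClass("SimConfig",
  representation(
    nParticles = "integer",
    boxSize    = "numeric",
    dFree      = "numeric",
    wXY        = "numeric",
    wZ         = "numeric",
    brightness = "numeric",
    rateHz     = "numeric",
    durationS  = "numeric",
    konShort   = "numeric",
    koffShort  = "numeric",
    konLong    = "numeric",
    koffLong   = "numeric",
    seed       = "integer"
  )
)

setValidity("SimConfig", function(object) {
  pos <- c(boxSize = object@boxSize, dFree = object@dFree, wXY = object@wXY,
           wZ = object@wZ, brightness = object@brightness,
           rateHz = object@rateHz, durationS = object@durationS)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return("boxSize, dFree, waists, brightness, rateHz, durationS must be > 0")
  rates <- c(object@konShort, object@koffShort, object@konLong,
             object@koffLong)
  if (any(!is.finite(rates)) || any(rates < 0))
    return("kinetic rates must be finite and >= 0")
  if (object@nParticles < 1L) return("nParticles must be >= 1")
  if (object@boxSize < 10 * object@wXY)
    return("boxSize must be >= 10 * wXY (stationarity of the focal signal)")
  if (object@wZ <= object@wXY)
    return("wZ must exceed wXY (omega > 1)")
  TRUE
})

#' Output of the FCS simulator
#'
#' @slot trace simulated [IntensityTrace-class].
#' @slot truth expected [FCSParams-class] implied by the configuration
#'   (see [expectedParamsFromConfig()]).
#' @slot occupancy named time-fraction of particle-steps spent free,
#'   short-bound and long-bound; sums to 1.
#'
#' @export
setClass("SimOutput",
  representation(trace = "IntensityTrace", truth = "FCSParams",
                 occupancy = "numeric")
)

setValidity("SimOutput", function(object) {
  if (length(object@occupancy) != 3L ||
      !identical(names(object@occupancy), c("free", "short", "long")))
    return("occupancy must be named c('free','short','long')")
  if (abs(sum(object@occupancy) - 1) > 1e-9)
    return("occupancy fractions must sum to 1")
  TRUE
})

#' Synthetic single-nucleus scene
#'
#' One synthetic confocal section of a nucleus: the intensity image, the
#' nucleus and nucleoli masks, the ground-truth list of planted foci and,
#' for PCNA renders, the true cell-cycle phase label.
#'
#' @slot image numeric matrix of nonnegative intensities (arbitrary units).
#' @slot nucleusMask,nucleoliMask logical matrices; nucleoli within nucleus.
#' @slot fociTruth data.frame with columns \code{x}, \code{y} (centre,
#'   pixels), \code{radius} (full width at half maximum, pixels) and
#'   \code{amplitude} (peak height in multiples of the background level).
#' @slot phaseTruth one of "G", "ES", "MS", "LS", or NA for plain scenes.
#' @slot pixelSize micrometres per pixel.
#' @slot background nucleoplasmic background level (a.u.).
#' @slot seed integer seed that produced the scene.
#'
#' @seealso [makeNucleus()], [addFoci()], [renderPCNA()].
#' @export
setClass("NucleusScene",
  representation(
    image        = "matrix",
    nucleusMask  = "matrix",
    nucleoliMask = "matrix",
    fociTruth    = "data.frame",
    phaseTruth   = "character",
    pixelSize    = "numeric",
    background   = "numeric",
    seed         = "integer"
  )
)

setValidity("NucleusScene", function(object) {
  if (!all(dim(object@image) == dim(object@nucleusMask)) ||
      !all(dim(object@image) == dim(object@nucleoliMask)))
    return("image and masks must share dimensions")
  if (any(object@image < 0)) return("image must be nonnegative")
  nuc <- object@nucleusMask; nucl <- object@nucleoliMask
  if (!is.logical(nuc) || !is.logical(nucl))
    return("masks must be logical matrices")
  if (any(nucl & !nuc)) return("nucleoli mask must lie inside nucleus mask")
  ft <- object@fociTruth
  need <- c("x", "y", "radius", "amplitude")
  if (!all(need %in% names(ft)))
    return("fociTruth must have columns x, y, radius, amplitude")
  if (nrow(ft) > 0L) {
    ij <- cbind(round(ft$x), round(ft$y))
    if (any(ij[, 1] < 1 | ij[, 1] > nrow(nuc) |
            ij[, 2] < 1 | ij[, 2] > ncol(nuc)) || !all(nuc[ij]))
      return("all truth foci centres must lie inside the nucleus mask")
  }
  if (!object@phaseTruth %in% c("G", "ES", "MS", "LS", NA_character_))
    return("phaseTruth must be G, ES, MS, LS or NA")
  TRUE
})

#' Per-nucleus foci quantification report
#'
#' @slot cv coefficient of variation of nuclear intensity (SD/mean over
#'   nucleus pixels excluding nucleoli; population SD).
#' @slot nFoci number of detected foci passing the size filter.
#' @slot iRFoci mean intensity over all retained foci pixels relative to
#'   the mean of the analysis region; \code{NA} when no foci were found.
#' @slot foci data.frame with one row per retained focus: \code{label},
#'   \code{area} (px^2), \code{meanIntensity}, \code{cx}, \code{cy}.
#'
#' @seealso [detectFoci()], [computeCV()].
#' @export
setClass("FociReport",
  representation(cv = "numeric", nFoci = "integer", iRFoci = "numeric",
                 foci = "data.frame")
)

setValidity("FociReport", function(object) {
  if (object@nFoci != nrow(object@foci))
    return("nFoci must equal the number of per-focus records")
  if (object@nFoci > 0L && (!is.finite(object@iRFoci) || object@iRFoci <= 0))
    return("iRFoci must be > 0 when foci are present")
  TRUE
})

#' Geometric features of a PCNA focal pattern
#'
#' @slot nFoci number of detected foci.
#' @slot medianFocusArea,meanFocusArea focus areas in px^2 (NA when none).
#' @slot fracPeripheral fraction of foci in the outer radial shell.
#' @slot fracPerinucleolar fraction of foci within the nucleoli-adjacent
#'   ring.
#' @slot fracInterior fraction in neither region.
#' @slot interiorCount,boundaryCount focus counts; boundary = peripheral
#'   or perinucleolar.
#'
#' @seealso [extractPCNAFeatures()], [classifyPhase()].
#' @export
setClass("PCNAFeatures",
  representation(
    nFoci             = "integer",
    medianFocusArea   = "numeric",
    meanFocusArea     = "numeric",
    fracPeripheral    = "numeric",
    fracPerinucleolar = "numeric",
    fracInterior      = "numeric",
    interiorCount     = "integer",
    boundaryCount     = "integer"
  )
)

setValidity("PCNAFeatures", function(object) {
  fr <- c(object@fracPeripheral, object@fracPerinucleolar,
          object@fracInterior)
  if (any(is.finite(fr) & (fr < 0 | fr > 1)))
    return("fractions must lie in [0, 1]")
  if (object@interiorCount + object@boundaryCount > object@nFoci)
    return("interior + boundary counts cannot exceed nFoci")
  TRUE
})

#' Cell-cycle phase call from a PCNA pattern
#'
#' @slot label one of "G", "ES", "MS", "LS", "DISCARD".
#' @slot ruleFired identifier of the decision branch that produced the call.
#' @slot features the [PCNAFeatures-class] the call was based on.
#'
#' @seealso [classifyPhase()].
#' @export
setClass("PhaseCall",
  representation(label = "character", ruleFired = "character",
                 features = "PCNAFeatures")
)

setValidity("PhaseCall", function(object) {
  if (!object@label %in% c("G", "ES", "MS", "LS", "DISCARD"))
    return("label must be one of G, ES, MS, LS, DISCARD")
  TRUE
})
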