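## Photon-count autocorrelation estimation. All estimators use the
## symmetric normalization
##   G(k) = <F(t) F(t+k)> / (<F(t)>_t <F(t+k)>_t) - 1,
## where the two means are taken over the overlapping samples of the
## leading and lagged segments at each lag. This suppresses the bias of
## slow drifts relative to dividing by the global squared mean, and
## divides by the number of overlapping pairs at each lag. Lag 0
## (shot-noise dominated) is never reported.
##
## Any mean-normalized estimator on a finite record of length T carries a
## small lag-independent negative offset of order 2 integral(G)/T; the
## model fit absorbs it through an additive baseline parameter (see
## fitACF), so the estimator itself stays simple and its per-segment
## variance honest.

## symmetric estimator at integer lags
.acfAtLags <- function(x, lagBins) {
  n <- length(x)
  vapply(lagBins, function(k) {
    a <- x[seq_len(n - k)]
    b <- x[seq.int(k + 1L, n)]
    mean(a * b) / (mean(a) * mean(b)) - 1
  }, 0)
}

.checkTrace <- function(trace) {
  stopifnot(is(trace, "IntensityTrace"))
  validObject(trace)
  if (mean(trace@counts) == 0)
    stop("degenerate trace: mean count is zero")
}

#' Direct (linear-lag) autocorrelation of a photon-count trace
#'
#' Estimates \eqn{G(\tau) = \langle\delta F(t)\,\delta F(t+\tau)\rangle /
#' \langle F\rangle^2} at every lag from 1 to \code{maxLagBins} sampling
#' bins, using only overlapping samples at each lag and the symmetric
#' normalization described above. This is the exact reference estimator
#' against which the multi-tau path is validated.
#'
#' @param trace an [IntensityTrace-class] with more than
#'   \code{2 * maxLagBins} bins and positive mean.
#' @param maxLagBins largest lag, in bins.
#' @return an [ACFCurve-class] without per-lag errors.
#' @export
directACF <- function(trace, maxLagBins) {
  .checkTrace(trace)
  maxLagBins <- as.integer(maxLagBins)
  if (maxLagBins < 1L) stop("maxLagBins must be >= 1")
  if (length(trace@counts) <= 2L * maxLagBins)
    stop("trace must be longer than twice the largest lag")
  ks <- seq_len(maxLagBins)
  acfCurve(ks * trace@binWidth,
           .acfAtLags(as.numeric(trace@counts), ks))
}

## integer lag ladder of one multi-tau level
.mtLevelLags <- function(level, m) {
  if (level == 0L) seq_len(m) else seq.int(m %/% 2L + 1L, m)
}

## shared multi-tau engine on a plain numeric signal
.multitauEngine <- function(counts, binWidth, m, maxLagS) {
  sig <- as.numeric(counts)
  width <- binWidth
  level <- 0L
  lagsOut <- list(); gOut <- list()
  repeat {
    ks <- .mtLevelLags(level, m)
    lagS <- ks * width
    ok <- lagS <= maxLagS & (2L * ks) < length(sig)
    if (any(ok)) {
      lagsOut[[level + 1L]] <- lagS[ok]
      gOut[[level + 1L]] <- .acfAtLags(sig, ks[ok])
    }
    if (!all(ok)) break
    n2 <- length(sig) %/% 2L
    if (n2 <= 2L * m) break
    sig <- sig[seq.int(1L, 2L * n2, 2L)] + sig[seq.int(2L, 2L * n2, 2L)]
    width <- width * 2
    level <- level + 1L
  }
  list(lags = unlist(lagsOut), g = unlist(gOut))
}

#' Multi-tau autocorrelation of a photon-count trace
#'
#' Quasi-logarithmic correlator: within the first octave the lags are
#' linear in sampling bins (1..\code{pointsPerOctave}) and coincide exactly
#' with [directACF()]; each subsequent level doubles the bin width by
#' summing adjacent bins and evaluates lags
#' \code{pointsPerOctave/2 + 1 .. pointsPerOctave} in rebinned units.
#' This covers millisecond-to-minute lags at a cost that shrinks
#' geometrically with lag.
#'
#' @param trace an [IntensityTrace-class].
#' @param pointsPerOctave even number of lags per octave (default 16).
#' @param maxLagS largest lag to report, seconds; default a quarter of the
#'   trace duration.
#' @return an [ACFCurve-class].
#' @export
multitauACF <- function(trace, pointsPerOctave = 16L, maxLagS = NULL) {
  .checkTrace(trace)
  m <- as.integer(pointsPerOctave)
  if (m < 2L || m %% 2L != 0L)
    stop("pointsPerOctave must be an even integer >= 2")
  dur <- length(trace@counts) * trace@binWidth
  if (is.null(maxLagS)) maxLagS <- dur / 4
  if (length(trace@counts) <= 2L * m)
    stop("trace must be longer than twice the first-octave lag range")
  res <- .multitauEngine(trace@counts, trace@binWidth, m, maxLagS)
  acfCurve(res$lags, res$g)
}

#' Segment-averaged autocorrelation with per-lag standard errors
#'
#' Splits the trace into \code{nSegments} equal-length contiguous
#' segments, computes the multi-tau ACF of each segment and of the whole
#' record, and returns per lag either the full-record estimate (default)
#' or the mean of the per-segment estimates, together with the standard
#' error across segments. The per-lag errors feed the weighted fit in
#' [fitACF()].
#'
#' The full-record estimate is preferred as the curve value because
#' per-segment mean normalization depresses the curve by a nearly
#' lag-independent offset of order \eqn{2\int G / T_{segment}}, which is
#' substantial when residence times reach a few percent of the segment
#' length; on the full record the same offset is \code{nSegments}-fold
#' smaller. Either way [fitACF()] can absorb the remainder with its
#' additive baseline parameter.
#'
#' @param trace an [IntensityTrace-class].
#' @param nSegments number of segments (>= 2).
#' @param pointsPerOctave passed to the multi-tau ladder.
#' @param maxLagS largest lag, seconds; default half the segment
#'   duration, and always below the segment duration.
#' @param value \code{"full"} (default) to report the full-record
#'   estimate, \code{"segment-mean"} for the mean of per-segment curves.
#' @param biasCorrect when \code{TRUE} (default), the reported curve is
#'   corrected for the record-length offset of mean-normalized
#'   estimators: every value is raised by \eqn{2\int \hat G\, d\tau / T}
#'   (T = record length for \code{"full"}, segment length for
#'   \code{"segment-mean"}), iterated to self-consistency. The
#'   correction is a deterministic function of the curve itself and
#'   removes the systematic depression of slow components whose
#'   residence times approach a few percent of T.
#' @return an [ACFCurve-class] with \code{sem}.
#' @export
segmentACF <- function(trace, nSegments, pointsPerOctave = 16L,
                       maxLagS = NULL, value = c("full", "segment-mean"),
                       biasCorrect = TRUE) {
  .checkTrace(trace)
  value <- match.arg(value)
  nSegments <- as.integer(nSegments)
  if (nSegments < 2L) stop("nSegments must be >= 2")
  m <- as.integer(pointsPerOctave)
  segLen <- length(trace@counts) %/% nSegments
  if (segLen <= 4L * m)
    stop("segments too short for the requested lag ladder")
  segDur <- segLen * trace@binWidth
  if (is.null(maxLagS)) maxLagS <- segDur / 2
  if (maxLagS >= segDur)
    stop("segments must be longer than the largest lag")
  per <- lapply(seq_len(nSegments), function(i) {
    idx <- seq.int((i - 1L) * segLen + 1L, i * segLen)
    .multitauEngine(trace@counts[idx], trace@binWidth, m, maxLagS)
  })
  ## equal segment lengths give identical ladders
  nlag <- length(per[[1L]]$lags)
  gm <- vapply(per, `[[`, numeric(nlag), "g")
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1L)
  sem <- apply(gm, 1L, stats::sd) / sqrt(nSegments)
  mu <- if (value == "full") {
    full <- .multitauEngine(trace@counts, trace@binWidth, m, maxLagS)
    full$g[seq_len(nlag)]
  } else rowMeans(gm)
  if (biasCorrect) {
    tRec <- if (value == "full")
      length(trace@counts) * trace@binWidth else segDur
    lg <- per[[1L]]$lags
    g <- mu
    for (i in 1:3) {  # self-consistent record-offset correction
      integ <- sum(diff(lg) * (g[-length(g)] + g[-1]) / 2) + lg[1] * g[1]
      g <- mu + 2 * integ / tRec
    }
    mu <- g
  }
  acfCurve(per[[1L]]$lags, mu, sem)
}
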