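## Rule-based S-phase staging from PCNA focal patterns. The qualitative
## vocabulary (many small dispersed foci = early S; perinucleolar or
## peripheral foci = mid S; few large foci = late S; none = G) is
## quantified by configurable thresholds; the two transition rules are:
## (1) between early and mid S the call follows the majority location of
## the foci, and the cell is discarded when interior and boundary counts
## are similar; (2) a cell with few but larger-than-reference foci is
## called late S even when they sit at the periphery.

#' Classifier rule configuration
#'
#' Thresholds quantifying the qualitative staging rules. \code{"similar"}
#' interior/boundary counts means a relative difference below
#' \code{similarityTol}; \code{"bigger than the average size"} is
#' referenced to the median focus area of early-S-like calibration scenes
#' (\code{referenceAreaPx2}, see [calibrateReferenceArea()]).
#'
#' @param shellThreshold normalized radial position beyond which a focus
#'   counts as peripheral (matches the scene generator convention).
#' @param ringPx perinucleolar ring width, px.
#' @param similarityTol discard the cell when
#'   \code{abs(interior - boundary) / nFoci < similarityTol}.
#' @param minFoci fewer foci than this is called G.
#' @param bigAreaFactor late-S area multiplier over the reference area.
#' @param fewMax maximal focus count for the late-S rule.
#' @param referenceAreaPx2 median early-S focus area, px^2.
#' @param resolutionUm,pixelUm lateral optical resolution and pixel size
#'   (their ratio is the size-filter resolution in px).
#' @return a list of class \code{"pcnaRuleConfig"}.
#' @export
pcnaRuleConfig <- function(shellThreshold = 0.75, ringPx = 3L,
                           similarityTol = 0.2, minFoci = 3L,
                           bigAreaFactor = 2, fewMax = 10L,
                           referenceAreaPx2 = 9,
                           resolutionUm = 0.25, pixelUm = 0.1) {
  cfg <- list(shellThreshold = shellThreshold, ringPx = as.integer(ringPx),
              similarityTol = similarityTol, minFoci = as.integer(minFoci),
              bigAreaFactor = bigAreaFactor, fewMax = as.integer(fewMax),
              referenceAreaPx2 = referenceAreaPx2,
              resolutionUm = resolutionUm, pixelUm = pixelUm)
  stopifnot(cfg$shellThreshold > 0, cfg$shellThreshold < 1,
            cfg$similarityTol >= 0, cfg$similarityTol <= 1,
            cfg$minFoci >= 1L, cfg$bigAreaFactor > 1,
            cfg$referenceAreaPx2 > 0, cfg$resolutionUm > 0,
            cfg$pixelUm > 0)
  class(cfg) <- "pcnaRuleConfig"
  cfg
}

#' Calibrate the late-S reference focus area
#'
#' Renders \code{n} early-S-like scenes and returns the median detected
#' focus area, the reference against which the late-S "bigger than
#' average" rule compares. Store the result in
#' \code{pcnaRuleConfig(referenceAreaPx2 = ...)}.
#'
#' @param cfg a [pcnaRuleConfig()].
#' @param sceneCfg a [sceneConfig()].
#' @param n number of calibration scenes.
#' @param seed integer seed.
#' @return median focus area, px^2.
#' @export
calibrateReferenceArea <- function(cfg = pcnaRuleConfig(),
                                   sceneCfg = sceneConfig(), n = 20L,
                                   seed = 1L) {
  areas <- unlist(lapply(seq_len(n), function(i) {
    sc <- renderPCNA("ES", sceneCfg, seed = seed + i)
    rep <- detectFoci(sc@image, sc@nucleusMask, sc@nucleoliMask,
                      cfg$resolutionUm / cfg$pixelUm)
    rep@foci$area
  }))
  stats::median(areas)
}

#' Extract geometric features of a PCNA focal pattern
#'
#' Runs [detectFoci()] and classifies every detected focus centroid by its
#' normalized radial position (peripheral beyond the shell threshold) and
#' by membership of the perinucleolar ring (nucleoli dilated by
#' \code{ringPx}). The boundary set is the union of peripheral and
#' perinucleolar foci, since both locations signal mid S. Deterministic.
#'
#' @param image numeric intensity matrix.
#' @param nucleusMask,nucleoliMask logical masks.
#' @param cfg a [pcnaRuleConfig()].
#' @return a [PCNAFeatures-class].
#' @export
extractPCNAFeatures <- function(image, nucleusMask, nucleoliMask = NULL,
                                cfg = pcnaRuleConfig()) {
  if (is.null(nucleoliMask))
    nucleoliMask <- matrix(FALSE, nrow(image), ncol(image))
  rep <- detectFoci(image, nucleusMask, nucleoliMask,
                    cfg$resolutionUm / cfg$pixelUm)
  nF <- rep@nFoci
  if (nF == 0L) {
    return(new("PCNAFeatures", nFoci = 0L,
               medianFocusArea = NA_real_, meanFocusArea = NA_real_,
               fracPeripheral = 0, fracPerinucleolar = 0,
               fracInterior = 0, interiorCount = 0L, boundaryCount = 0L))
  }
  rr <- .radialRank(nucleusMask)
  scene <- new("NucleusScene", image = image, nucleusMask = nucleusMask,
               nucleoliMask = nucleoliMask,
               fociTruth = data.frame(x = numeric(0), y = numeric(0),
                                      radius = numeric(0),
                                      amplitude = numeric(0)),
               phaseTruth = NA_character_, pixelSize = cfg$pixelUm,
               background = 1, seed = 0L)
  ring <- .nucleoliRing(scene, cfg$ringPx)

  ci <- pmin(pmax(round(rep@foci$cx), 1L), nrow(image))
  cj <- pmin(pmax(round(rep@foci$cy), 1L), ncol(image))
  pos <- cbind(ci, cj)
  rpos <- rr[pos]
  ## a centroid rounding just outside the nucleus counts as peripheral
  rpos[is.na(rpos)] <- 1
  peri <- rpos > cfg$shellThreshold
  ringHit <- ring[pos]
  boundary <- peri | ringHit
  new("PCNAFeatures", nFoci = nF,
      medianFocusArea = stats::median(rep@foci$area),
      meanFocusArea = mean(rep@foci$area),
      fracPeripheral = mean(peri),
      fracPerinucleolar = mean(ringHit),
      fracInterior = mean(!boundary),
      interiorCount = as.integer(sum(!boundary)),
      boundaryCount = as.integer(sum(boundary)))
}

#' Classify a PCNA pattern into a cell-cycle stage
#'
#' Decision tree over [PCNAFeatures-class]:
#' \enumerate{
#'   \item fewer than \code{minFoci} foci: G (homogeneous distribution);
#'   \item at most \code{fewMax} foci with mean area at least
#'     \code{bigAreaFactor} times the reference area: LS, even when the
#'     foci sit at the periphery (the mid-to-late transition rule);
#'   \item otherwise the majority location decides ES (interior) or MS
#'     (boundary = peripheral or perinucleolar), and the cell is
#'     DISCARDed when the two counts are similar
#'     (\code{abs(interior - boundary)/nFoci < similarityTol}).
#' }
#' Deterministic, and invariant to intensity scaling of the underlying
#' image (the threshold scales with the image).
#'
#' @param features a [PCNAFeatures-class].
#' @param cfg a [pcnaRuleConfig()].
#' @return a [PhaseCall-class] with the fired rule recorded.
#' @export
classifyPhase <- function(features, cfg = pcnaRuleConfig()) {
  stopifnot(is(features, "PCNAFeatures"))
  validObject(features)
  n <- features@nFoci
  call <- if (n < cfg$minFoci) {
    c("G", "few-foci-G")
  } else if (n <= cfg$fewMax &&
             isTRUE(features@meanFocusArea >=
                    cfg$bigAreaFactor * cfg$referenceAreaPx2)) {
    c("LS", "big-few-LS")
  } else {
    i <- features@interiorCount
    b <- features@boundaryCount
    if (abs(i - b) / n < cfg$similarityTol) {
      c("DISCARD", "similar-counts-discard")
    } else if (i > b) {
      c("ES", "majority-interior-ES")
    } else {
      c("MS", "majority-boundary-MS")
    }
  }
  new("PhaseCall", label = call[1], ruleFired = call[2],
      features = features)
}

#' Evaluate the classifier against labeled synthetic scenes
#'
#' Classifies every scene and compares with its recorded ground-truth
#' phase. Accuracy is computed over non-discarded calls on scenes with an
#' unambiguous truth label; the discard rate is reported separately.
#'
#' @param scenes list of [NucleusScene-class] objects.
#' @param cfg a [pcnaRuleConfig()].
#' @return a list with \code{calls} (data.frame of truth, label, rule),
#'   \code{confusion} (truth x call table), \code{accuracy},
#'   \code{discardRate}, and per-class \code{precision} and \code{recall}.
#' @export
evaluateClassifier <- function(scenes, cfg = pcnaRuleConfig()) {
  stopifnot(length(scenes) >= 1L)
  calls <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    ft <- extractPCNAFeatures(sc@image, sc@nucleusMask, sc@nucleoliMask,
                              cfg)
    pc <- classifyPhase(ft, cfg)
    data.frame(scene = i, truth = sc@phaseTruth, call = pc@label,
               rule = pc@ruleFired, nFoci = ft@nFoci)
  }))
  labeled <- calls[!is.na(calls$truth), ]
  kept <- labeled[labeled$call != "DISCARD", ]
  acc <- if (nrow(kept)) mean(kept$call == kept$truth) else NA_real_
  lev <- c("G", "ES", "MS", "LS")
  conf <- table(truth = factor(labeled$truth, lev),
                call = factor(labeled$call, c(lev, "DISCARD")))
  prec <- vapply(lev, function(l) {
    d <- sum(kept$call == l)
    if (d == 0) NA_real_ else sum(kept$call == l & kept$truth == l) / d
  }, 0)
  rec <- vapply(lev, function(l) {
    d <- sum(kept$truth == l)
    if (d == 0) NA_real_ else sum(kept$call == l & kept$truth == l) / d
  }, 0)
  list(calls = calls, confusion = conf, accuracy = acc,
       discardRate = mean(calls$call == "DISCARD"),
       precision = prec, recall = rec)
}
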