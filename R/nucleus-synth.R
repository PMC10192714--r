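## Synthetic single-nucleus scenes with ground truth. 2D scenes (one
## confocal section); foci are isotropic Gaussians whose "radius" is the
## full width at half maximum in pixels. All generators are
## seed-deterministic (R RNG under a locally restored seed).

#' Scene generator configuration
#'
#' Fixture conventions for synthetic nuclei. The defaults emulate a 60x
#' oil-immersion confocal section at 0.1 um/px with an optical resolution
#' of 0.25 um: an elliptical nucleus of semi-axes around 4 x 3 um with 1-3
#' darker elliptical nucleoli, a flat nucleoplasmic background and
#' (optionally) Poisson-scaled noise of configurable SNR.
#'
#' @param size frame edge, px.
#' @param pixelSize um per px.
#' @param background nucleoplasmic intensity level, a.u.
#' @param nucleusAxes ranges of the nucleus semi-axes, px:
#'   \code{list(a = c(lo, hi), b = c(lo, hi))}.
#' @param nNucleoli integer range of nucleolus count.
#' @param nucleoliAxes range of nucleolus semi-axes, px.
#' @param nucleoliLevel nucleolus intensity as a fraction of background.
#' @param noiseSNR signal-to-noise ratio of the background (mean/SD under
#'   Poisson-scaled noise); \code{Inf} disables noise.
#' @param shellThreshold normalized radial position beyond which a
#'   location counts as the peripheral shell.
#' @param ringPx width of the perinucleolar ring (dilation of the
#'   nucleoli mask), px.
#' @param maxTries placement attempts per focus before giving up.
#' @return a list of class \code{"sceneConfig"}.
#' @export
sceneConfig <- function(size = 160L, pixelSize = 0.1, background = 100,
                        nucleusAxes = list(a = c(46, 54), b = c(34, 42)),
                        nNucleoli = c(1L, 3L), nucleoliAxes = c(5, 8),
                        nucleoliLevel = 0.4, noiseSNR = Inf,
                        shellThreshold = 0.75, ringPx = 3L,
                        maxTries = 200L) {
  cfg <- list(size = as.integer(size), pixelSize = pixelSize,
              background = background, nucleusAxes = nucleusAxes,
              nNucleoli = as.integer(nNucleoli),
              nucleoliAxes = nucleoliAxes, nucleoliLevel = nucleoliLevel,
              noiseSNR = noiseSNR, shellThreshold = shellThreshold,
              ringPx = as.integer(ringPx), maxTries = as.integer(maxTries))
  stopifnot(cfg$size >= 64L, cfg$background > 0,
            cfg$nucleoliLevel > 0, cfg$nucleoliLevel < 1,
            cfg$noiseSNR > 0, cfg$shellThreshold > 0,
            cfg$shellThreshold < 1)
  class(cfg) <- "sceneConfig"
  cfg
}

## normalized radial position for every nucleus pixel: sqrt of the
## fraction of nucleus pixels strictly more interior (larger distance to
## the boundary). 0 at the most interior point, -> 1 at the rim; equals
## r/R exactly on a disk. Shared by focus placement and by the phase
## classifier so that "peripheral" means the same thing on both sides.
.radialRank <- function(nucleusMask) {
  d <- EBImage::imageData(EBImage::distmap(nucleusMask * 1))
  out <- matrix(NA_real_, nrow(nucleusMask), ncol(nucleusMask))
  dv <- d[nucleusMask]
  fLE <- stats::ecdf(dv)
  out[nucleusMask] <- sqrt(pmax(0, 1 - fLE(dv)))
  out
}

## perinucleolar ring: nucleoli dilated by ringPx, minus the nucleoli
.nucleoliRing <- function(scene, ringPx) {
  if (!any(scene@nucleoliMask)) {
    return(matrix(FALSE, nrow(scene@image), ncol(scene@image)))
  }
  br <- EBImage::makeBrush(2L * ringPx + 1L, shape = "disc")
  dil <- EBImage::imageData(
    EBImage::dilate(scene@nucleoliMask * 1, br)) > 0
  dil & !scene@nucleoliMask & scene@nucleusMask
}

.ellipseMask <- function(size, cx, cy, a, b) {
  x <- matrix(seq_len(size), size, size)
  y <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

#' Generate a background-only synthetic nucleus
#'
#' Elliptical nucleus with 1-3 non-overlapping elliptical nucleoli, a flat
#' nucleoplasmic background and optional Poisson-scaled noise. With noise
#' disabled the image equals the background level everywhere inside the
#' nucleus outside the nucleoli.
#'
#' @param cfg a [sceneConfig()].
#' @param seed integer seed; identical seeds give identical scenes.
#' @return a [NucleusScene-class] without foci.
#' @export
makeNucleus <- function(cfg = sceneConfig(), seed = 1L) {
  stopifnot(inherits(cfg, "sceneConfig"))
  .withSeed(seed, {
    size <- cfg$size
    a <- stats::runif(1, cfg$nucleusAxes$a[1], cfg$nucleusAxes$a[2])
    b <- stats::runif(1, cfg$nucleusAxes$b[1], cfg$nucleusAxes$b[2])
    if (2 * max(a, b) > size - 8)
      stop("requested nucleus does not fit the frame")
    cx <- size / 2 + stats::runif(1, -3, 3)
    cy <- size / 2 + stats::runif(1, -3, 3)
    nuc <- .ellipseMask(size, cx, cy, a, b)

    nN <- if (cfg$nNucleoli[1] == cfg$nNucleoli[2]) cfg$nNucleoli[1] else
      sample(seq.int(cfg$nNucleoli[1], cfg$nNucleoli[2]), 1L)
    nucl <- matrix(FALSE, size, size)
    centers <- NULL
    for (i in seq_len(nN)) {
      placed <- FALSE
      for (try in seq_len(cfg$maxTries)) {
        na <- stats::runif(1, cfg$nucleoliAxes[1], cfg$nucleoliAxes[2])
        nb <- stats::runif(1, cfg$nucleoliAxes[1], cfg$nucleoliAxes[2])
        ## keep nucleoli interior (elliptical coordinate < 0.55)
        th <- stats::runif(1, 0, 2 * pi); rr <- sqrt(stats::runif(1)) * 0.55
        px <- cx + rr * a * cos(th); py <- cy + rr * b * sin(th)
        if (!is.null(centers) &&
            any(sqrt((centers[, 1] - px)^2 + (centers[, 2] - py)^2) <
                (2.2 * max(na, nb)))) next
        cand <- .ellipseMask(size, px, py, na, nb)
        if (any(cand & !nuc) || any(cand & nucl)) next
        nucl <- nucl | cand
        centers <- rbind(centers, c(px, py))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place nucleoli within the configured tries")
    }

    img <- matrix(0, size, size)
    img[nuc] <- cfg$background
    img[nucl] <- cfg$background * cfg$nucleoliLevel
    if (is.finite(cfg$noiseSNR)) {
      k <- cfg$noiseSNR^2 / cfg$background
      img[] <- stats::rpois(length(img), img * k) / k
    }
    new("NucleusScene", image = img, nucleusMask = nuc,
        nucleoliMask = nucl,
        fociTruth = data.frame(x = numeric(0), y = numeric(0),
                               radius = numeric(0), amplitude = numeric(0)),
        phaseTruth = NA_character_, pixelSize = cfg$pixelSize,
        background = cfg$background, seed = as.integer(seed))
  })
}

#' Add Gaussian foci to a scene
#'
#' Plants \code{n} isotropic 2D Gaussian foci at positions drawn according
#' to \code{placement}:
#' \describe{
#'   \item{uniform}{anywhere in the nucleus outside the nucleoli;}
#'   \item{interior}{the sub-shell region (normalized radial position
#'     below the shell threshold), outside the perinucleolar ring;}
#'   \item{peripheral}{the outer radial shell;}
#'   \item{perinucleolar}{the ring around the nucleoli.}
#' }
#' Non-overlap is enforced by a minimum centre distance equal to the sum
#' of the two radii (FWHM), scaled by \code{minSepFactor}; a placement
#' region too small for \code{n} such foci raises an error. Dense
#' replication-focus patterns use a factor below 1, since real early-S
#' foci partially overlap at this density. The focus peak height is
#' \code{amplitude * background} and its Gaussian sigma is
#' \code{radius / 2.355} (radius = FWHM).
#'
#' @param scene a [NucleusScene-class].
#' @param n number of foci (0 returns the scene unchanged).
#' @param radiusPx range of focus FWHM, px.
#' @param amplitude range of peak amplitude, in multiples of background.
#' @param placement placement rule, see above.
#' @param cfg the [sceneConfig()] carrying shell/ring conventions.
#' @param minSepFactor multiplier on the sum-of-radii minimum centre
#'   distance (1 = strict non-overlap).
#' @param seed integer seed; \code{NULL} derives one from the scene seed
#'   and the current focus count.
#' @return the scene with foci added and \code{fociTruth} updated.
#' @export
addFoci <- function(scene, n, radiusPx = c(3, 4.5), amplitude = c(6, 10),
                    placement = c("uniform", "interior", "peripheral",
                                  "perinucleolar"),
                    cfg = sceneConfig(), minSepFactor = 1, seed = NULL) {
  stopifnot(is(scene, "NucleusScene"), n >= 0)
  placement <- match.arg(placement)
  if (n == 0L) return(scene)
  if (is.null(seed))
    seed <- scene@seed + 7919L * (nrow(scene@fociTruth) + 1L) + as.integer(n)
  .withSeed(seed, {
    rr <- .radialRank(scene@nucleusMask)
    ring <- .nucleoliRing(scene, cfg$ringPx)
    allowed <- switch(placement,
      uniform       = scene@nucleusMask & !scene@nucleoliMask,
      interior      = scene@nucleusMask & !scene@nucleoliMask & !ring &
                      !is.na(rr) & rr <= cfg$shellThreshold,
      peripheral    = scene@nucleusMask & !scene@nucleoliMask &
                      !is.na(rr) & rr > cfg$shellThreshold,
      perinucleolar = ring & !scene@nucleoliMask)
    idx <- which(allowed)
    if (length(idx) < n)
      stop("placement region too small for the requested foci")
    sz <- nrow(scene@image)
    px <- ((idx - 1L) %% sz) + 1L
    py <- ((idx - 1L) %/% sz) + 1L

    rad <- stats::runif(n, radiusPx[1], radiusPx[length(radiusPx)])
    amp <- stats::runif(n, amplitude[1], amplitude[length(amplitude)])
    acc <- matrix(numeric(0), 0, 2)
    accR <- numeric(0)
    order_try <- sample.int(length(idx))
    ti <- 1L
    tries <- 0L
    for (i in seq_len(n)) {
      repeat {
        tries <- tries + 1L
        if (tries > cfg$maxTries * n || ti > length(order_try))
          stop("placement region too small for the requested foci ",
               "(non-overlap constraint)")
        j <- order_try[ti]; ti <- ti + 1L
        cxy <- c(px[j], py[j])
        if (nrow(acc) == 0L ||
            all(sqrt(rowSums(sweep(acc, 2, cxy)^2)) >=
                minSepFactor * (accR + rad[i]))) {
          acc <- rbind(acc, cxy)
          accR <- c(accR, rad[i])
          break
        }
      }
    }

    img <- scene@image
    xg <- matrix(seq_len(sz), sz, sz)
    yg <- matrix(seq_len(sz), sz, sz, byrow = TRUE)
    for (i in seq_len(n)) {
      sg <- rad[i] / 2.355
      d2 <- (xg - acc[i, 1])^2 + (yg - acc[i, 2])^2
      img <- img + amp[i] * scene@background *
        exp(-d2 / (2 * sg^2)) * (d2 < (6 * rad[i])^2)
    }
    scene@image <- img
    scene@fociTruth <- rbind(
      scene@fociTruth,
      data.frame(x = acc[, 1], y = acc[, 2], radius = rad,
                 amplitude = amp))
    validObject(scene)
    scene
  })
}

#' Render a canonical PCNA replication pattern
#'
#' Produces the focal pattern characteristic of each cell-cycle stage as
#' seen through a PCNA fusion reporter: G cells (G1/G2, pooled) show a
#' homogeneous distribution without replication foci; early-S cells many
#' small foci dispersed through the nuclear interior; mid-S cells foci
#' concentrated at the nuclear periphery and around nucleoli; late-S
#' cells few foci at least twice the early-S size. Transition mixtures
#' are available for exercising the tie-breaking rules of the
#' classifier: \code{"ES_MS"} places interior and peripheral foci in a
#' configurable proportion, \code{"MS_LS"} inflates the size of an
#' M-S-like pattern.
#'
#' Focus counts and sizes per phase are generator conventions (the
#' qualitative pattern vocabulary does not quantify them); they are
#' chosen so the patterns are unambiguous at the default classifier
#' thresholds.
#'
#' @param phase one of \code{"G"}, \code{"ES"}, \code{"MS"}, \code{"LS"},
#'   \code{"ES_MS"}, \code{"MS_LS"}.
#' @param cfg a [sceneConfig()].
#' @param seed integer seed.
#' @param mixFraction for \code{"ES_MS"}: fraction of foci placed in the
#'   interior (0.5 gives exactly equal interior/peripheral counts).
#' @param sizeInflation for \code{"MS_LS"}: focus FWHM multiplier.
#' @return a [NucleusScene-class] with \code{phaseTruth} recorded
#'   (\code{NA} for transition mixtures, whose truth is ambiguous by
#'   construction).
#' @export
renderPCNA <- function(phase, cfg = sceneConfig(), seed = 1L,
                       mixFraction = 0.5, sizeInflation = 2) {
  phases <- c("G", "ES", "MS", "LS", "ES_MS", "MS_LS")
  if (!is.character(phase) || length(phase) != 1L || !phase %in% phases)
    stop("unknown phase token: ", paste(phase, collapse = ","))
  scene <- makeNucleus(cfg, seed)
  esRad <- c(2.5, 3.5)   # early-S focus FWHM, px
  esAmp <- c(6, 10)      # peak amplitude, x background
  drawN <- function(lo, hi) .withSeed(seed + 211L, sample(lo:hi, 1L))
  ## perinucleolar rings can be small; overflow goes to the periphery,
  ## which signals the same stage
  dense <- 0.6  # partial overlap allowed in crowded patterns
  periMix <- function(s, nPeri, nRing, rad) {
    s <- addFoci(s, nPeri, rad, esAmp, "peripheral", cfg, dense)
    if (nRing > 0L) {
      s2 <- try(addFoci(s, nRing, rad, esAmp, "perinucleolar", cfg, dense),
                silent = TRUE)
      s <- if (inherits(s2, "try-error"))
        addFoci(s, nRing, rad, esAmp, "peripheral", cfg, dense) else s2
    }
    s
  }
  scene <- switch(phase,
    G = scene,
    ES = {
      n <- drawN(30L, 60L)
      addFoci(scene, n, esRad, esAmp, "interior", cfg, dense)
    },
    MS = {
      n <- drawN(25L, 45L)
      nPeri <- round(0.75 * n)
      periMix(scene, nPeri, n - nPeri, esRad)
    },
    LS = {
      n <- drawN(3L, 8L)
      addFoci(scene, n, 2 * esRad, esAmp, "uniform", cfg)
    },
    ES_MS = {
      n <- drawN(30L, 50L)
      nInt <- round(mixFraction * n)
      s <- addFoci(scene, nInt, esRad, esAmp, "interior", cfg, dense)
      addFoci(s, n - nInt, esRad, esAmp, "peripheral", cfg, dense)
    },
    MS_LS = {
      n <- drawN(3L, 8L)
      nPeri <- ceiling(0.7 * n)
      periMix(scene, nPeri, n - nPeri, sizeInflation * esRad)
    })
  scene@phaseTruth <- if (phase %in% c("G", "ES", "MS", "LS")) phase else
    NA_character_
  scene
}

#' Synthesize a per-colony DAPI intensity table
#'
#' Draws one integrated DAPI intensity per cell from phase-dependent DNA
#' content means (G1 = 1, G2 = 2, S stages interpolated so that
#' E-S < M-S < L-S), multiplies each colony by its own gain factor
#' (emulating illumination/staining variation across the coverslip), and
#' records the true phase of every cell.
#'
#' @param nColonies number of colonies.
#' @param cellsPerColony cells per colony (>= 2).
#' @param phaseMix named proportions over
#'   \code{c("G1", "ES", "MS", "LS", "G2")}; must sum to 1.
#' @param gainJitter lognormal sigma of the per-colony gain (0 = no
#'   jitter).
#' @param cellNoise per-cell multiplicative noise SD (default 0: DNA
#'   content alone).
#' @param seed integer seed.
#' @return a data.frame with columns \code{colony_id}, \code{cell_id},
#'   \code{integrated_dapi}, \code{phase_truth}.
#' @export
makeColonyTable <- function(nColonies = 10L, cellsPerColony = 12L,
                            phaseMix = c(G1 = 0.30, ES = 0.15, MS = 0.15,
                                         LS = 0.15, G2 = 0.25),
                            gainJitter = 0.1, cellNoise = 0,
                            seed = 1L) {
  stopifnot(cellsPerColony >= 2L, abs(sum(phaseMix) - 1) < 1e-9,
            all(names(phaseMix) %in% c("G1", "ES", "MS", "LS", "G2")))
  dnaMean <- c(G1 = 1, ES = 1.25, MS = 1.5, LS = 1.75, G2 = 2)
  .withSeed(seed, {
    rows <- lapply(seq_len(nColonies), function(ci) {
      gain <- exp(stats::rnorm(1, 0, gainJitter))
      ph <- sample(names(phaseMix), cellsPerColony, replace = TRUE,
                   prob = phaseMix)
      v <- dnaMean[ph] * gain
      if (cellNoise > 0)
        v <- v * exp(stats::rnorm(cellsPerColony, 0, cellNoise))
      data.frame(colony_id = ci, cell_id = seq_len(cellsPerColony),
                 integrated_dapi = unname(v), phase_truth = ph)
    })
    do.call(rbind, rows)
  })
}
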