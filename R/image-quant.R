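## Image metrics for nuclear protein distribution: coefficient of
## variation excluding nucleoli, foci segmentation at mean + 2 SD with an
## optical-resolution size filter, relative foci intensity, per-colony
## DAPI normalization, stack averaging, and a permutation utility for
## adjacent-phase comparisons.
##
## Conventions fixed here (documented rather than configurable where a
## single choice suffices): threshold statistics are computed over the
## same nucleus-minus-nucleoli region as the CV; population (not sample)
## SD throughout; 8-connected components; foci touching the nucleus
## border are retained.

.analysisRegion <- function(image, nucleusMask, nucleoliMask) {
  if (is.null(nucleoliMask))
    nucleoliMask <- matrix(FALSE, nrow(image), ncol(image))
  stopifnot(all(dim(image) == dim(nucleusMask)),
            all(dim(image) == dim(nucleoliMask)))
  region <- nucleusMask & !nucleoliMask
  if (!any(region))
    stop("degenerate input: empty analysis region")
  region
}

.popSD <- function(x) sqrt(mean((x - mean(x))^2))

#' Nuclear coefficient of variation
#'
#' Ratio of the standard deviation to the mean of the pixel intensities
#' over the nucleus, both computed excluding the nucleoli (population SD).
#' A homogeneously distributed protein gives CV near 0; recruitment into
#' foci raises it. Invariant under multiplication of the image by any
#' positive scalar.
#'
#' @param image numeric intensity matrix.
#' @param nucleusMask logical nucleus mask.
#' @param nucleoliMask logical nucleoli mask (NULL for none).
#' @return the CV (dimensionless scalar).
#' @export
computeCV <- function(image, nucleusMask, nucleoliMask = NULL) {
  region <- .analysisRegion(image, nucleusMask, nucleoliMask)
  px <- image[region]
  m <- mean(px)
  if (m <= 0) stop("degenerate input: nonpositive mean intensity")
  .popSD(px) / m
}

#' Detect nuclear foci by mean + 2 SD thresholding
#'
#' Binarizes the nucleus (excluding nucleoli) at an intensity threshold of
#' mean + 2 x SD computed over that same region, labels 8-connected
#' components, and retains those with area at least that of a circle with
#' diameter equal to the lateral optical resolution
#' (\eqn{\pi (resolution/2)^2} px^2). Reports the focus count, per-focus
#' area, mean intensity and centroid, and the relative foci intensity
#' \eqn{I_{r,foci}}: mean intensity over all retained foci pixels divided
#' by the mean intensity of the analysis region.
#'
#' @param image numeric intensity matrix.
#' @param nucleusMask,nucleoliMask logical masks.
#' @param resolutionPx lateral optical resolution in pixels (> 0), e.g.
#'   0.25 um at 0.1 um/px gives 2.5.
#' @return a [FociReport-class].
#' @export
detectFoci <- function(image, nucleusMask, nucleoliMask = NULL,
                       resolutionPx = 2.5) {
  stopifnot(is.numeric(resolutionPx), resolutionPx > 0)
  region <- .analysisRegion(image, nucleusMask, nucleoliMask)
  px <- image[region]
  m <- mean(px)
  if (m <= 0) stop("degenerate input: nonpositive mean intensity")
  s <- .popSD(px)
  thr <- m + 2 * s
  bin <- region & (image > thr)
  lab <- .label8Cpp(bin)
  minArea <- pi * (resolutionPx / 2)^2

  nlab <- max(lab)
  recs <- data.frame(label = integer(0), area = numeric(0),
                     meanIntensity = numeric(0), cx = numeric(0),
                     cy = numeric(0))
  if (nlab > 0L) {
    idx <- which(lab > 0L)
    li <- lab[idx]
    area <- tabulate(li, nlab)
    keep <- which(area >= minArea)
    if (length(keep)) {
      ii <- ((idx - 1L) %% nrow(image)) + 1L
      jj <- ((idx - 1L) %/% nrow(image)) + 1L
      sumI <- rowsum(image[idx], li)[, 1L]
      sumX <- rowsum(as.numeric(ii), li)[, 1L]
      sumY <- rowsum(as.numeric(jj), li)[, 1L]
      ulab <- sort(unique(li))
      ord <- match(keep, ulab)
      recs <- data.frame(label = seq_along(keep),
                         area = area[keep],
                         meanIntensity = (sumI[ord] / area[keep]),
                         cx = sumX[ord] / area[keep],
                         cy = sumY[ord] / area[keep])
      fociPix <- idx[li %in% keep]
      iR <- mean(image[fociPix]) / m
    }
  }
  nF <- nrow(recs)
  new("FociReport", cv = s / m, nFoci = as.integer(nF),
      iRFoci = if (nF > 0L) iR else NA_real_, foci = recs)
}

#' Normalize integrated DAPI intensities within colonies
#'
#' Divides each cell's integrated DAPI intensity by the mean of its
#' colony, correcting slow illumination/staining variation across the
#' sample. By construction the per-colony mean of the normalized values
#' is exactly 1, and the result is invariant to any positive per-colony
#' gain.
#'
#' @param colonyTable data.frame with columns \code{colony_id} and
#'   \code{integrated_dapi} (as from [makeColonyTable()]).
#' @return the table with an added column \code{i_dapi_normalized}.
#' @export
normalizeDapi <- function(colonyTable) {
  stopifnot(is.data.frame(colonyTable),
            all(c("colony_id", "integrated_dapi") %in% names(colonyTable)))
  v <- colonyTable$integrated_dapi
  if (any(!is.finite(v))) stop("integrated intensities must be finite")
  mu <- stats::ave(v, colonyTable$colony_id, FUN = mean)
  if (any(mu <= 0)) stop("nonpositive colony mean intensity")
  colonyTable$i_dapi_normalized <- v / mu
  colonyTable
}

#' Average an image stack
#'
#' Pixelwise arithmetic mean of K same-shape images, as acquired in
#' stacks of repeated frames to reduce shot noise before quantification.
#'
#' @param stack a list of numeric matrices with identical dimensions, or
#'   a 3D array with the third dimension indexing frames.
#' @return a numeric matrix.
#' @export
averageStack <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  stopifnot(is.list(stack), length(stack) >= 1L)
  d <- dim(stack[[1L]])
  if (!all(vapply(stack, function(m) identical(dim(m), d), TRUE)))
    stop("shape mismatch across stack frames")
  Reduce(`+`, stack) / length(stack)
}

#' Permutation comparison of a metric across adjacent phases
#'
#' Two-sided permutation test on the difference of group means for each
#' consecutive pair of phases (e.g. ES vs G, MS vs ES, LS vs MS), the
#' contrast structure used when each cell-cycle stage is compared with
#' its predecessor. This is a transparent resampling substitute for
#' model-based group testing and is labeled as such in the output.
#'
#' @param values numeric metric values.
#' @param labels group labels; order of contrasts follows factor levels
#'   (or the natural phase order G, ES, MS, LS when labels are character).
#' @param nPermutations permutations per contrast.
#' @param seed integer seed (the test is seed-deterministic).
#' @return data.frame with one row per adjacent contrast: \code{contrast},
#'   \code{diff} (later minus earlier phase), \code{p_value}, \code{n1},
#'   \code{n2}, and a \code{method} attribute
#'   \code{"two-sided permutation test on difference of means"}.
#' @export
compareGroups <- function(values, labels, nPermutations = 10000L,
                          seed = 1L) {
  stopifnot(length(values) == length(labels))
  if (!is.factor(labels)) {
    canonical <- c("G", "G1", "ES", "MS", "LS", "G2")
    lev <- unique(as.character(labels))
    lev <- c(intersect(canonical, lev), setdiff(lev, canonical))
    labels <- factor(labels, levels = lev)
  }
  lev <- levels(droplevels(labels))
  if (length(lev) < 2L) stop("need at least two groups")
  counts <- table(labels)[lev]
  if (any(counts < 3L)) stop("each group needs at least 3 values")

  res <- .withSeed(seed, {
    out <- NULL
    for (i in seq_len(length(lev) - 1L)) {
      a <- values[labels == lev[i]]
      b <- values[labels == lev[i + 1L]]
      obs <- mean(b) - mean(a)
      pool <- c(a, b)
      nb <- length(b)
      perm <- vapply(seq_len(nPermutations), function(q) {
        pick <- sample.int(length(pool), nb)
        mean(pool[pick]) - mean(pool[-pick])
      }, 0)
      p <- (1 + sum(abs(perm) >= abs(obs))) / (nPermutations + 1)
      out <- rbind(out, data.frame(
        contrast = paste(lev[i + 1L], "vs", lev[i]),
        diff = obs, p_value = p,
        n1 = length(a), n2 = nb))
    }
    out
  })
  attr(res, "method") <- "two-sided permutation test on difference of means"
  res
}
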