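# Shared fixtures for the suite. Everything is generated in code; no
# stored data.

# a random valid parameter set (fractions sum to 1, tauShort < tauLong)
randomParams <- function() {
  f <- 0.12 + stats::runif(3)   # keep every component identifiable
  f <- f / sum(f)
  # separated timescales: the two-exponential decomposition is only
  # well-conditioned when diffusion, short and long binding are distinct
  tauD <- 10^stats::runif(1, -4, -2)
  tauS <- tauD * 10^stats::runif(1, 0.8, 2)
  tauL <- tauS * 10^stats::runif(1, 0.8, 2)
  fcsParams(nMolecules = 10^stats::runif(1, -1, 1), fDiff = f[1],
            tauDiff = tauD, omega = stats::runif(1, 2, 8),
            fShort = f[2], tauShort = tauS,
            fLong = f[3], tauLong = tauL)
}

# the canonical simulated-study parameter set
studyParams <- function() {
  fcsParams(nMolecules = 2, fDiff = 0.5, tauDiff = 1e-3, omega = 5,
            fShort = 0.3, tauShort = 0.1, fLong = 0.2, tauLong = 2)
}

logLags <- function(n = 128L, lo = 1e-5, hi = 50) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

# model curve without noise
modelCurve <- function(params, n = 128L) {
  lg <- logLags(n)
  acfCurve(lg, evalACFModel(params, lg))
}

# small disc-shaped nucleus mask in a square frame, plus an image at a
# constant background; the cheap fixture for metric tests
discScene <- function(size = 64L, radius = 24, background = 100) {
  x <- matrix(seq_len(size), size, size)
  y <- matrix(seq_len(size), size, size, byrow = TRUE)
  mask <- (x - size / 2)^2 + (y - size / 2)^2 <= radius^2
  img <- matrix(0, size, size)
  img[mask] <- background
  list(image = img, nucleus = mask,
       nucleoli = matrix(FALSE, size, size))
}

# plant a Gaussian focus directly (bypassing placement logic)
plantFocus <- function(img, cx, cy, fwhm, peak) {
  size <- nrow(img)
  x <- matrix(seq_len(size), size, size)
  y <- matrix(seq_len(size), size, size, byrow = TRUE)
  sg <- fwhm / 2.355
  img + peak * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sg^2))
}

# synthetic PCNAFeatures for rule tests
makeFeatures <- function(nFoci, interior, boundary, meanArea = 10,
                         medianArea = meanArea) {
  new("PCNAFeatures", nFoci = as.integer(nFoci),
      medianFocusArea = medianArea, meanFocusArea = meanArea,
      fracPeripheral = if (nFoci) boundary / nFoci else 0,
      fracPerinucleolar = 0,
      fracInterior = if (nFoci) interior / nFoci else 0,
      interiorCount = as.integer(interior),
      boundaryCount = as.integer(boundary))
}
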