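## Brownian dynamics FCS simulator: point emitters diffusing through a
## periodic box, observed through a 3D Gaussian volume centred in the box,
## exchanging with two classes of immobile, non-depleting binding sites
## (pseudo-first-order kinetics, free <-> short and free <-> long only).
## Bound molecules stay fluorescent at their fixed site, which is what
## gives the ACF its two exponential binding terms.

#' Construct an FCS simulation configuration
#'
#' Defaults describe the test fixture used throughout the package: a
#' 50 kHz, 162 s (2.7 min) acquisition of a molecule with a 1 ms diffusion
#' time through a 0.25 x 1.25 um observation volume (omega = 5), with
#' residence times 0.1 s and 2 s at the short- and long-lived sites and
#' equilibrium occupancies 0.5/0.3/0.2 (free/short/long). The particle
#' number corresponds to about one molecule in the effective confocal
#' volume, so that the fitted amplitude fractions of the model coincide
#' with the state occupancies (see the vignette).
#'
#' @param nParticles particles in the box.
#' @param boxSize periodic cube edge, um.
#' @param dFree diffusion coefficient, um^2/s.
#' @param wXY,wZ radial and axial waists, um.
#' @param brightness counts/s per molecule at beam centre.
#' @param rateHz sampling rate (50000 by default; use 25000 for the
#'   longer, slower acquisition regime).
#' @param durationS trace duration, s.
#' @param konShort,koffShort,konLong,koffLong binding/unbinding rates, s^-1.
#' @param seed integer seed; fully determines the simulated trace.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nParticles = 70L, boxSize = 3.125, dFree = 15.625,
                      wXY = 0.25, wZ = 1.25, brightness = 1e5,
                      rateHz = 50000, durationS = 162,
                      konShort = 6, koffShort = 10,
                      konLong = 0.2, koffLong = 0.5, seed = 1L) {
  new("SimConfig", nParticles = as.integer(nParticles), boxSize = boxSize,
      dFree = dFree, wXY = wXY, wZ = wZ, brightness = brightness,
      rateHz = rateHz, durationS = durationS, konShort = konShort,
      koffShort = koffShort, konLong = konLong, koffLong = koffLong,
      seed = as.integer(seed))
}

#' Effective confocal volume of a configuration
#'
#' \eqn{V_{eff} = \pi^{3/2} w_{xy}^2 w_z}, the standard effective volume of
#' a 3D Gaussian observation profile.
#'
#' @param cfg a [SimConfig-class].
#' @return volume in um^3.
#' @export
effectiveVolume <- function(cfg) pi^(3 / 2) * cfg@wXY^2 * cfg@wZ

#' Equilibrium state probabilities of the free/short/long binding scheme
#'
#' @param cfg a [SimConfig-class].
#' @return named vector \code{c(free, short, long)} summing to 1.
#' @export
equilibriumOccupancy <- function(cfg) {
  if ((cfg@konShort > 0 && cfg@koffShort == 0) ||
      (cfg@konLong > 0 && cfg@koffLong == 0))
    stop("absorbing state: kon > 0 with koff = 0 has no equilibrium")
  wS <- if (cfg@koffShort > 0) cfg@konShort / cfg@koffShort else 0
  wL <- if (cfg@koffLong > 0) cfg@konLong / cfg@koffLong else 0
  z <- 1 + wS + wL
  c(free = 1 / z, short = wS / z, long = wL / z)
}

#' Model parameters implied by a simulator configuration
#'
#' Maps the generative configuration to the observables of the
#' autocorrelation model: \eqn{\tau_D = w_{xy}^2 / (4 D)}, residence times
#' as reciprocal unbinding rates, amplitude fractions as the equilibrium
#' state probabilities of the three-state chain, and
#' \eqn{N = n_{particles} \cdot V_{eff} / V_{box}}.
#'
#' When no binding occurs the residence-time slots are filled with the
#' canonical placeholder values (0.01 s / 1 s) at zero amplitude.
#'
#' @param cfg a [SimConfig-class].
#' @return an [FCSParams-class].
#' @export
expectedParamsFromConfig <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  occ <- equilibriumOccupancy(cfg)
  tauD <- cfg@wXY^2 / (4 * cfg@dFree)
  n <- cfg@nParticles * effectiveVolume(cfg) / cfg@boxSize^3
  tS <- if (cfg@koffShort > 0) 1 / cfg@koffShort else 0.01
  tL <- if (cfg@koffLong > 0) 1 / cfg@koffLong else 1
  fS <- occ[["short"]]; fL <- occ[["long"]]
  if (tS > tL) {  # honour the short < long labeling convention
    tmp <- tS; tS <- tL; tL <- tmp
    tmp <- fS; fS <- fL; fL <- tmp
  }
  if (tS == tL) tL <- tS * (1 + 1e-9)
  fcsParams(n, occ[["free"]], tauD, cfg@wZ / cfg@wXY, fS, tS, fL, tL)
}

#' Simulate a photon-count trace by Brownian dynamics
#'
#' Per sampling bin, each free particle takes an isotropic Gaussian step of
#' per-axis variance \eqn{2 D \Delta t} with periodic wrapping; binding
#' state transitions are drawn from the exponential waiting times of the
#' three-state scheme; bound particles do not move. The expected photon
#' count of a bin is \eqn{\Delta t \cdot B \sum_i \exp(-2 r_{xy,i}^2 /
#' w_{xy}^2 - 2 z_i^2 / w_z^2)} and the realized count is Poisson. If the
#' sampling interval does not resolve the kinetics (max rate x dt < 0.1)
#' or the diffusion step (step < wXY/4), the dynamics are internally
#' sub-stepped; configurations needing more than 64 sub-steps are refused.
#'
#' The configuration seed fully determines the output (an internal
#' counter-based generator is used; R's RNG state is untouched).
#'
#' @param cfg a [SimConfig-class].
#' @return a [SimOutput-class] holding the trace, the expected model
#'   parameters ([expectedParamsFromConfig()]) and the realized state
#'   occupancy fractions.
#' @export
simulateTrace <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  truth <- expectedParamsFromConfig(cfg)  # also rejects absorbing schemes
  dt <- 1 / cfg@rateHz
  maxRate <- max(cfg@konShort + cfg@konLong, cfg@koffShort, cfg@koffLong)
  nSub <- max(1,
              ceiling(maxRate * dt / 0.1),
              ceiling(2 * cfg@dFree * dt / (cfg@wXY / 4)^2))
  if (nSub > 64)
    stop("configuration error: kinetics/diffusion need > 64 sub-steps per bin")
  res <- .simulateFcsCpp(cfg@nParticles, cfg@boxSize, cfg@dFree, cfg@wXY,
                         cfg@wZ, cfg@brightness, cfg@rateHz, cfg@durationS,
                         cfg@konShort, cfg@koffShort, cfg@konLong,
                         cfg@koffLong, cfg@seed, as.integer(nSub))
  trace <- new("IntensityTrace", counts = res$counts, binWidth = dt)
  occupancy <- res$occupancy
  new("SimOutput", trace = trace, truth = truth,
      occupancy = occupancy / sum(occupancy))
}
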