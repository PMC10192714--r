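# Brownian dynamics simulator: configuration algebra, determinism,
# equilibrium occupancy, Poisson emission statistics.

test_that("expected parameters follow from the configuration algebra", {
  cfg <- simConfig(wXY = 0.25, dFree = 15.625, koffLong = 0.5)
  p <- expectedParamsFromConfig(cfg)
  expect_equal(p@tauDiff, 0.001)          # w^2 / (4 D)
  expect_equal(p@tauLong, 2)              # 1 / koff
  expect_equal(p@tauShort, 0.1)
  expect_equal(p@fDiff + p@fShort + p@fLong, 1, tolerance = 1e-12)
  # default kinetics give the 0.5/0.3/0.2 occupancy split
  expect_equal(unname(equilibriumOccupancy(cfg)), c(0.5, 0.3, 0.2),
               tolerance = 1e-12)
  # n_molecules = particles x effective volume / box volume
  expect_equal(p@nMolecules,
               cfg@nParticles * pi^1.5 * 0.25^2 * 1.25 / 3.125^3)
})

test_that("no binding means a purely diffusing population", {
  cfg <- simConfig(konShort = 0, koffShort = 0, konLong = 0, koffLong = 0)
  p <- expectedParamsFromConfig(cfg)
  expect_equal(p@fDiff, 1)
  expect_equal(p@fShort, 0)
  expect_equal(p@fLong, 0)
})

test_that("binding without unbinding is rejected as absorbing", {
  cfg <- simConfig(konShort = 1, koffShort = 0)
  expect_error(expectedParamsFromConfig(cfg), "absorbing")
  expect_error(simulateTrace(cfg), "absorbing")
})

test_that("identical configurations give bit-identical traces", {
  a <- simulateTrace(simConfig(durationS = 1, seed = 33L))
  b <- simulateTrace(simConfig(durationS = 1, seed = 33L))
  expect_identical(counts(a@trace), counts(b@trace))
  expect_identical(a@occupancy, b@occupancy)
  c <- simulateTrace(simConfig(durationS = 1, seed = 34L))
  expect_false(identical(counts(a@trace), counts(c@trace)))
})

test_that("occupancy log matches the Markov-chain equilibrium", {
  out <- simulateTrace(simConfig(durationS = 30, seed = 5L))
  expect_equal(sum(out@occupancy), 1, tolerance = 1e-9)
  expect_lt(max(abs(out@occupancy - c(free = 0.5, short = 0.3,
                                      long = 0.2))), 0.05)
})

test_that("photon emission is Poisson for an effectively static scene", {
  # near-zero diffusion, no binding: each bin draws Poisson counts around
  # a constant rate, so the variance-to-mean ratio is 1
  cfg <- simConfig(dFree = 1e-9, konShort = 0, koffShort = 0,
                   konLong = 0, koffLong = 0, durationS = 4, seed = 8L)
  cts <- counts(simulateTrace(cfg)@trace)
  expect_gt(mean(cts), 0.2)
  expect_equal(var(cts) / mean(cts), 1, tolerance = 0.05)
})

test_that("mean count rate is set by N and invariant to box size", {
  # at fixed concentration the rate is brightness * N / 2^{3/2}, up to
  # the small axial truncation of the periodic box; binding is switched
  # off so the record mean relaxes on the millisecond diffusion scale
  base <- simConfig(durationS = 8, seed = 21L, konShort = 0,
                    koffShort = 0, konLong = 0, koffLong = 0)
  dens <- base@nParticles / base@boxSize^3
  big <- simConfig(nParticles = round(dens * 4^3), boxSize = 4,
                   durationS = 8, seed = 22L, konShort = 0,
                   koffShort = 0, konLong = 0, koffLong = 0)
  rate1 <- mean(counts(simulateTrace(base)@trace)) * base@rateHz
  rate2 <- mean(counts(simulateTrace(big)@trace)) * big@rateHz
  expect_equal(rate1 / rate2, 1, tolerance = 0.1)
  nEff <- expectedParamsFromConfig(base)@nMolecules
  expect_equal(rate1, base@brightness * nEff / 2^1.5, tolerance = 0.1)
})

test_that("configurations needing excessive sub-stepping are refused", {
  cfg <- simConfig(dFree = 1e6, durationS = 0.1)
  expect_error(simulateTrace(cfg), "sub-steps")
})

test_that("simulated ACF matches the expected model shape", {
  # moderate-length pure-diffusion run: fitted tauD within 25 percent
  cfg <- simConfig(konShort = 0, koffShort = 0, konLong = 0,
                   koffLong = 0, durationS = 20, seed = 44L)
  out <- simulateTrace(cfg)
  crv <- segmentACF(out@trace, 6L, maxLagS = 0.5)
  fit <- fitACF(crv, init = fcsParams(0.35, 1, 2e-3, 5),
                fixed = c("omega", "fShort", "fLong"))
  expect_equal(fittedParams(fit)@tauDiff, 1e-3, tolerance = 0.25)
})
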