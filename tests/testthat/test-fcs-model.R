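# The autocorrelation model: closed forms, parameter conventions, fitting.

test_that("model evaluation matches hand-computed values", {
  # pure diffusion at zero lag collapses to the amplitude prefactor
  p <- fcsParams(1, fDiff = 1, tauDiff = 1e-3, omega = 5)
  expect_equal(evalACFModel(p, 0), 2^(-3 / 2), tolerance = 1e-14)

  # all terms decay to numerical zero far beyond the slowest timescale
  p2 <- studyParams()
  expect_lt(evalACFModel(p2, 1e9 * max(p2@tauDiff, p2@tauLong)), 1e-6)

  # term-by-term hand evaluation at tau = tauDiff
  expected <- 0.5 / (2^(3 / 2) * 2) * (1 / 2) * (1 + 1 / 25)^(-1 / 2) +
    0.3 * exp(-0.01) + 0.2 * exp(-0.0005)
  expect_equal(evalACFModel(p2, 1e-3), expected, tolerance = 1e-14)

  # elementwise over a vector of lags
  lg <- c(0, 1e-4, 1e-2, 1)
  expect_equal(evalACFModel(p2, lg),
               vapply(lg, function(t) evalACFModel(p2, t), 0))
})

test_that("invalid lags and invalid parameters are rejected", {
  p <- studyParams()
  expect_error(evalACFModel(p, -1), "nonnegative")
  expect_error(evalACFModel(p, NaN), "finite")
  expect_error(fcsParams(1, 0.5, 1e-3, fShort = 0.2, fLong = 0.2),
               "equal 1")
  expect_error(fcsParams(1, 0.4, 1e-3, omega = 5, fShort = 0.3,
                         tauShort = 2, fLong = 0.3, tauLong = 0.1),
               "tauShort")
  expect_error(fcsParams(-1, 1, 1e-3), "nMolecules")
  expect_error(fcsParams(1, 1, 1e-3, omega = 0.5), "omega")
})

test_that("dissociation rate is the reciprocal residence time", {
  expect_identical(koffFromResidence(0.5), 2)
  expect_identical(koffFromResidence(1), 1)
  expect_equal(koffFromResidence(c(0.1, 2)), c(10, 0.5))
  expect_error(koffFromResidence(0), "> 0")
  expect_error(koffFromResidence(-1), "> 0")
})

test_that("G is strictly decreasing and G(0) matches the closed form", {
  set.seed(421)
  lg <- logLags(200)
  for (i in 1:50) {
    p <- randomParams()
    g <- evalACFModel(p, lg)
    expect_true(all(diff(g) < 0))
    g0 <- p@fDiff / (2^(3 / 2) * p@nMolecules) + p@fShort + p@fLong
    expect_equal(evalACFModel(p, 0), g0, tolerance = 1e-12)
  }
})

test_that("noiseless fits recover generating parameters", {
  set.seed(7)
  for (i in 1:5) {
    truth <- randomParams()
    curve <- modelCurve(truth)
    # perturb the init by up to +/-30 percent
    pv <- nucleodyn:::.paramsToVec(truth)
    pv <- pv * stats::runif(length(pv), 0.7, 1.3)
    fS <- min(pv[["fShort"]], 0.45); fL <- min(pv[["fLong"]], 0.45)
    init <- fcsParams(pv[["nMolecules"]], 1 - fS - fL, pv[["tauDiff"]],
                      truth@omega, fS, min(pv[["tauShort"]],
                                           pv[["tauLong"]]) * 0.99,
                      fL, max(pv[["tauShort"]], pv[["tauLong"]]))
    fit <- fitACF(curve, init = init, fixed = "omega", minLag = 0)
    got <- paramsAsVector(fittedParams(fit))
    want <- paramsAsVector(truth)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-12)), 1e-4)
    expect_true(fit@converged)
  }
})

test_that("fitting is a projection: refitting a fitted curve is stable", {
  truth <- studyParams()
  fit1 <- fitACF(modelCurve(truth), init = "auto")
  curve2 <- modelCurve(fittedParams(fit1))
  fit2 <- fitACF(curve2, init = fittedParams(fit1), minLag = 0)
  v1 <- paramsAsVector(fittedParams(fit1))
  v2 <- paramsAsVector(fittedParams(fit2))
  expect_lt(max(abs(v2 - v1) / pmax(abs(v1), 1e-12)), 1e-6)
})

test_that("degenerate or malformed fit inputs raise errors", {
  lg <- logLags(64)
  expect_error(fitACF(acfCurve(lg, rep(0, 64))), "non-identifiable")
  expect_error(fitACF(acfCurve(lg[1:5], seq(0.5, 0.1, length.out = 5))),
               "at least 10 lags")
  expect_error(fitACF(acfCurve(seq(1, 2, length.out = 20),
                               seq(0.5, 0.1, length.out = 20))),
               "decades")
  expect_error(fitACF(modelCurve(studyParams()),
                      bounds = list(tauDiff = c(1, 0.1))),
               "infeasible")
  expect_error(fitACF(modelCurve(studyParams()),
                      bounds = list(banana = c(0, 1))),
               "unknown parameter")
})

test_that("koff slots equal exact reciprocals of fitted residence times", {
  fit <- fitACF(modelCurve(studyParams()), init = studyParams())
  expect_identical(fit@koffShort, 1 / fittedParams(fit)@tauShort)
  expect_identical(fit@koffLong, 1 / fittedParams(fit)@tauLong)
})

test_that("timescale ordering is restored by relabeling after the fit", {
  # initialize with the exponentials swapped relative to truth
  truth <- studyParams()
  init <- fcsParams(2, 0.5, 1e-3, 5, fShort = 0.2, tauShort = 0.05,
                    fLong = 0.3, tauLong = 1.5)
  fit <- fitACF(modelCurve(truth), init = init)
  p <- fittedParams(fit)
  expect_lt(p@tauShort, p@tauLong)
  expect_equal(p@tauShort, truth@tauShort, tolerance = 1e-3)
  expect_equal(p@tauLong, truth@tauLong, tolerance = 1e-3)
})

test_that("sem weighting is used when present", {
  truth <- studyParams()
  lg <- logLags(96)
  g <- evalACFModel(truth, lg)
  # corrupt a block of lags and give them huge errors: a weighted fit
  # must ignore them, an unweighted fit must not
  bad <- 41:48
  gBad <- g
  gBad[bad] <- g[bad] + 0.2
  sem <- rep(1e-4, length(lg)); sem[bad] <- 10
  fitW <- fitACF(acfCurve(lg, gBad, sem), init = truth, minLag = 0)
  fitU <- fitACF(acfCurve(lg, gBad), init = truth, minLag = 0)
  errW <- abs(paramsAsVector(fittedParams(fitW)) - paramsAsVector(truth))
  errU <- abs(paramsAsVector(fittedParams(fitU)) - paramsAsVector(truth))
  expect_lt(max(errW / pmax(paramsAsVector(truth), 1e-9)), 1e-3)
  expect_gt(max(errU / pmax(paramsAsVector(truth), 1e-9)), 1e-3)
})
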