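# Correlation estimators: exact small cases, white-noise bounds,
# multi-tau ladder structure and equivalence with the direct estimator.

test_that("a constant trace has zero correlation at every lag", {
  tr <- intensityTrace(rep(5L, 400), rateHz = 1000)
  expect_true(all(gValues(directACF(tr, 20)) == 0))
  expect_true(all(gValues(multitauACF(tr, 8)) == 0))
})

test_that("alternating trace gives G(1) = -1 and G(2) = +1", {
  tr <- intensityTrace(rep(c(1L, 0L), 500), rateHz = 1000)
  g <- gValues(directACF(tr, 2))
  expect_equal(g[1], -1, tolerance = 1e-12)
  expect_equal(g[2], 1, tolerance = 1e-12)
})

test_that("white Poisson noise decorrelates beyond lag zero", {
  set.seed(11)
  n <- 1e5
  tr <- intensityTrace(rpois(n, 10), rateHz = 50000)
  g <- gValues(directACF(tr, 30))
  expect_true(all(abs(g) < 5 / sqrt(n)))
})

test_that("the estimator is invariant to count scaling", {
  set.seed(12)
  cts <- rpois(5000, 7)
  a <- directACF(intensityTrace(cts, 1000), 25)
  b <- directACF(intensityTrace(cts * 3L, 1000), 25)
  expect_equal(gValues(a), gValues(b), tolerance = 1e-12)
})

test_that("multi-tau ladder is linear in the first octave, then doubles", {
  set.seed(13)
  tr <- intensityTrace(rpois(20000, 5), rateHz = 1000)
  crv <- multitauACF(tr, pointsPerOctave = 16)
  lg <- lags(crv)
  dt <- binWidth(tr)
  expect_equal(lg[1:16], (1:16) * dt)
  expect_equal(lg[17:24], seq(18, 32, by = 2) * dt)
  expect_equal(lg[25:32], seq(36, 64, by = 4) * dt)
})

test_that("multi-tau equals the direct estimator on first-octave lags", {
  set.seed(14)
  for (i in 1:5) {
    lam <- runif(1, 1, 20)
    tr <- intensityTrace(rpois(5e4, lam), rateHz = 50000)
    d <- gValues(directACF(tr, 16))
    m <- gValues(multitauACF(tr, 16))[1:16]
    expect_lt(max(abs(d - m)), 1e-12)
  }
})

test_that("degenerate traces are refused", {
  expect_error(directACF(intensityTrace(rep(0L, 100), 1000), 5),
               "degenerate")
  expect_error(directACF(intensityTrace(rpois(50, 3), 1000), 30),
               "longer than")
  expect_error(multitauACF(intensityTrace(rpois(100, 3), 1000), 15),
               "even")
})

test_that("segment errors vanish for periodic repeats and are positive for noise", {
  block <- rep(c(2L, 7L, 1L, 4L), 250)
  tr <- intensityTrace(rep(block, 6), rateHz = 1000)
  crv <- segmentACF(tr, nSegments = 6, maxLagS = 0.2,
                    value = "segment-mean")
  expect_true(all(semValues(crv) == 0))

  set.seed(15)
  trn <- intensityTrace(rpois(6000, 8), rateHz = 1000)
  crvn <- segmentACF(trn, nSegments = 6, maxLagS = 0.2)
  expect_true(all(semValues(crvn) > 0))
})

test_that("segment sem scales like one over sqrt of segment count", {
  # at fixed segment length, n vs 4n segments: sem of the mean halves
  set.seed(16)
  segLen <- 4000L
  mk <- function(nSeg) intensityTrace(rpois(segLen * nSeg, 8), 1000)
  reps <- vapply(1:8, function(r) {
    s4 <- mean(semValues(segmentACF(mk(4L), 4, maxLagS = 1)))
    s16 <- mean(semValues(segmentACF(mk(16L), 16, maxLagS = 1)))
    s16 / s4
  }, 0)
  expect_equal(mean(reps), 0.5, tolerance = 0.25)
})

test_that("full-record and segment-mean values agree at short lags", {
  set.seed(17)
  tr <- intensityTrace(rpois(40000, 8), rateHz = 1000)
  a <- segmentACF(tr, 4, maxLagS = 0.05)
  b <- segmentACF(tr, 4, maxLagS = 0.05, value = "segment-mean")
  expect_equal(lags(a), lags(b))
  expect_lt(max(abs(gValues(a) - gValues(b))), 0.02)
})

test_that("segments must be longer than the largest lag", {
  tr <- intensityTrace(rpois(2000, 5), rateHz = 1000)
  expect_error(segmentACF(tr, 10, maxLagS = 0.5), "longer than")
  expect_error(segmentACF(tr, 40), "too short")
  expect_error(segmentACF(tr, 1), "nSegments")
})
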