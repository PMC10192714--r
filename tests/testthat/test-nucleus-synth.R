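# Synthetic scenes: mask consistency, determinism, placement rules,
# phase renders, colony tables.

test_that("noise-free scenes are flat inside the analysis region", {
  sc <- makeNucleus(sceneConfig(noiseSNR = Inf), seed = 3L)
  region <- sc@nucleusMask & !sc@nucleoliMask
  expect_true(all(sc@image[region] == sc@background))
  expect_true(all(sc@image[!sc@nucleusMask] == 0))
  expect_true(all(sc@image[sc@nucleoliMask] < sc@background))
})

test_that("scene generation is seed-deterministic", {
  a <- makeNucleus(seed = 17L)
  b <- makeNucleus(seed = 17L)
  expect_identical(a@image, b@image)
  expect_identical(a@nucleusMask, b@nucleusMask)
  c <- makeNucleus(seed = 18L)
  expect_false(identical(a@nucleusMask, c@nucleusMask))
})

test_that("masks are consistent and nucleolar area stays in range", {
  fr <- vapply(1:20, function(i) {
    sc <- makeNucleus(seed = 100L + i)
    expect_true(all(!sc@nucleoliMask | sc@nucleusMask))
    sum(sc@nucleoliMask) / sum(sc@nucleusMask)
  }, 0)
  expect_true(all(fr > 0.005 & fr < 0.15))
})

test_that("adding zero foci is the identity", {
  sc <- makeNucleus(seed = 4L)
  expect_identical(addFoci(sc, 0), sc)
})

test_that("peripheral placement lands in the outer shell", {
  cfg <- sceneConfig()
  sc <- addFoci(makeNucleus(cfg, seed = 5L), 12, placement = "peripheral",
                cfg = cfg)
  rr <- nucleodyn:::.radialRank(sc@nucleusMask)
  pos <- rr[cbind(round(sc@fociTruth$x), round(sc@fociTruth$y))]
  expect_true(all(pos > cfg$shellThreshold))
})

test_that("interior placement stays below the shell threshold", {
  cfg <- sceneConfig()
  sc <- addFoci(makeNucleus(cfg, seed = 6L), 20, placement = "interior",
                cfg = cfg, minSepFactor = 0.6)
  rr <- nucleodyn:::.radialRank(sc@nucleusMask)
  pos <- rr[cbind(round(sc@fociTruth$x), round(sc@fociTruth$y))]
  expect_true(all(pos <= cfg$shellThreshold))
})

test_that("non-overlap enforcement respects the sum of radii", {
  sc <- addFoci(makeNucleus(seed = 7L), 10, radiusPx = c(4, 4))
  xy <- as.matrix(sc@fociTruth[, c("x", "y")])
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  expect_true(all(d >= 8))
})

test_that("an oversubscribed placement region is refused", {
  cfg <- sceneConfig()
  sc <- makeNucleus(cfg, seed = 8L)
  expect_error(addFoci(sc, 500, radiusPx = c(6, 8), cfg = cfg),
               "placement region too small")
})

test_that("a single bright focus is recovered by the detector", {
  sc <- addFoci(makeNucleus(seed = 9L), 1, radiusPx = c(5, 5),
                amplitude = c(10, 10))
  rep <- detectFoci(sc@image, sc@nucleusMask, sc@nucleoliMask, 2.5)
  expect_identical(rep@nFoci, 1L)
  expect_gt(rep@iRFoci, 1)
})

test_that("phase renders produce the documented pattern vocabulary", {
  g <- renderPCNA("G", seed = 31L)
  expect_identical(nrow(g@fociTruth), 0L)
  expect_identical(g@phaseTruth, "G")

  es <- renderPCNA("ES", seed = 32L)
  expect_true(nrow(es@fociTruth) >= 30 && nrow(es@fociTruth) <= 60)
  expect_true(all(es@fociTruth$radius <= 3.5))

  ls <- renderPCNA("LS", seed = 33L)
  expect_true(nrow(ls@fociTruth) >= 3 && nrow(ls@fociTruth) <= 8)
  # late-S foci at least twice the early-S size
  expect_true(min(ls@fociTruth$radius) >= 2 * min(es@fociTruth$radius))

  ms <- renderPCNA("MS", seed = 34L)
  rr <- nucleodyn:::.radialRank(ms@nucleusMask)
  pos <- rr[cbind(round(ms@fociTruth$x), round(ms@fociTruth$y))]
  ring <- nucleodyn:::.nucleoliRing(ms, 3L)
  inRing <- ring[cbind(round(ms@fociTruth$x), round(ms@fociTruth$y))]
  expect_true(all(pos > 0.75 | inRing))

  expect_error(renderPCNA("banana"), "unknown phase")
})

test_that("transition renders are mixtures and renders are deterministic", {
  tr <- renderPCNA("ES_MS", seed = 35L, mixFraction = 0.5)
  expect_true(is.na(tr@phaseTruth))
  rr <- nucleodyn:::.radialRank(tr@nucleusMask)
  pos <- rr[cbind(round(tr@fociTruth$x), round(tr@fociTruth$y))]
  expect_gt(sum(pos > 0.75), 0)
  expect_gt(sum(pos <= 0.75), 0)

  a <- renderPCNA("MS", seed = 36L)
  b <- renderPCNA("MS", seed = 36L)
  expect_identical(a@image, b@image)
  expect_identical(a@fociTruth, b@fociTruth)
})

test_that("colony tables reflect DNA content, gain and normalization", {
  # no jitter, single phase: all values equal
  t0 <- makeColonyTable(3, 5, c(G1 = 1, ES = 0, MS = 0, LS = 0, G2 = 0),
                        gainJitter = 0, seed = 2L)
  expect_true(all(t0$integrated_dapi == t0$integrated_dapi[1]))

  # normalization identity: per-colony mean exactly 1
  tab <- makeColonyTable(8, 10, gainJitter = 0.2, seed = 3L)
  nd <- normalizeDapi(tab)
  mu <- tapply(nd$i_dapi_normalized, nd$colony_id, mean)
  expect_equal(as.numeric(mu), rep(1, 8), tolerance = 1e-12)

  # DNA-content ordering of the S stages over many cells
  big <- makeColonyTable(100, 10, seed = 4L)
  nb <- normalizeDapi(big)
  m <- tapply(nb$i_dapi_normalized, nb$phase_truth, mean)
  expect_lt(m[["ES"]], m[["MS"]])
  expect_lt(m[["MS"]], m[["LS"]])

  expect_identical(makeColonyTable(seed = 5L), makeColonyTable(seed = 5L))
})
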