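# Image metrics: CV, foci detection and size filter, DAPI normalization,
# stack averaging, permutation comparisons.

test_that("CV is zero for uniform images and matches hand arithmetic", {
  d <- discScene()
  expect_identical(computeCV(d$image, d$nucleus, d$nucleoli), 0)

  # 4-pixel region with values 1,1,3,3: mean 2, population SD 1, CV 0.5
  img <- matrix(c(1, 1, 3, 3), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  expect_equal(computeCV(img, mask), 0.5, tolerance = 1e-15)
})

test_that("nucleoli are excluded from the CV region", {
  d <- discScene()
  nucleoli <- matrix(FALSE, nrow(d$image), ncol(d$image))
  nucleoli[30:34, 30:34] <- d$nucleus[30:34, 30:34]
  img <- d$image
  img[nucleoli] <- 10 * d$image[nucleoli]  # bright nucleolus
  expect_identical(computeCV(img, d$nucleus, nucleoli), 0)
})

test_that("CV is invariant under positive scaling", {
  set.seed(31)
  d <- discScene()
  img <- d$image + matrix(rpois(length(d$image), 20), nrow(d$image))
  cv1 <- computeCV(img, d$nucleus, d$nucleoli)
  cv2 <- computeCV(img * 137.5, d$nucleus, d$nucleoli)
  expect_equal(cv1, cv2, tolerance = 1e-12)
})

test_that("degenerate CV inputs raise errors", {
  d <- discScene()
  expect_error(computeCV(d$image, matrix(FALSE, 64, 64)), "empty")
  expect_error(computeCV(matrix(0, 64, 64), d$nucleus), "mean")
})

test_that("uniform images contain no foci", {
  d <- discScene()
  rep <- detectFoci(d$image, d$nucleus, d$nucleoli, 2.5)
  expect_identical(rep@nFoci, 0L)
  expect_true(is.na(rep@iRFoci))
})

test_that("a bright focus above the resolution limit is detected", {
  d <- discScene()
  img <- plantFocus(d$image, 32, 32, fwhm = 5, peak = 10 * 100)
  rep <- detectFoci(img, d$nucleus, d$nucleoli, 2.5)
  expect_identical(rep@nFoci, 1L)
  expect_gt(rep@iRFoci, 1)
  expect_true(all(rep@foci$area >= pi * (2.5 / 2)^2))
  expect_equal(rep@foci$cx, 32, tolerance = 0.5)
})

test_that("sub-resolution foci are removed by the size filter", {
  d <- discScene()
  img <- plantFocus(d$image, 32, 32, fwhm = 0.3 * 2.5, peak = 10 * 100)
  rep <- detectFoci(img, d$nucleus, d$nucleoli, 2.5)
  expect_identical(rep@nFoci, 0L)
})

test_that("focus count is monotone non-increasing in the resolution", {
  set.seed(32)
  d <- discScene()
  img <- d$image
  for (k in 1:4)
    img <- plantFocus(img, 15 + 10 * k, 20 + 7 * k, fwhm = 1 + k,
                      peak = 900)
  counts <- vapply(c(0.5, 1, 2, 3, 4, 6),
                   function(r) detectFoci(img, d$nucleus, d$nucleoli,
                                          r)@nFoci, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("DAPI normalization matches hand arithmetic and invariances", {
  tab <- data.frame(colony_id = c(1, 1, 1, 2),
                    cell_id = 1:4,
                    integrated_dapi = c(100, 200, 300, 77))
  nd <- normalizeDapi(tab)
  expect_equal(nd$i_dapi_normalized, c(0.5, 1, 1.5, 1))

  # per-colony gain invariance
  tab2 <- tab
  tab2$integrated_dapi[tab2$colony_id == 1] <-
    tab$integrated_dapi[tab$colony_id == 1] * 13
  nd2 <- normalizeDapi(tab2)
  expect_equal(nd2$i_dapi_normalized, nd$i_dapi_normalized,
               tolerance = 1e-12)

  expect_error(normalizeDapi(data.frame(colony_id = 1, cell_id = 1,
                                        integrated_dapi = 0)),
               "nonpositive")
})

test_that("stack averaging is exact and reduces noise as 1/sqrt(K)", {
  a <- matrix(0, 8, 8); b <- matrix(2, 8, 8)
  expect_identical(averageStack(list(a, b)), matrix(1, 8, 8))
  expect_identical(averageStack(list(b, b, b)), b)
  expect_error(averageStack(list(a, matrix(0, 4, 4))), "shape")

  set.seed(33)
  k <- 5L
  sds <- replicate(40, {
    frames <- lapply(seq_len(k), function(i)
      matrix(rpois(400, 50), 20, 20))
    c(sd(frames[[1]]), sd(averageStack(frames)))
  })
  expect_equal(mean(sds[2, ]) / mean(sds[1, ]), 1 / sqrt(k),
               tolerance = 0.1)
})

test_that("permutation comparisons behave under null and strong shifts", {
  set.seed(34)
  vals <- c(rnorm(15), rnorm(15))
  labs <- rep(c("G", "ES"), each = 15)
  # identical populations: p far from significance
  res0 <- compareGroups(c(vals[1:15], vals[1:15]), labs,
                        nPermutations = 2000, seed = 9)
  expect_gte(res0$p_value[1], 0.9)

  # 10 SD shift: maximally significant at this permutation count
  shifted <- c(rnorm(20), rnorm(20) + 10)
  res1 <- compareGroups(shifted, rep(c("ES", "MS"), each = 20),
                        nPermutations = 10000, seed = 9)
  expect_lte(res1$p_value[1], 0.001)
  expect_gt(res1$diff[1], 0)

  # contrast structure follows the canonical phase order
  set.seed(35)
  v4 <- rnorm(40)
  l4 <- rep(c("G", "ES", "MS", "LS"), each = 10)
  res2 <- compareGroups(v4, l4, nPermutations = 500, seed = 9)
  expect_identical(res2$contrast,
                   c("ES vs G", "MS vs ES", "LS vs MS"))
  expect_identical(res2, compareGroups(v4, l4, nPermutations = 500,
                                       seed = 9))
  expect_error(compareGroups(1:5, c("a", "a", "a", "b", "b")),
               "at least 3")
})

test_that("null calibration: permutation p-values are roughly uniform", {
  set.seed(36)
  ps <- replicate(200, {
    v <- rnorm(24)
    compareGroups(v, rep(c("G", "ES"), each = 12),
                  nPermutations = 200, seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(ps < 0.25), 0.15)
  expect_lt(mean(ps < 0.25), 0.35)
  expect_gt(mean(ps > 0.5), 0.38)
  expect_lt(mean(ps > 0.5), 0.62)
})
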