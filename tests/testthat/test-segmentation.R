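test_that("disabled filters are the identity and top-hat kills constants", {
  m <- matrix(runif(400, 0, 500), 20, 20)
  off <- PreprocessParams(medianEnabled = FALSE, tophatEnabled = FALSE)
  expect_identical(preprocessChannel(m, off), m)

  const <- matrix(42, 40, 40)
  th <- PreprocessParams(medianEnabled = FALSE, tophatRadius = 5)
  expect_true(all(preprocessChannel(const, th) == 0))

  expect_error(preprocessChannel(matrix(1, 10, 10),
                                 PreprocessParams(tophatRadius = 50)),
               "configuration error")
  expect_error(preprocessChannel(matrix(-1, 5, 5), off), "non-negative")
})

test_that("top-hat keeps a small blob and suppresses a background ramp", {
  H <- 48; W <- 48
  ramp <- matrix(seq_len(W), H, W, byrow = TRUE) * 2   # slope 2 per px
  img <- ramp
  img[23:25, 23:25] <- img[23:25, 23:25] + 150         # bright 3x3 blob
  radius <- 10
  out <- preprocessChannel(img, PreprocessParams(medianEnabled = FALSE,
                                                 tophatRadius = radius))
  blob <- out[23:25, 23:25]
  offBlob <- out
  offBlob[23:25, 23:25] <- NA
  expect_gt(min(blob), max(offBlob, na.rm = TRUE))

  # agrees with a brute-force erosion/dilation oracle away from the border
  oracle <- brute_tophat_interior(img,
                                  EBImage::makeBrush(2L * radius + 1L, "disc"))
  ok <- !is.na(oracle)
  expect_equal(out[ok], oracle[ok], tolerance = 1e-12)
})

test_that("top-hat output is invariant to a constant intensity offset", {
  withr::local_seed(31)
  m <- matrix(runif(900, 0, 100), 30, 30)
  p <- PreprocessParams(medianEnabled = FALSE, tophatRadius = 4)
  expect_equal(preprocessChannel(m, p), preprocessChannel(m + 57, p),
               tolerance = 1e-9)
})

test_that("median filtering smooths isolated hot pixels", {
  m <- matrix(10, 21, 21)
  m[11, 11] <- 5000
  out <- preprocessChannel(m, PreprocessParams(tophatEnabled = FALSE,
                                               medianRadius = 1))
  expect_lt(out[11, 11], 11)
})

test_that("Otsu matches a brute-force between-class-variance search", {
  two <- cbind(matrix(10, 16, 8), matrix(200, 16, 8))
  mask <- thresholdChannel(two, ThresholdSpec("otsu"))
  expect_identical(maskPixels(mask), brute_otsu_mask(two))
  expect_identical(unname(maskPixels(mask)[, 9:16]), matrix(1, 16, 8))
  expect_identical(unname(maskPixels(mask)[, 1:8]), matrix(0, 16, 8))

  withr::local_seed(77)
  noisy <- matrix(c(rnorm(300, 30, 5), rnorm(100, 180, 10)), 20, 20)
  noisy <- pmax(noisy, 0)
  m2 <- thresholdChannel(noisy, ThresholdSpec("otsu"))
  # discretised search (256 levels) against the exhaustive oracle
  expect_gt(jaccard(maskPixels(m2), brute_otsu_mask(noisy)), 0.98)
})

test_that("fixed and quantile thresholds behave as specified", {
  m <- matrix(runif(256, 1, 10), 16, 16)
  expect_true(all(maskPixels(thresholdChannel(m, ThresholdSpec("fixed", 0))) == 1))
  lvl <- 5
  expect_identical(maskPixels(thresholdChannel(m, ThresholdSpec("fixed", lvl))),
                   (m > lvl) * 1)
  q <- thresholdChannel(m, ThresholdSpec("quantile", 0.25))
  expect_equal(mean(maskPixels(q)), 0.25, tolerance = 0.01)
  expect_error(ThresholdSpec("quantile", 1.5), "in \\(0, 1\\)")
  expect_error(ThresholdSpec("bananas"), "method")
})

test_that("constant channels under Otsu give an empty mask with a warning", {
  expect_warning(mask <- thresholdChannel(matrix(7, 12, 12)),
                 "constant channel")
  expect_true(all(maskPixels(mask) == 0))
  expect_true(is.na(realizedThreshold(mask)))
})

test_that("raising a fixed threshold never adds foreground pixels", {
  withr::local_seed(42)
  m <- matrix(runif(1024, 0, 100), 32, 32)
  levels <- sort(runif(8, 0, 100))
  prev <- maskPixels(thresholdChannel(m, ThresholdSpec("fixed", levels[1])))
  for (lvl in levels[-1]) {
    cur <- maskPixels(thresholdChannel(m, ThresholdSpec("fixed", lvl)))
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("segmentPair recovers truth masks on noiseless scenes", {
  sc <- generateScene(SceneConfig(seed = 19, noiseScale = 0,
                                  proteinMode = "mito_ring"))
  pair <- segmentPair(sceneImage(sc), "mito", "protein")
  expect_named(pair, c("mito", "protein"))
  expect_gt(jaccard(maskPixels(pair$mito), maskPixels(truthMitoMask(sc))), 0.7)
  expect_gt(jaccard(maskPixels(pair$protein),
                    maskPixels(truthProteinMask(sc))), 0.7)
  expect_false(is.na(realizedThreshold(pair$mito)))
})

test_that("the same channel in both slots yields identical masks", {
  sc <- generateScene(SceneConfig(seed = 23))
  pair <- segmentPair(sceneImage(sc), "mito", "mito")
  expect_identical(maskPixels(pair[[1L]]), maskPixels(pair[[2L]]))
})

test_that("an ROI over an empty corner blanks both masks", {
  sc <- generateScene(SceneConfig(seed = 4, noiseScale = 0,
                                  backgroundGradientAmplitude = 0))
  roiPx <- matrix(FALSE, 256, 256)
  roiPx[1:8, 1:8] <- TRUE   # outside the elliptical cell
  suppressWarnings(
    pair <- segmentPair(sceneImage(sc), "mito", "protein",
                        roi = RoiMask(roiPx)))
  expect_true(all(maskPixels(pair$mito) == 0))
  expect_true(all(maskPixels(pair$protein) == 0))
})
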