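test_that("percent overlap counts AND and OR pixels exactly", {
  a <- matrix(0, 8, 8); a[2, 2:5] <- 1           # 4 px
  b <- matrix(0, 8, 8); b[2, 4:7] <- 1           # 4 px, 2 shared
  ov <- percentOverlap(a, b)
  expect_equal(commonCount(ov), 2)
  expect_equal(unionCount(ov), 6)
  expect_equal(overlapFraction(ov), 2 / 6)
  expect_equal(overlapPercent(ov), 100 * 2 / 6)

  withr::local_seed(12)
  for (rep in 1:25) {
    A <- random_mask(16, 16, runif(1, 0.05, 0.6))
    B <- random_mask(16, 16, runif(1, 0.05, 0.6))
    ref <- brute_overlap(A, B)
    got <- percentOverlap(A, B)
    expect_identical(commonCount(got), as.numeric(ref$common))
    expect_identical(unionCount(got), as.numeric(ref$union))
    expect_equal(overlapFraction(got), ref$overlap)
    # symmetry
    expect_equal(overlapFraction(percentOverlap(B, A)), ref$overlap)
  }
})

test_that("percent overlap handles subsets, empties and shape errors", {
  A <- matrix(0, 10, 10); A[3:7, 3:7] <- 1
  B <- matrix(0, 10, 10); B[4:6, 4:6] <- 1       # B strictly inside A
  expect_equal(overlapFraction(percentOverlap(A, B)), sum(B) / sum(A))
  expect_warning(ov <- percentOverlap(matrix(0, 4, 4), matrix(0, 4, 4)),
                 "both masks are empty")
  expect_equal(overlapFraction(ov), 0)
  expect_error(percentOverlap(matrix(0, 4, 4), matrix(0, 5, 5)),
               "input error")
  expect_error(percentOverlap(matrix(2, 4, 4), matrix(0, 4, 4)),
               "binary")
})

test_that("averaging masks gives 1 / 0.5 / 0 per pixel", {
  ones <- matrix(1, 5, 5); zeros <- matrix(0, 5, 5)
  expect_true(all(averageMasks(ones, ones) == 1))
  expect_true(all(averageMasks(ones, zeros) == 0.5))
  withr::local_seed(3)
  A <- random_mask(12, 12); B <- random_mask(12, 12)
  expect_identical(averageMasks(A, B), (A + B) / 2)
})

test_that("the ratio factor is the minimum count ratio, zero on absence", {
  expect_equal(windowRatioFactor(4, 2), 0.5)
  expect_equal(windowRatioFactor(2, 4), 0.5)
  expect_equal(windowRatioFactor(7, 7), 1)
  expect_equal(windowRatioFactor(5, 0), 0)
  expect_equal(windowRatioFactor(0, 0), 0)
  expect_equal(windowRatioFactor(c(4, 5, 3), c(2, 0, 3)), c(0.5, 0, 1))
  expect_error(windowRatioFactor(-1, 2), "non-negative")
})

test_that("a single window reproduces the hand-executed stepwise definition", {
  # 4x4 window: 2 px where both channels exist (avg 1), 2 px where one
  # does (avg 0.5); counts 4 vs 2 give ratio 1/2; weighted non-zero
  # pixels are 0.5, 0.5, 0.25, 0.25 and their mean is 0.375
  w <- matrix(0, 4, 4)
  w[1, 1:2] <- 1
  w[2, 1:2] <- 0.5
  expect_equal(windowProximity(w, 0.5), 0.375)
  expect_equal(windowProximity(matrix(1, 4, 4), 1), 1)
  expect_equal(windowProximity(matrix(0, 4, 4), 0.7), 0)

  # the same window embedded in an otherwise empty 64x64 image drives the
  # whole-image index: one non-zero window out of 256
  A <- matrix(0, 64, 64); B <- matrix(0, 64, 64)
  A[9, 9:12] <- 1                      # 4 px in the window at (9,9)
  B[9, 9:10] <- 1                      # 2 px, both shared
  res <- proximityIndex(A, B, ProximityConfig(k = 2))
  expect_equal(overallIndex(res), 0.375)
  expect_equal(nNonzeroWindows(res), 1L)
  expect_equal(sum(perWindowIndex(res) > 0), 1)
  expect_equal(naive_proximity(A, B, 2), 0.375)
})

test_that("proximity index hits its analytic limits", {
  withr::local_seed(8)
  A <- random_mask(128, 128, 0.2)
  for (k in c(2L, 4L, 6L, 7L)) {
    expect_equal(overallIndex(proximityIndex(A, A, ProximityConfig(k = k))), 1)
  }
  zero <- matrix(0, 128, 128)
  expect_equal(overallIndex(proximityIndex(A, zero)), 0)
  expect_equal(overallIndex(proximityIndex(zero, zero)), 0)
  expect_error(proximityIndex(A[1:32, 1:32], A[1:32, 1:32],
                              ProximityConfig(k = 6)),
               "configuration error")
})

test_that("the tiling engine matches the naive reference on random masks", {
  withr::local_seed(99)
  for (rep in 1:40) {
    H <- sample(40:90, 1)
    W <- sample(40:90, 1)
    A <- random_mask(H, W, runif(1, 0.02, 0.5))
    B <- random_mask(H, W, runif(1, 0.02, 0.5))
    k <- sample(2:5, 1)
    got <- overallIndex(proximityIndex(A, B, ProximityConfig(k = k)))
    expect_equal(got, naive_proximity(A, B, k), tolerance = 1e-12)
    # symmetry
    expect_equal(got,
                 overallIndex(proximityIndex(B, A, ProximityConfig(k = k))),
                 tolerance = 1e-14)
    expect_true(got >= 0 && got <= 1)
  }
})

test_that("edge policies and strides are honoured", {
  withr::local_seed(7)
  A <- random_mask(70, 50, 0.3)   # not a multiple of 16
  B <- random_mask(70, 50, 0.3)
  part <- proximityIndex(A, B, ProximityConfig(k = 4, edgePolicy = "partial"))
  pad <- proximityIndex(A, B, ProximityConfig(k = 4, edgePolicy = "pad"))
  drp <- proximityIndex(A, B, ProximityConfig(k = 4, edgePolicy = "drop"))
  # zero padding adds nothing to counts, so pad and partial agree
  expect_equal(overallIndex(pad), overallIndex(part), tolerance = 1e-14)
  expect_identical(dim(perWindowIndex(part)), c(5L, 4L))
  expect_identical(dim(perWindowIndex(drp)), c(4L, 3L))
  expect_equal(overallIndex(drp), naive_proximity(A, B, 4, edge = "drop"),
               tolerance = 1e-12)

  # overlapping stride: more windows, still matches the naive sweep
  s8 <- proximityIndex(A, B, ProximityConfig(k = 4, stride = 8L))
  expect_equal(overallIndex(s8), naive_proximity(A, B, 4, stride = 8),
               tolerance = 1e-12)
})

test_that("the window sweep separates limit groups and validates input", {
  withr::local_seed(5)
  idPairs <- lapply(1:3, function(i) {
    m <- random_mask(128, 128, 0.25)
    list(m, m)
  })
  absentPairs <- lapply(1:3, function(i) {
    list(random_mask(128, 128, 0.25), matrix(0, 128, 128))
  })
  sw <- windowSizeSweep(list(same = idPairs, absent = absentPairs),
                        kRange = 2:7)
  expect_true(all(separation(sw) == 1))
  expect_identical(selectedK(sw), 2L)   # ties break toward the smaller k
  means <- perKGroupMeans(sw)
  expect_equal(means$mean_proximity[means$group == "same"], rep(1, 6))
  expect_equal(means$mean_proximity[means$group == "absent"], rep(0, 6))

  expect_error(windowSizeSweep(list(only = idPairs)), "at least two")
  expect_error(windowSizeSweep(list(a = idPairs, b = list())),
               "at least one mask pair")
})
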