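test_that("a fixed seed yields bit-identical scenes and leaves the caller RNG alone", {
  cfg <- SceneConfig(seed = 21)
  set.seed(555)
  before <- .Random.seed
  s1 <- generateScene(cfg)
  expect_identical(.Random.seed, before)
  s2 <- generateScene(cfg)
  expect_identical(s1@image@pixels, s2@image@pixels)
  expect_identical(maskPixels(truthMitoMask(s1)), maskPixels(truthMitoMask(s2)))
  s3 <- generateScene(SceneConfig(seed = 22))
  expect_false(identical(s1@image@pixels, s3@image@pixels))
})

test_that("fully colocalized protein with no shift is contained in the mito mask", {
  for (seed in c(2, 13, 40)) {
    sc <- generateScene(SceneConfig(seed = seed, noiseScale = 0,
                                    proteinMode = "mito_colocalized",
                                    colocFraction = 1, displacement = 0))
    m <- maskPixels(truthMitoMask(sc))
    p <- maskPixels(truthProteinMask(sc))
    expect_gt(sum(p), 0)
    expect_true(all(p <= m))
  }
})

test_that("protein modes produce their intended geometry", {
  base <- SceneConfig(seed = 5, noiseScale = 0)
  mito <- maskPixels(truthMitoMask(generateScene(base)))

  ring <- generateScene(SceneConfig(seed = 5, noiseScale = 0,
                                    proteinMode = "mito_ring"))
  rp <- maskPixels(truthProteinMask(ring))
  expect_gt(sum(rp), 0)
  expect_equal(sum(rp * mito), 0)   # ring hugs but never covers mitochondria

  adj <- generateScene(SceneConfig(seed = 5, noiseScale = 0,
                                   proteinMode = "mito_adjacent_puncta"))
  expect_equal(sum(maskPixels(truthProteinMask(adj)) * mito), 0)

  memb <- generateScene(SceneConfig(seed = 5, noiseScale = 0,
                                    proteinMode = "membrane"))
  expect_gt(sum(maskPixels(truthProteinMask(memb))), 0)

  expect_error(SceneConfig(proteinMode = "golgi"), "unknown proteinMode")
  expect_error(SceneConfig(phenotype = "swollen"), "unknown phenotype")
  expect_error(SceneConfig(height = 32), ">= 64")
})

test_that("membrane and colocalized modes separate in downstream percent overlap", {
  sc1 <- generateScene(SceneConfig(seed = 8, noiseScale = 0,
                                   proteinMode = "mito_colocalized",
                                   colocFraction = 1))
  sc2 <- generateScene(SceneConfig(seed = 8, noiseScale = 0,
                                   proteinMode = "membrane"))
  ov1 <- brute_overlap(maskPixels(truthMitoMask(sc1)),
                       maskPixels(truthProteinMask(sc1)))
  ov2 <- brute_overlap(maskPixels(truthMitoMask(sc2)),
                       maskPixels(truthProteinMask(sc2)))
  expect_gt(ov1$overlap, ov2$overlap)
})

test_that("noiseless rendering is brighter on truth pixels than the mean background", {
  sc <- generateScene(SceneConfig(seed = 17, noiseScale = 0))
  for (ch in c("mito", "protein")) {
    truth <- if (ch == "mito") truthMitoMask(sc) else truthProteinMask(sc)
    px <- getChannel(sceneImage(sc), ch)
    onTruth <- px[maskPixels(truth) == 1]
    bgMean <- mean(px[maskPixels(truth) == 0])
    expect_true(all(onTruth > bgMean))
  }
})

test_that("toroidal displacement conserves the protein mask area", {
  areas <- vapply(c(0, 8, 32, 60), function(d) {
    sc <- generateScene(SceneConfig(seed = 3, noiseScale = 0,
                                    displacement = d))
    sum(maskPixels(truthProteinMask(sc)))
  }, numeric(1))
  expect_true(all(areas == areas[1L]))
})

test_that("scene batches are reproducible and validate their inputs", {
  cfgs <- replicate(4, SceneConfig(noiseScale = 2), simplify = FALSE)
  labels <- rep(c("treated", "control"), each = 2)
  b1 <- sceneBatch(cfgs, labels, baseSeed = 7)
  expect_length(b1, 4L)
  expect_identical(names(b1), c("treated_1", "treated_2",
                                "control_1", "control_2"))
  expect_identical(vapply(b1, attr, character(1), "group"),
                   stats::setNames(labels, names(b1)))
  b2 <- sceneBatch(cfgs, labels, baseSeed = 7)
  expect_identical(scene_pixel_hash(b1), scene_pixel_hash(b2))
  b3 <- sceneBatch(cfgs, labels, baseSeed = 8)
  expect_false(identical(scene_pixel_hash(b1), scene_pixel_hash(b3)))

  expect_error(sceneBatch(list(), character(0)), "empty scene list")
  expect_error(sceneBatch(cfgs, labels, ids = rep("x", 4)), "duplicate")
  expect_error(sceneBatch(cfgs, labels[1:2]), "one group label per config")
})
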