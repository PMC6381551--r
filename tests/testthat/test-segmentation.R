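test_that("growing over a constant volume fills it and flags the border", {
  v <- ctVolume(array(0, c(8, 8, 8)), c(1, 1, 1))
  crit <- growCriterion("fixed_interval", -10, 10)
  expect_warning(m <- regionGrow(v, c(4, 4, 4), crit), "border")
  expect_equal(voxelCount(m), 512)
  expect_true("boundary_leak" %in% maskFlags(m))
})

test_that("a seed that fails the criterion raises an empty-region error", {
  v <- ctVolume(array(-850, c(8, 8, 8)), c(1, 1, 1))
  crit <- growCriterion("fixed_interval", -200, 400)
  expect_error(regionGrow(v, c(4, 4, 4), crit), "empty region")
})

test_that("noise-free nodules are segmented with high Dice and volume accuracy", {
  # sharp (lung) kernel: the realistic choice for nodule work
  sc <- defaultScene()
  p <- scanProtocol(1.25, 120, "lung")
  r <- renderPhantom(sc, p, seed = 3, noiseScale = 0)
  for (ni in seq_along(sceneNodules(sc))) {
    nd <- sceneNodules(sc)[[ni]]
    sv <- autoSeed(r$volume, nd@centerMm)
    m <- regionGrow(r$volume, sv, defaultCriterion(nd@targetHu))
    expect_gte(diceOverlap(m, r$masks[[ni]]), 0.95)
    vol <- voxelCount(m) * prod(voxelSpacing(r$volume))
    vtrue <- 4 / 3 * pi * (nd@diameterMm / 2)^3
    expect_lt(abs(vol - vtrue) / vtrue, 0.15)
  }
})

test_that("growth is idempotent from any interior voxel and monotone in the interval", {
  r <- renderPhantom(smallScene(100, 12), scanProtocol(2.5, 120, "standard"),
                     seed = 8, noiseScale = 0)
  crit <- growCriterion("fixed_interval", -200, 400)
  sv <- autoSeed(r$volume, c(12.6, 12.6, 10))
  m1 <- regionGrow(r$volume, sv, crit)
  w <- which(maskArray(m1), arr.ind = TRUE)
  alt <- w[nrow(w) %/% 2, ]
  m2 <- regionGrow(r$volume, alt, crit)
  expect_identical(maskArray(m1), maskArray(m2))

  wide <- growCriterion("fixed_interval", -400, 600)
  m3 <- regionGrow(r$volume, sv, wide)
  expect_true(all(maskArray(m3)[maskArray(m1)]))
})

test_that("the seed-adaptive criterion freezes its interval from the seed neighbourhood", {
  r <- renderPhantom(smallScene(100, 12), scanProtocol(1.25, 120, "standard"),
                     seed = 8, noiseScale = 0, heterogeneitySdHu = 0)
  sv <- autoSeed(r$volume, c(12.6, 12.6, 10))
  m <- regionGrow(r$volume, sv, growCriterion("seed_adaptive", adaptK = 3))
  # grows a compact region around the uniform core, not the whole volume
  expect_gt(voxelCount(m), 100)
  expect_lt(voxelCount(m), 3000)
})

test_that("autoSeed finds the bright core, breaks ties lexicographically, checks bounds", {
  r <- renderPhantom(smallScene(100, 12), scanProtocol(1.25, 120, "standard"),
                     seed = 8, noiseScale = 0)
  sv <- autoSeed(r$volume, c(12.6, 12.6, 10))
  expect_lt(abs(voxelData(r$volume)[sv[1], sv[2], sv[3]] - 100), 10)

  # two identical maxima: the lexicographically smaller index wins
  a <- array(0, c(5, 5, 3))
  a[4, 2, 2] <- 50
  a[2, 4, 2] <- 50
  v <- ctVolume(a, c(1, 1, 1))
  expect_equal(autoSeed(v, c(2.5, 2.5, 1.5), searchRadiusMm = 5),
               c(2, 4, 2))

  expect_error(autoSeed(r$volume, c(100, 100, 100)), "outside")
})

test_that("mask QC reports volume, sphericity and flags without editing", {
  r <- renderPhantom(smallScene(100, 12), scanProtocol(1.25, 120, "lung"),
                     seed = 3, noiseScale = 0)
  q <- maskQC(r$masks[[1]], voxelSpacing(r$volume))
  expect_equal(q$voxelCount, voxelCount(r$masks[[1]]))
  expect_gt(q$sphericity, 0.6)
  expect_equal(q$flags, "")
  # a thin plane is flagged as non-spherical
  plane <- array(FALSE, c(20, 20, 20))
  plane[3:18, 3:18, 10] <- TRUE
  q2 <- maskQC(plane, c(1, 1, 1))
  expect_match(q2$flags, "low_sphericity")
})
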