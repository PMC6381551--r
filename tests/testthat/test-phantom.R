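test_that("the design enumerates the full factorial with derived seeds", {
  d <- makeDesign(repetitions = 10, masterSeed = 1)
  protos <- designProtocols(d)
  expect_equal(nrow(protos), 12)
  expect_equal(nrow(unique(protos)), 12)
  expect_setequal(unique(protos$thicknessMm), c(1.25, 2.5, 5.0))
  expect_setequal(unique(protos$tubeCurrentMas), c(30, 120))
  expect_setequal(unique(protos$reconKernel), c("lung", "standard"))
  expect_equal(nrow(designScans(d)), 120)

  d0 <- makeDesign(repetitions = 0, masterSeed = 1)
  expect_equal(nrow(designScans(d0)), 0)
  expect_equal(nrow(designProtocols(d0)), 12)

  d1a <- makeDesign(repetitions = 1, masterSeed = 99)
  d1b <- makeDesign(repetitions = 1, masterSeed = 99)
  expect_identical(designScans(d1a)$childSeed, designScans(d1b)$childSeed)
  expect_true(all(designScans(d1a)$childSeed < 2^31))

  expect_error(makeDesign(repetitions = -1), "nonnegative")
})

test_that("the noise model reproduces its reference points and scalings", {
  expect_equal(noiseSigma(scanProtocol(5.0, 120, "standard")), 12)
  expect_equal(noiseSigma(scanProtocol(5.0, 30, "standard")), 24)
  # 12 * sqrt(5 / 1.25) * 2, hand-computed
  expect_equal(noiseSigma(scanProtocol(1.25, 120, "lung")), 48)
  expect_error(
    noiseSigma(list(thicknessMm = -1, tubeCurrentMas = 120,
                    reconKernel = "lung")), "positive")
  expect_error(
    noiseSigma(list(thicknessMm = 5, tubeCurrentMas = 0,
                    reconKernel = "lung")), "positive")
})

test_that("rendering is deterministic and recovers target density", {
  sc <- smallScene(100, 12)
  p <- scanProtocol(1.25, 120, "standard")
  r1 <- renderPhantom(sc, p, seed = 11)
  r2 <- renderPhantom(sc, p, seed = 11)
  expect_identical(voxelData(r1$volume), voxelData(r2$volume))
  expect_identical(maskArray(r1$masks[[1]]), maskArray(r2$masks[[1]]))
  expect_equal(voxelSpacing(r1$volume)[3], 1.25)

  # noise-free render: interior (mask eroded by 1 voxel) within 10 HU
  r0 <- renderPhantom(sc, p, seed = 11, noiseScale = 0)
  m <- maskArray(r0$masks[[1]])
  er <- m
  for (d in 1:3) for (t in c(-1, 1))
    er <- er & nodtex:::shiftArray(m, t, d)
  expect_lt(abs(mean(voxelData(r0$volume)[er]) - 100), 10)
})

test_that("measured background noise follows the mAs, thickness and kernel orderings", {
  bg <- backgroundScene()
  sdAt <- function(th, mas, kern, seed) {
    r <- renderPhantom(bg, scanProtocol(th, mas, kern), seed = seed)
    stats::sd(voxelData(r$volume))
  }
  # sigma ratio 30 vs 120 mAs = sqrt(4) = 2, within 5% (3 seeds)
  ratios <- vapply(1:3, function(s)
    sdAt(2.5, 30, "standard", s) / sdAt(2.5, 120, "standard", s + 50),
    numeric(1))
  expect_true(all(abs(ratios - 2) < 0.1))
  # monotone orderings at fixed seeds
  for (s in 1:3) {
    expect_gt(sdAt(1.25, 120, "standard", s), sdAt(2.5, 120, "standard", s))
    expect_gt(sdAt(2.5, 120, "standard", s), sdAt(5.0, 120, "standard", s))
    expect_gt(sdAt(2.5, 30, "standard", s), sdAt(2.5, 120, "standard", s))
    expect_gt(sdAt(2.5, 120, "lung", s), sdAt(2.5, 120, "standard", s))
  }
})

test_that("relocation jitters centres but not diameters or densities", {
  sc <- defaultScene()
  s1 <- relocateNodules(sc, 2, seed = 1)
  s2 <- relocateNodules(sc, 2, seed = 2)
  for (i in seq_along(sceneNodules(sc))) {
    expect_false(isTRUE(all.equal(sceneNodules(s1)[[i]]@centerMm,
                                  sceneNodules(s2)[[i]]@centerMm)))
    expect_equal(sceneNodules(s1)[[i]]@diameterMm,
                 sceneNodules(sc)[[i]]@diameterMm)
    expect_equal(sceneNodules(s1)[[i]]@targetHu,
                 sceneNodules(sc)[[i]]@targetHu)
  }
})

test_that("ground-truth mask volume approximates the analytic sphere", {
  p <- scanProtocol(1.25, 120, "standard")
  for (dmm in c(10, 12)) {
    r <- renderPhantom(smallScene(100, dmm), p, seed = 5, noiseScale = 0)
    vol <- voxelCount(r$masks[[1]]) * prod(voxelSpacing(r$volume))
    vtrue <- 4 / 3 * pi * (dmm / 2)^3
    expect_lt(abs(vol - vtrue) / vtrue, 0.15)
  }
})

test_that("a nodule that does not fit the field of view is rejected", {
  expect_error(
    phantomScene(list(noduleSpec(12, 100, c(3, 12, 10))),
                 fieldOfViewMm = c(25.2, 25.2, 20)),
    "fit inside")
})
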