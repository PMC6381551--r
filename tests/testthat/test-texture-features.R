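test_that("histogram features recover closed forms and brute-force moments", {
  # degenerate distribution
  f <- histogramFeatures(rep(7L, 20))
  expect_equal(unname(f), c(7, 0, 0, 0, 0, 1, 0))

  # uniform over all 256 bins: entropy 8 bits, energy 1/256
  f2 <- histogramFeatures(rep(0:255, each = 3))
  expect_equal(unname(f2["hist_entropy"]), 8)
  expect_equal(unname(f2["hist_energy"]), 1 / 256)

  # 4-point sample {0,0,0,1}: independent moment computation
  x <- c(0, 0, 0, 1)
  m <- sum(x) / 4
  mu2 <- sum((x - m)^2) / 4
  mu3 <- sum((x - m)^3) / 4
  mu4 <- sum((x - m)^4) / 4
  f3 <- histogramFeatures(as.integer(x))
  expect_equal(unname(f3["hist_mean"]), 0.25)
  expect_equal(unname(f3["hist_variance"]), 0.1875)
  expect_equal(unname(f3["hist_skewness"]), mu3 / mu2^1.5)
  expect_equal(unname(f3["hist_kurtosis"]), mu4 / mu2^2 - 3)
  expect_equal(unname(f3["hist_stddev"])^2, unname(f3["hist_variance"]),
               tolerance = 1e-12)
})

test_that("feature extraction returns the 20 named features with valid ranges", {
  r <- renderPhantom(smallScene(100, 10), scanProtocol(2.5, 120, "standard"),
                     seed = 21)
  f <- extractFeatures(r$volume, r$masks[[1]],
                       covariates = list(density_hu = 100))
  expect_equal(names(f)[1:20], featureNames())
  expect_equal(ncol(f), 21)
  expect_true(all(is.finite(unlist(f[1:20]))))
  expect_gt(f$glcm_homogeneity, 0); expect_lte(f$glcm_homogeneity, 1)
  expect_gt(f$glcm_asm, 0); expect_lte(f$glcm_asm, 1)
  expect_gt(f$glcm_probability_max, 0); expect_lte(f$glcm_probability_max, 1)
  expect_gte(f$glcm_entropy, 0); expect_lte(f$glcm_entropy, 2 * log2(256))
  expect_gte(f$hist_entropy, 0); expect_lte(f$hist_entropy, 2 * log2(256))
  expect_equal(f$hist_stddev^2, f$hist_variance, tolerance = 1e-9)
  # energy = sqrt(ASM) holds exactly per direction (averaging the
  # square root over directions is not the square root of the average)
  roi <- quantizeHU(r$volume, r$masks[[1]])
  for (k in c(1, 7, 13)) {
    fd <- glcmFeatures(computeGLCM(roi, directionOffsets()[k, ]))
    expect_equal(unname(fd["glcm_energy"])^2, unname(fd["glcm_asm"]),
                 tolerance = 1e-12)
  }
})

test_that("an isotropic constant ROI gives the same features in every direction", {
  m <- array(FALSE, c(11, 11, 11))
  ctr <- c(6, 6, 6)
  for (i in 1:11) for (j in 1:11) for (k in 1:11)
    m[i, j, k] <- sum((c(i, j, k) - ctr)^2) <= 16
  v <- ctVolume(array(0, c(11, 11, 11)), c(1, 1, 1))
  roi <- quantizeHU(v, m)
  offs <- directionOffsets()
  per <- sapply(seq_len(nrow(offs)), function(k)
    glcmFeatures(computeGLCM(roi, offs[k, ])))
  f <- extractFeatures(v, m)
  for (nm in rownames(per)) {
    expect_equal(stats::sd(per[nm, ]), 0)
    expect_equal(f[[nm]], unname(per[nm, 1]))
  }
})

test_that("features are invariant to rigid whole-voxel translation", {
  set.seed(88)
  core <- randomGrayROI(c(5, 5, 4), levels = 6L, maskProb = 0.8)
  place <- function(at) {
    hu <- core * 16 - 1024  # gray level g back to a HU inside bin g
    big <- array(-1024, c(16, 16, 12))
    msk <- array(FALSE, c(16, 16, 12))
    big[at[1]:(at[1] + 4), at[2]:(at[2] + 4), at[3]:(at[3] + 3)] <-
      ifelse(is.na(hu), -1024, hu)
    msk[at[1]:(at[1] + 4), at[2]:(at[2] + 4), at[3]:(at[3] + 3)] <-
      !is.na(core)
    extractFeatures(ctVolume(big, c(1, 1, 1)), msk)
  }
  expect_equal(place(c(2, 3, 2)), place(c(9, 8, 6)))
})

test_that("gray-level inversion preserves contrast but not the gray-level emphases", {
  set.seed(99)
  g <- randomGrayROI(c(6, 6, 4), levels = 12L)
  gflip <- 255L - g
  roi <- asQuantizedROI(g); roiF <- asQuantizedROI(gflip)
  off <- c(1, 0, 0)
  f <- glcmFeatures(computeGLCM(roi, off))
  fF <- glcmFeatures(computeGLCM(roiF, off))
  expect_equal(f["glcm_contrast"], fF["glcm_contrast"])
  expect_equal(f["glcm_dissimilarity"], fF["glcm_dissimilarity"])
  r <- glrlmFeatures(computeGLRLM(roi, off))
  rF <- glrlmFeatures(computeGLRLM(roiF, off))
  expect_gt(rF["glrlm_hgre"], r["glrlm_hgre"])  # bright relabeling
  expect_lt(rF["glrlm_lgre"], r["glrlm_lgre"])
})

test_that("the direction mean equals the mean of per-direction oracle features", {
  set.seed(202)
  g <- randomGrayROI(c(4, 4, 4), levels = 5L)
  hu <- array(ifelse(is.na(g), -1024, g * 16 - 1024), dim(g))
  v <- ctVolume(hu, c(1, 1, 1))
  msk <- array(!is.na(g), dim(g))
  f <- extractFeatures(v, msk)
  offs <- directionOffsets()
  perG <- rowMeans(sapply(seq_len(nrow(offs)), function(k)
    glcmFeatures(matrix(bruteGLCM(g, offs[k, ]), 256, 256))))
  perR <- rowMeans(sapply(seq_len(nrow(offs)), function(k)
    glrlmFeatures(bruteGLRLM(g, offs[k, ]))))
  for (nm in names(perG)) expect_equal(f[[nm]], unname(perG[nm]))
  for (nm in names(perR)) expect_equal(f[[nm]], unname(perR[nm]))
})

test_that("direction offsets cover the 26-neighbourhood without double counting", {
  offs <- directionOffsets()
  expect_equal(nrow(offs), 13)
  all26 <- rbind(offs, -offs)
  expect_equal(nrow(unique(all26)), 26)
  expect_true(all(offs %in% c(-1, 0, 1)))
  expect_false(any(rowSums(abs(offs)) == 0))
})
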