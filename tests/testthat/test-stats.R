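test_that("min-max scaling maps features onto [0, 1] and is idempotent", {
  tab <- data.frame(matrix(0, nrow = 3, ncol = 20))
  names(tab) <- featureNames()
  for (f in featureNames()) tab[[f]] <- c(2, 4, 6)
  s <- minmaxScale(tab)
  expect_equal(s$hist_mean, c(0, 0.5, 1))
  expect_equal(min(s$glrlm_hgre), 0)
  expect_equal(max(s$glrlm_hgre), 1)
  expect_equal(minmaxScale(s)$hist_mean, s$hist_mean)  # idempotent
  sc <- attr(s, "scaling")
  expect_equal(sc$min[sc$feature == "hist_mean"], 2)

  tab$glcm_asm <- 1
  expect_error(minmaxScale(tab), "glcm_asm")
})

test_that("the regression recovers injected dummy effects", {
  set.seed(1234)
  tab <- syntheticFeatureTable(reps = 10,
                               effects = list(thickness_1.25 = 0.4),
                               noiseSd = 0.01, base = 0.3)
  expect_equal(nrow(tab), 240)
  fit <- fitFeatureRegression(tab, "hist_mean")
  expect_equal(length(fit$coefficients), 4)
  expect_lt(abs(fit$coefficients["thickness_1.25"] - 0.4), 0.01)
  expect_lte(fit$pValues[["thickness_1.25"]], 0.05)
})

test_that("a constant response yields zero effects and the constant itself", {
  tab <- syntheticFeatureTable(reps = 2, noiseSd = 0, base = 0.42)
  # lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(fitFeatureRegression(tab, "glcm_contrast"))
  expect_equal(unname(fit$coefficients), rep(0, 4), tolerance = 1e-10)
  expect_equal(fit$constant, 0.42, tolerance = 1e-10)
})

test_that("a missing protocol cell makes the design rank-deficient", {
  tab <- syntheticFeatureTable(reps = 2)
  drop <- tab$thickness_mm == 5 & tab$mas == 30 & tab$kernel == "lung"
  expect_error(fitFeatureRegression(tab[!drop, ], "hist_mean"),
               "rank-deficient")
})

test_that("pairwise contrasts obey the reference, antisymmetry and chain identities", {
  set.seed(555)
  tab <- syntheticFeatureTable(reps = 10,
                               effects = list(thickness_2.5 = 0.2,
                                              thickness_1.25 = 0.5),
                               noiseSd = 0.01)
  fit <- fitFeatureRegression(tab, "hist_mean")
  c52 <- pairwiseContrast(fit, "thickness", "5", "2.5")
  expect_equal(unname(c52["rc"]),
               unname(fit$coefficients["thickness_2.5"]))
  c25 <- pairwiseContrast(fit, "thickness", "2.5", "1.25")
  c52r <- pairwiseContrast(fit, "thickness", "2.5", "5")
  expect_equal(unname(c52["rc"]), -unname(c52r["rc"]))
  # injected difference 0.5 - 0.2 = 0.3
  expect_lt(abs(c25["rc"] - 0.3), 0.02)
  # exact linear-algebra identity
  c51 <- pairwiseContrast(fit, "thickness", "5", "1.25")
  expect_equal(unname(c51["rc"] - c52["rc"]), unname(c25["rc"]),
               tolerance = 1e-12)
  expect_error(pairwiseContrast(fit, "mas", "30", "30"), "identical")
})

test_that("|RC| summaries reproduce the published worked examples", {
  t2 <- publishedCoefficients("100")
  expect_equal(unname(rcSummary(t2$thickness_2.5)),
               c(0.541, 0.388, 0.011))
  expect_equal(unname(rcSummary(t2$thickness_1.25)),
               c(0.672, 0.574, 0.135))
  expect_equal(unname(rcSummary(t2$mas_120)["max"]), 0.186)
  t4 <- publishedCoefficients("-630")
  expect_equal(unname(rcSummary(t4$kernel_standard)["max"]), 0.436)

  expect_equal(unname(rcSummary(rep(-0.3, 20))), c(0.3, 0.3, 0.3))
  expect_error(rcSummary(1:19), "exactly 20")

  set.seed(8)
  for (i in 1:10) {
    s <- rcSummary(stats::rnorm(20))
    expect_true(s["min"] <= s["median"] && s["median"] <= s["max"])
  }
})

test_that("Cohen's d matches closed forms, thresholds and invariances", {
  set.seed(99)
  a <- as.numeric(scale(stats::rnorm(100)))  # mean 0, sample SD 1
  es <- cohensD(a, a + 1)
  expect_equal(es$d, 1, tolerance = 1e-12)
  expect_equal(es$category, "large")
  expect_equal(es$direction, "<")

  expect_equal(cohensD(a, a + 0.5)$category, "medium")
  expect_equal(cohensD(a, a + 0.19)$category, "none")
  expect_equal(cohensD(a, a + 0.25)$category, "small")

  same <- cohensD(a, a)
  expect_equal(same$d, 0)
  expect_equal(same$direction, "0")

  b <- stats::rnorm(60, 2, 3)
  expect_equal(cohensD(a, b)$d, cohensD(b, a)$d)
  expect_equal(cohensD(a + 5, b + 5)$d, cohensD(a, b)$d)
  expect_equal(cohensD(a * 3, b * 3)$d, cohensD(a, b)$d, tolerance = 1e-12)

  zc <- cohensD(rep(1, 5), rep(2, 5))
  expect_true(is.infinite(zc$d))
  expect_true(attr(zc, "infiniteD"))
  expect_equal(cohensD(rep(1, 5), rep(1, 5))$d, 0)
  expect_error(cohensD(1, 1:5), "at least 2")
})

test_that("significance tallies count the 100 comparison sets per stratum", {
  grid <- expand.grid(feature = featureNames(),
                      contrast = nodtex:::CONTRAST_NAMES,
                      stringsAsFactors = FALSE)
  grid$p <- 0.01
  t1 <- significanceTally(grid)
  expect_equal(unname(t1$perContrast), rep(20L, 5), ignore_attr = TRUE)
  expect_equal(t1$totalSignificant, 100)
  expect_equal(t1$totalSets, 100)
  grid$p <- 0.5
  expect_equal(significanceTally(grid)$totalSignificant, 0)
  expect_error(significanceTally(grid[-1, ]), "20 features")
})

test_that("estimates are unbiased and the test keeps its nominal size", {
  set.seed(321)
  nrep <- 50
  bhat <- matrix(NA_real_, nrep, 2)
  nullP <- numeric(0)
  for (r in seq_len(nrep)) {
    tab <- syntheticFeatureTable(reps = 10,
                                 effects = list(thickness_1.25 = 0.3,
                                                mas_120 = 0.1),
                                 noiseSd = 0.05)
    fit <- fitFeatureRegression(tab, "hist_mean")
    bhat[r, ] <- fit$coefficients[c("thickness_1.25", "mas_120")]
    # thickness_2.5 and kernel_standard carry no injected effect
    fit2 <- fitFeatureRegression(tab, "glcm_contrast")
    nullP <- c(nullP,
               fit$pValues[c("thickness_2.5", "kernel_standard")],
               fit2$pValues[c("thickness_2.5", "kernel_standard")])
  }
  mcse <- apply(bhat, 2, stats::sd) / sqrt(nrep)
  expect_lt(abs(mean(bhat[, 1]) - 0.3), 2 * mcse[1])
  expect_lt(abs(mean(bhat[, 2]) - 0.1), 2 * mcse[2])
  typeI <- mean(nullP <= 0.05)
  expect_gte(typeI, 0.03)
  expect_lte(typeI, 0.07)
})
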