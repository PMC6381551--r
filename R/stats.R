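## Parameter-effect statistics: per-feature dummy-coded multiple
## regression, pairwise contrasts, |RC| summaries, Cohen's d effect
## sizes, significance tallies.

CONTRAST_NAMES <- c("thickness_5.0_vs_2.5", "thickness_5.0_vs_1.25",
                    "thickness_2.5_vs_1.25", "mas_30_vs_120",
                    "kernel_lung_vs_standard")

#' Min-max scale the feature columns of a table
#'
#' Each feature column is independently mapped to [0, 1] by
#' `(x - min) / (max - min)` across all observations in the table
#' (apply per density stratum). The regression coefficients of the
#' study are on this normalized scale. Scaling constants are recorded
#' in the `scaling` attribute; applying the function twice is a no-op.
#'
#' @param table data.frame with the feature columns.
#' @param featureCols columns to scale (default [featureNames()]).
#' @return The table with scaled feature columns and a `scaling`
#'   attribute (data.frame of feature, min, max).
#' @export
minmaxScale <- function(table, featureCols = featureNames()) {
  sc <- data.frame(feature = featureCols, min = NA_real_, max = NA_real_,
                   stringsAsFactors = FALSE)
  for (k in seq_along(featureCols)) {
    nm <- featureCols[k]
    x <- table[[nm]]
    if (is.null(x)) stop("missing feature column: ", nm, call. = FALSE)
    rng <- range(x)
    if (!all(is.finite(rng)))
      stop("non-finite values in feature: ", nm, call. = FALSE)
    if (rng[1] == rng[2])
      stop("constant feature column cannot be scaled: ", nm, call. = FALSE)
    table[[nm]] <- (x - rng[1]) / (rng[2] - rng[1])
    sc$min[k] <- rng[1]; sc$max[k] <- rng[2]
  }
  attr(table, "scaling") <- sc
  table
}

# Factor-coded design columns with the study's reference levels:
# thickness 5.0 mm, 30 mAs, lung kernel.
designFactors <- function(table) {
  data.frame(
    thickness = factor(as.character(table$thickness_mm),
                       levels = c("5", "2.5", "1.25")),
    mas = factor(as.character(table$mas), levels = c("30", "120")),
    kernel = factor(as.character(table$kernel),
                    levels = c("lung", "standard"))
  )
}

#' Dummy-coded multiple regression of one feature on the scan parameters
#'
#' Ordinary least squares of the (scaled) feature on an intercept plus
#' four dummy variables: thickness 2.5 and 1.25 mm (reference 5.0 mm),
#' 120 mAs (reference 30 mAs) and standard kernel (reference lung).
#' Two-sided t-test p-values per coefficient; significance is read at
#' p <= 0.05.
#'
#' @param table feature table (one row per nodule observation) with
#'   covariate columns `thickness_mm`, `mas`, `kernel`.
#' @param featureName the feature column to regress.
#' @return A list of class `featureFit`: `feature`, `constant`,
#'   `coefficients` and `pValues` (named `thickness_2.5`,
#'   `thickness_1.25`, `mas_120`, `kernel_standard`), `vcov`, `df`,
#'   `fit` (the underlying `lm`).
#' @export
fitFeatureRegression <- function(table, featureName) {
  y <- table[[featureName]]
  if (is.null(y)) stop("missing feature column: ", featureName,
                       call. = FALSE)
  df <- designFactors(table)
  df$y <- y
  if (any(table(df$thickness, df$mas, df$kernel) == 0))
    stop("rank-deficient design: at least one protocol cell is empty",
         call. = FALSE)
  fit <- stats::lm(y ~ thickness + mas + kernel, data = df)
  sm <- summary(fit)$coefficients
  map <- c(thickness_2.5 = "thickness2.5", thickness_1.25 = "thickness1.25",
           mas_120 = "mas120", kernel_standard = "kernelstandard")
  coefs <- stats::coef(fit)[map]
  names(coefs) <- names(map)
  pv <- sm[map, "Pr(>|t|)"]
  names(pv) <- names(map)
  structure(list(feature = featureName,
                 constant = unname(stats::coef(fit)["(Intercept)"]),
                 coefficients = coefs, pValues = pv,
                 vcov = stats::vcov(fit),
                 df = stats::df.residual(fit), fit = fit),
            class = "featureFit")
}

#' @export
print.featureFit <- function(x, ...) {
  cat(sprintf("featureFit: %s ~ thickness + mAs + kernel\n", x$feature))
  cat(sprintf("  constant %.4f\n", x$constant))
  for (nm in names(x$coefficients))
    cat(sprintf("  %-16s %+.4f  (p = %.4g)\n", nm, x$coefficients[nm],
                x$pValues[nm]))
  invisible(x)
}

coefNameFor <- function(factor, level) {
  lvl <- as.character(level)
  switch(factor,
    thickness = switch(lvl, "5" = NA_character_,
                       "2.5" = "thickness2.5", "1.25" = "thickness1.25",
                       stop("unknown thickness level: ", lvl, call. = FALSE)),
    mas = switch(lvl, "30" = NA_character_, "120" = "mas120",
                 stop("unknown mAs level: ", lvl, call. = FALSE)),
    kernel = switch(lvl, "lung" = NA_character_,
                    "standard" = "kernelstandard",
                    stop("unknown kernel level: ", lvl, call. = FALSE)),
    stop("unknown factor: ", factor, call. = FALSE))
}

#' Pairwise contrast between two levels of one scan parameter
#'
#' The regression coefficient (RC) for level B relative to level A,
#' obtained as a linear contrast of the fitted dummy coefficients:
#' contrast(5.0, 2.5) equals the thickness 2.5 coefficient, and
#' contrast(2.5, 1.25) equals coefficient(1.25) - coefficient(2.5).
#' The p-value is the two-sided t-test of the contrast.
#'
#' @param fit a `featureFit` from [fitFeatureRegression()].
#' @param factor `"thickness"`, `"mas"` or `"kernel"`.
#' @param levelA,levelB the two levels being compared (A is the
#'   baseline of the comparison).
#' @return Named numeric: `rc` and `p`.
#' @export
pairwiseContrast <- function(fit, factor, levelA, levelB) {
  if (as.character(levelA) == as.character(levelB))
    stop("identical levels in contrast", call. = FALSE)
  cn <- colnames(fit$vcov)
  cc <- stats::setNames(numeric(length(cn)), cn)
  na <- coefNameFor(factor, levelA)
  nb <- coefNameFor(factor, levelB)
  if (!is.na(nb)) cc[nb] <- 1
  if (!is.na(na)) cc[na] <- -1
  beta <- stats::coef(fit$fit)
  rc <- sum(cc * beta)
  se <- sqrt(drop(t(cc) %*% fit$vcov %*% cc))
  tval <- rc / se
  p <- 2 * stats::pt(-abs(tval), df = fit$df)
  c(rc = rc, p = p)
}

#' Max / median / min summary of 20 absolute regression coefficients
#'
#' The median is the LOWER median: the 10th order statistic of the 20
#' ordered absolute values. Exactly 20 coefficients (one per feature)
#' are required.
#'
#' @param coefficients numeric vector of exactly 20 regression
#'   coefficients for one contrast.
#' @return Named numeric: `max`, `median`, `min` of the absolute values.
#' @examples
#' rcSummary(c(rep(0.2, 19), -0.7))
#' @export
rcSummary <- function(coefficients) {
  if (length(coefficients) != 20)
    stop("exactly 20 coefficients (one per feature) are required",
         call. = FALSE)
  a <- sort(abs(coefficients))
  c(max = a[20], median = a[10], min = a[1])
}

#' Cohen's d effect size between two groups
#'
#' `d = |mean(A) - mean(B)| / s_pooled` with the pooled SD
#' `sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2))`. Classified
#' small at d >= 0.20, medium at >= 0.50, large at >= 0.80 (below 0.20:
#' "none"). The direction symbol comes from a Welch two-sample t-test
#' at p <= 0.05: `"<"` when A is significantly smaller, `">"` when
#' larger, `"0"` otherwise.
#'
#' @param groupA,groupB numeric vectors (>= 2 observations each).
#' @return A one-row data.frame: `d`, `category`, `direction`, `p`.
#' @examples
#' set.seed(1)
#' cohensD(rnorm(50), rnorm(50, mean = 1))
#' @export
cohensD <- function(groupA, groupB) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2 || nB < 2)
    stop("both groups need at least 2 observations", call. = FALSE)
  mA <- mean(groupA); mB <- mean(groupB)
  sp <- sqrt(((nA - 1) * stats::var(groupA) +
              (nB - 1) * stats::var(groupB)) / (nA + nB - 2))
  infiniteD <- FALSE
  if (sp == 0) {
    if (mA == mB) d <- 0 else { d <- Inf; infiniteD <- TRUE }
    p <- 1
  } else {
    d <- abs(mA - mB) / sp
    p <- tryCatch(stats::t.test(groupA, groupB)$p.value,
                  error = function(e) 1)
  }
  category <- if (d >= 0.8) "large" else if (d >= 0.5) "medium"
              else if (d >= 0.2) "small" else "none"
  direction <- if (is.na(p) || p > 0.05) "0" else if (mA < mB) "<" else ">"
  out <- data.frame(d = d, category = category, direction = direction,
                    p = p, stringsAsFactors = FALSE)
  attr(out, "infiniteD") <- infiniteD
  out
}

#' Tally significant (feature, contrast) pairs
#'
#' Per contrast, the number of the 20 features with p <= 0.05, and the
#' total over all 100 (feature, contrast) comparison sets of a stratum.
#'
#' @param contrastTable data.frame with columns `feature`, `contrast`,
#'   `p` — 20 features x 5 contrasts.
#' @return A list: `perContrast` (named integer vector over the 5
#'   contrasts) and `totalSignificant` out of `totalSets` (100).
#' @export
significanceTally <- function(contrastTable) {
  need <- c("feature", "contrast", "p")
  if (!all(need %in% names(contrastTable)))
    stop("contrastTable needs columns feature, contrast, p", call. = FALSE)
  tab <- table(contrastTable$contrast)
  if (length(unique(contrastTable$feature)) != 20 || any(tab != 20) ||
      length(tab) != length(CONTRAST_NAMES))
    stop("expected 20 features x 5 contrasts", call. = FALSE)
  sig <- contrastTable$p <= 0.05
  per <- tapply(sig, contrastTable$contrast, sum)
  per <- per[CONTRAST_NAMES]
  list(perContrast = per, totalSignificant = sum(sig),
       totalSets = nrow(contrastTable))
}

#' Full parameter-effect analysis of one density stratum
#'
#' Min-max scales the 20 features, fits the dummy-coded regression per
#' feature, evaluates the five pairwise contrasts (thickness 5.0 vs
#' 2.5, 5.0 vs 1.25, 2.5 vs 1.25; 30 vs 120 mAs; lung vs standard
#' kernel), summarises |RC| per contrast, computes Cohen's d per
#' (feature, contrast) by pooling all observations at each level, and
#' tallies significance. Headline tallies use raw p-values (mirroring
#' the study); a Holm-adjusted column is emitted alongside but never
#' used for the tallies.
#'
#' @param table feature table of one density stratum (from
#'   [runStudy()] / [extractFeatures()]).
#' @return A list of class `strataAnalysis`: `coefficients` (per
#'   feature: constant + 4 dummies + p-values), `contrasts` (feature x
#'   contrast RC/p/p_holm), `rcSummaries`, `effectSizes`, `tally`,
#'   `scaling`.
#' @export
analyzeStratum <- function(table) {
  scaled <- minmaxScale(table)
  feats <- featureNames()
  fits <- lapply(feats, function(f) fitFeatureRegression(scaled, f))
  names(fits) <- feats

  coefTab <- do.call(rbind, lapply(fits, function(ft)
    data.frame(feature = ft$feature, constant = ft$constant,
               thickness_2.5 = ft$coefficients["thickness_2.5"],
               thickness_1.25 = ft$coefficients["thickness_1.25"],
               mas_120 = ft$coefficients["mas_120"],
               kernel_standard = ft$coefficients["kernel_standard"],
               p_thickness_2.5 = ft$pValues["thickness_2.5"],
               p_thickness_1.25 = ft$pValues["thickness_1.25"],
               p_mas_120 = ft$pValues["mas_120"],
               p_kernel_standard = ft$pValues["kernel_standard"],
               row.names = NULL, stringsAsFactors = FALSE)))

  contrastSpec <- list(
    c("thickness", "5", "2.5"), c("thickness", "5", "1.25"),
    c("thickness", "2.5", "1.25"), c("mas", "30", "120"),
    c("kernel", "lung", "standard"))
  rows <- list()
  for (fi in seq_along(fits)) {
    for (ci in seq_along(contrastSpec)) {
      cs <- contrastSpec[[ci]]
      r <- pairwiseContrast(fits[[fi]], cs[1], cs[2], cs[3])
      rows[[length(rows) + 1]] <- data.frame(
        feature = feats[fi], contrast = CONTRAST_NAMES[ci],
        rc = unname(r["rc"]), p = unname(r["p"]),
        stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, rows)
  contrasts$p_holm <- stats::p.adjust(contrasts$p, method = "holm")

  rcSummaries <- do.call(rbind, lapply(CONTRAST_NAMES, function(cn) {
    s <- rcSummary(contrasts$rc[contrasts$contrast == cn])
    data.frame(contrast = cn, max_abs = s["max"], median_abs = s["median"],
               min_abs = s["min"], row.names = NULL,
               stringsAsFactors = FALSE)
  }))

  levelPairs <- list(
    thickness = list(c("5", "2.5"), c("5", "1.25"), c("2.5", "1.25")),
    mas = list(c("30", "120")),
    kernel = list(c("lung", "standard")))
  fac <- designFactors(scaled)
  esRows <- list()
  ci <- 0
  for (fname in names(levelPairs)) {
    for (pair in levelPairs[[fname]]) {
      ci <- ci + 1
      cn <- CONTRAST_NAMES[ci]
      for (f in feats) {
        a <- scaled[[f]][fac[[fname]] == pair[1]]
        b <- scaled[[f]][fac[[fname]] == pair[2]]
        es <- cohensD(a, b)
        esRows[[length(esRows) + 1]] <- data.frame(
          feature = f, contrast = cn, d = es$d, category = es$category,
          direction = es$direction, p = es$p, stringsAsFactors = FALSE)
      }
    }
  }
  effectSizes <- do.call(rbind, esRows)

  structure(list(coefficients = coefTab, contrasts = contrasts,
                 rcSummaries = rcSummaries, effectSizes = effectSizes,
                 tally = significanceTally(contrasts),
                 scaling = attr(scaled, "scaling")),
            class = "strataAnalysis")
}

#' @export
print.strataAnalysis <- function(x, ...) {
  cat("Parameter-effect analysis (one density stratum)\n")
  cat(sprintf("  %d of %d (feature, contrast) sets significant at p <= 0.05\n",
              x$tally$totalSignificant, x$tally$totalSets))
  print(x$rcSummaries, row.names = FALSE)
  invisible(x)
}

#' Analyse both density strata of a feature table
#'
#' Splits the table on `density_hu` (+100 vs -630) and runs
#' [analyzeStratum()] on each.
#'
#' @param table full feature table with a `density_hu` column.
#' @return Named list of `strataAnalysis` objects
#'   (`"100"`, `"-630"`).
#' @export
analyzeFeatures <- function(table) {
  if (is.null(table$density_hu))
    stop("feature table needs a density_hu column", call. = FALSE)
  out <- lapply(split(table, table$density_hu), analyzeStratum)
  # order: solid first
  nm <- names(out)
  out[order(match(nm, c("100", "-630")))]
}
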