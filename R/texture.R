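## Texture-features module: 4096 -> 256 quantization, 7 histogram
## features, 8 GLCM features and 5 GLRLM features, computed per
## direction over the 13 unique 3D offsets at distance 1 and averaged.

#' Names of the twenty radiomic features
#'
#' @return Character vector of the 20 feature column names, in order:
#'   7 histogram, 8 GLCM, 5 GLRLM.
#' @export
featureNames <- function() {
  c("hist_mean", "hist_stddev", "hist_variance", "hist_skewness",
    "hist_kurtosis", "hist_energy", "hist_entropy",
    "glcm_contrast", "glcm_dissimilarity", "glcm_homogeneity",
    "glcm_asm", "glcm_energy", "glcm_probability_max", "glcm_entropy",
    "glcm_correlation",
    "glrlm_lre", "glrlm_gln", "glrlm_rln", "glrlm_lgre", "glrlm_hgre")
}

#' The thirteen unique 3D direction offsets
#'
#' The 26-neighbourhood of a voxel contains 13 axis pairs (each offset
#' and its negation); this returns one lexicographically positive
#' representative per axis (first nonzero component is +1), at
#' distance 1.
#'
#' @return A 13 x 3 integer matrix of offsets.
#' @export
directionOffsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  firstNonzero <- apply(g, 1, function(r) r[which(r != 0)[1]])
  g <- g[firstNonzero > 0, , drop = FALSE]
  g <- g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
  rownames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

#' Quantize the HU values of an ROI to 256 gray levels
#'
#' Maps the full 4096-level HU window to 256 gray levels with exactly 16
#' raw levels per bin: `g = floor((HU + 1024) / 16)`, clamped to
#' [0, 255]. The window is global (not per-ROI min-max) so features stay
#' comparable across protocols. The result is cropped to the bounding
#' box of the mask; voxels outside the mask are NA.
#'
#' @param volume a [CTVolume-class].
#' @param mask an [ROIMask-class] or logical array on the same grid.
#' @return A [QuantizedROI-class].
#' @examples
#' v <- ctVolume(array(c(-1024, 3071, 0, 0), c(2, 2, 1)), c(1, 1, 1))
#' m <- array(TRUE, c(2, 2, 1))
#' grayValues(quantizeHU(v, m))
#' @export
quantizeHU <- function(volume, mask) {
  m <- if (is(mask, "ROIMask")) maskArray(mask) else mask
  v <- voxelData(volume)
  stopifnot(all(dim(m) == dim(v)))
  if (!any(m)) stop("empty ROI: the mask has no voxels", call. = FALSE)
  bb <- maskBoundingBox(m)
  ix <- bb[[1]][1]:bb[[1]][2]
  iy <- bb[[2]][1]:bb[[2]][2]
  iz <- bb[[3]][1]:bb[[3]][2]
  sub <- v[ix, iy, iz, drop = FALSE]
  msub <- m[ix, iy, iz, drop = FALSE]
  g <- floor((sub - HU_MIN) / 16)
  g <- pmin(pmax(g, 0), GRAY_LEVELS - 1)
  g[!msub] <- NA
  storage.mode(g) <- "integer"
  new("QuantizedROI", grayVolume = g, nVoxels = sum(msub),
      levels = GRAY_LEVELS)
}

#' Histogram features of the quantized ROI
#'
#' Population moments of the per-voxel quantized gray values — mean,
#' standard deviation, variance, skewness and excess kurtosis (so a
#' Gaussian scores 0) — plus energy and Shannon entropy of the 256-bin
#' normalized histogram. Skewness and kurtosis are defined as 0 when
#' the variance is 0.
#'
#' @param values integer gray values (e.g. `grayValues(roi)`), or a
#'   [QuantizedROI-class].
#' @return Named numeric of length 7: `hist_mean`, `hist_stddev`,
#'   `hist_variance`, `hist_skewness`, `hist_kurtosis`, `hist_energy`,
#'   `hist_entropy` (bits).
#' @export
histogramFeatures <- function(values) {
  if (is(values, "QuantizedROI")) values <- grayValues(values)
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0) stop("empty ROI: no values", call. = FALSE)
  m <- mean(values)
  dev <- values - m
  v <- mean(dev^2)
  sk <- if (v > 0) mean(dev^3) / v^1.5 else 0
  ku <- if (v > 0) mean(dev^4) / v^2 - 3 else 0
  p <- tabulate(values + 1L, nbins = GRAY_LEVELS) / n
  energy <- sum(p^2)
  pp <- p[p > 0]
  entropy <- -sum(pp * log2(pp))
  c(hist_mean = m, hist_stddev = sqrt(v), hist_variance = v,
    hist_skewness = sk, hist_kurtosis = ku, hist_energy = energy,
    hist_entropy = entropy)
}

#' Gray-level co-occurrence matrix of an ROI along one direction
#'
#' Counts every voxel pair `(p, p + offset * distance)` with both voxels
#' inside the mask into `counts[g(p) + 1, g(p + offset) + 1]`.
#' Accumulation is single-direction (asymmetric): the worked count for
#' the canonical 2D example (entry (1,1) = 2 at 0 degrees) is matched
#' exactly. Set `symmetric = TRUE` to also accumulate the transposed
#' pairs.
#'
#' @param roi a [QuantizedROI-class].
#' @param offset integer 3-vector from [directionOffsets()].
#' @param distance inter-voxel distance in voxels (default 1).
#' @param symmetric accumulate both orientations (default FALSE).
#' @return A 256 x 256 integer matrix of counts with attributes
#'   `offset`, `distance`, `npairs` and `degenerate` (TRUE when the ROI
#'   has no valid pair along this offset).
#' @export
computeGLCM <- function(roi, offset, distance = 1L, symmetric = FALSE) {
  g <- grayVolume(roi)
  d <- dim(g)
  off <- as.integer(offset) * as.integer(distance)
  rngFrom <- function(k) {
    if (off[k] >= 0) seq_len(max(0L, d[k] - off[k]))
    else if (1L - off[k] > d[k]) integer(0)
    else (1L - off[k]):d[k]
  }
  counts <- matrix(0L, GRAY_LEVELS, GRAY_LEVELS)
  ix <- rngFrom(1); iy <- rngFrom(2); iz <- rngFrom(3)
  npairs <- 0L
  if (length(ix) && length(iy) && length(iz)) {
    g1 <- g[ix, iy, iz, drop = FALSE]
    g2 <- g[ix + off[1], iy + off[2], iz + off[3], drop = FALSE]
    keep <- !is.na(g1) & !is.na(g2)
    a <- g1[keep]; b <- g2[keep]
    npairs <- length(a)
    if (npairs > 0) {
      tab <- tabulate(a * GRAY_LEVELS + b + 1L,
                      nbins = GRAY_LEVELS * GRAY_LEVELS)
      counts <- matrix(tab, GRAY_LEVELS, GRAY_LEVELS, byrow = TRUE)
      if (symmetric) {
        counts <- counts + t(counts)
        npairs <- 2L * npairs
      }
    }
  }
  structure(counts, offset = as.integer(offset),
            distance = as.integer(distance), npairs = npairs,
            degenerate = npairs == 0L)
}

#' The eight GLCM features
#'
#' With `P` the pair-normalized co-occurrence matrix and `i`, `j` the
#' gray levels: contrast `sum P (i-j)^2`, dissimilarity `sum P |i-j|`,
#' homogeneity `sum P / (1 + (i-j)^2)`, angular second moment
#' `sum P^2`, energy `sqrt(ASM)`, maximal probability `max P`, Shannon
#' entropy `-sum P log2 P` (bits), and correlation
#' `sum P (i - mu_i)(j - mu_j) / (sigma_i sigma_j)` — defined as 1 when
#' either marginal SD is 0 (a perfectly homogeneous ROI), with a
#' `degenerateCorrelation` attribute set.
#'
#' @param counts a count matrix from [computeGLCM()].
#' @return Named numeric of length 8 (`glcm_*`).
#' @export
glcmFeatures <- function(counts) {
  if (isTRUE(attr(counts, "degenerate")))
    stop("degenerate co-occurrence matrix: no voxel pairs", call. = FALSE)
  total <- sum(counts)
  if (total == 0)
    stop("degenerate co-occurrence matrix: no voxel pairs", call. = FALSE)
  P <- counts / total
  n <- nrow(P)
  lv <- seq_len(n) - 1
  D <- outer(lv, lv, "-")
  contrast <- sum(P * D^2)
  dissimilarity <- sum(P * abs(D))
  homogeneity <- sum(P / (1 + D^2))
  asm <- sum(P^2)
  energy <- sqrt(asm)
  pmax_ <- max(P)
  pp <- P[P > 0]
  entropy <- -sum(pp * log2(pp))
  pi_ <- rowSums(P)
  pj_ <- colSums(P)
  mui <- sum(lv * pi_); muj <- sum(lv * pj_)
  si <- sqrt(sum((lv - mui)^2 * pi_))
  sj <- sqrt(sum((lv - muj)^2 * pj_))
  degenerateCorr <- (si * sj == 0)
  corr <- if (degenerateCorr) 1
          else sum(P * outer(lv - mui, lv - muj)) / (si * sj)
  structure(
    c(glcm_contrast = contrast, glcm_dissimilarity = dissimilarity,
      glcm_homogeneity = homogeneity, glcm_asm = asm,
      glcm_energy = energy, glcm_probability_max = pmax_,
      glcm_entropy = entropy, glcm_correlation = corr),
    degenerateCorrelation = degenerateCorr)
}

#' Gray-level run-length matrix of an ROI along one direction
#'
#' Sweeps the ROI by maximal lines parallel to `offset`; within each
#' line, maximal runs of equal gray value (broken by mask boundaries)
#' are counted once each into `counts[gray + 1, length]`. Every masked
#' voxel belongs to exactly one run per direction, so
#' `sum_ij j * N(i, j)` equals the ROI voxel count.
#'
#' @param roi a [QuantizedROI-class].
#' @param offset integer 3-vector from [directionOffsets()].
#' @return A 256 x Rmax integer matrix of run counts with attributes
#'   `offset`, `nruns` and `degenerate`.
#' @export
computeGLRLM <- function(roi, offset) {
  g <- grayVolume(roi)
  off <- as.integer(offset)
  if (all(off == 0)) stop("offset must be nonzero", call. = FALSE)
  w <- which(!is.na(g), arr.ind = TRUE)
  if (nrow(w) == 0) stop("empty ROI", call. = FALSE)
  vals <- g[!is.na(g)]  # column-major order, same as which()
  ax <- which(off != 0)[1]
  s <- w[, ax] * off[ax]
  base <- w - s %o% off   # line anchor: constant along a line
  key <- paste(base[, 1], base[, 2], base[, 3], sep = ",")
  o <- order(key, s)
  key <- key[o]; s <- s[o]; vals <- vals[o]
  newRun <- c(TRUE, key[-1] != key[-length(key)] |
                s[-1] != s[-length(s)] + 1L |
                vals[-1] != vals[-length(vals)])
  runId <- cumsum(newRun)
  runLen <- tabulate(runId)
  runGray <- vals[newRun]
  rmax <- max(runLen)
  counts <- matrix(0L, GRAY_LEVELS, rmax)
  tab <- tabulate((runLen - 1L) * GRAY_LEVELS + runGray + 1L,
                  nbins = GRAY_LEVELS * rmax)
  counts <- matrix(tab, GRAY_LEVELS, rmax)
  structure(counts, offset = off, nruns = length(runLen),
            degenerate = length(runLen) == 0L)
}

#' The five GLRLM features
#'
#' With `P` the run-count-normalized matrix, `j` the run length and
#' `i' = i + 1` the 1-based gray weighting (so gray level 0 does not
#' blow up the low-gray emphasis): long-run emphasis `sum j^2 P`,
#' gray-level nonuniformity `sum_i (sum_j P)^2`, run-length
#' nonuniformity `sum_j (sum_i P)^2`, low-gray-level run emphasis
#' `sum P / i'^2` and high-gray-level run emphasis `sum i'^2 P`.
#' All five are invariant to scaling the counts by a constant.
#'
#' @param counts a run-length count matrix from [computeGLRLM()].
#' @return Named numeric of length 5 (`glrlm_*`).
#' @export
glrlmFeatures <- function(counts) {
  total <- sum(counts)
  if (total == 0) stop("degenerate run-length matrix: no runs", call. = FALSE)
  P <- counts / total
  jw <- seq_len(ncol(P))        # run lengths 1..Rmax
  iw <- seq_len(nrow(P))        # 1-based gray weighting i' = i + 1
  lre <- sum(sweep(P, 2, jw^2, "*"))
  gln <- sum(rowSums(P)^2)
  rln <- sum(colSums(P)^2)
  lgre <- sum(rowSums(P) / iw^2)
  hgre <- sum(rowSums(P) * iw^2)
  c(glrlm_lre = lre, glrlm_gln = gln, glrlm_rln = rln,
    glrlm_lgre = lgre, glrlm_hgre = hgre)
}

#' Extract the twenty features of one nodule observation
#'
#' Quantizes the masked voxels, computes the 7 histogram features once,
#' then the 8 GLCM and 5 GLRLM features in each of the 13 directions at
#' distance 1 and averages each feature arithmetically over the
#' non-degenerate directions (directions with no voxel pair / no run
#' are excluded from the mean rather than zero-filled).
#'
#' @param volume a [CTVolume-class].
#' @param mask an [ROIMask-class] or logical array.
#' @param covariates optional named list appended to the output row
#'   (e.g. density, diameter, protocol, repetition).
#' @return A one-row data.frame: the 20 feature columns of
#'   [featureNames()] plus any covariates.
#' @export
extractFeatures <- function(volume, mask, covariates = list()) {
  roi <- quantizeHU(volume, mask)
  hist7 <- histogramFeatures(roi)
  offs <- directionOffsets()
  glcmAcc <- NULL; nGlcm <- 0L
  glrlmAcc <- NULL; nGlrlm <- 0L
  for (k in seq_len(nrow(offs))) {
    cm <- computeGLCM(roi, offs[k, ])
    if (!isTRUE(attr(cm, "degenerate"))) {
      f <- glcmFeatures(cm)
      glcmAcc <- if (is.null(glcmAcc)) f else glcmAcc + f
      nGlcm <- nGlcm + 1L
    }
    rm_ <- computeGLRLM(roi, offs[k, ])
    if (!isTRUE(attr(rm_, "degenerate"))) {
      f <- glrlmFeatures(rm_)
      glrlmAcc <- if (is.null(glrlmAcc)) f else glrlmAcc + f
      nGlrlm <- nGlrlm + 1L
    }
  }
  if (nGlcm == 0L || nGlrlm == 0L)
    stop("all 13 directions are degenerate for this ROI", call. = FALSE)
  feats <- c(hist7, glcmAcc / nGlcm, glrlmAcc / nGlrlm)
  out <- as.data.frame(as.list(feats))
  names(out) <- featureNames()
  for (nm in names(covariates)) out[[nm]] <- covariates[[nm]]
  out
}
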