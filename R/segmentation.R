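## Segmentation module: seeded 3D region growing with frozen inclusion
## criteria, automatic seed selection, and mask QC.

# The 26 neighbour offsets of a voxel.
neighborOffsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

#' Default growing criterion for a nodule density
#'
#' Fixed HU inclusion intervals: `[-200, 400]` for solid (+100 HU)
#' nodules and `[-800, -400]` for ground-glass (-630 HU) nodules.
#'
#' @param targetHu the nominal nodule attenuation; >= -300 selects the
#'   solid interval, below it the ground-glass interval.
#' @return A [GrowCriterion-class].
#' @export
defaultCriterion <- function(targetHu) {
  if (targetHu >= -300) growCriterion("fixed_interval", -200, 400)
  else growCriterion("fixed_interval", -800, -400)
}

resolveInterval <- function(volumeArr, seedPoint, criterion) {
  if (criterion@mode == "fixed_interval")
    return(c(criterion@lowHu, criterion@highHu))
  # seed-adaptive: statistics of the 3x3x3 neighbourhood of the seed,
  # frozen before growth starts
  d <- dim(volumeArr)
  rg <- lapply(1:3, function(k)
    max(1L, seedPoint[k] - 1L):min(d[k], seedPoint[k] + 1L))
  nb <- volumeArr[rg[[1]], rg[[2]], rg[[3]]]
  m <- mean(nb)
  s <- stats::sd(nb)
  if (is.na(s)) s <- 0
  c(m - criterion@adaptK * s, m + criterion@adaptK * s)
}

#' Segment a nodule by seeded region growing
#'
#' Breadth-first growth from `seedPoint` over 26-connected neighbours
#' whose HU satisfies the (frozen) inclusion criterion. The interval
#' never drifts during growth, so the result is a pure function of the
#' volume, the criterion and the connected component containing the
#' seed — independent of growth order.
#'
#' @param volume a [CTVolume-class].
#' @param seedPoint integer voxel index (i, j, k), 1-based.
#' @param criterion a [GrowCriterion-class].
#' @param presmoothSigmaMm optional Gaussian pre-smoothing (mm) applied
#'   to a working copy of the volume before evaluating the criterion
#'   (default 0 = none). Used by the pipeline on noisy volumes as the
#'   automated stand-in for manual contour review.
#' @return An [ROIMask-class] with `source = "region_grow"`. If the
#'   region touches the volume border a `boundary_leak` flag is attached
#'   and a warning raised.
#' @export
regionGrow <- function(volume, seedPoint, criterion,
                       presmoothSigmaMm = 0) {
  v <- voxelData(volume)
  d <- dim(v)
  seedPoint <- as.integer(seedPoint)
  if (length(seedPoint) != 3 || any(seedPoint < 1) || any(seedPoint > d))
    stop("seedPoint must be a voxel index inside the volume", call. = FALSE)
  if (any(!is.finite(v)))
    stop("volume must be finite-valued", call. = FALSE)
  if (presmoothSigmaMm > 0)
    v <- gaussSmooth3d(v, presmoothSigmaMm / voxelSpacing(volume))
  iv <- resolveInterval(v, seedPoint, criterion)
  ok <- v >= iv[1] & v <= iv[2]
  seedLin <- seedPoint[1] + (seedPoint[2] - 1L) * d[1] +
    (seedPoint[3] - 1L) * d[1] * d[2]
  if (!ok[seedLin])
    stop("empty region: the seed voxel fails the inclusion criterion",
         call. = FALSE)
  offs <- neighborOffsets26()
  visited <- array(FALSE, d)
  visited[seedLin] <- TRUE
  frontier <- matrix(seedPoint, ncol = 3)
  while (nrow(frontier) > 0) {
    cand <- frontier[rep(seq_len(nrow(frontier)), times = nrow(offs)), ,
                     drop = FALSE] +
      offs[rep(seq_len(nrow(offs)), each = nrow(frontier)), , drop = FALSE]
    inb <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
           cand[, 2] >= 1 & cand[, 2] <= d[2] &
           cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[inb, , drop = FALSE]
    lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] +
      (cand[, 3] - 1L) * d[1] * d[2]
    keep <- ok[lin] & !visited[lin]
    lin <- lin[keep]
    cand <- cand[keep, , drop = FALSE]
    if (length(lin)) {
      dupes <- duplicated(lin)
      lin <- lin[!dupes]
      cand <- cand[!dupes, , drop = FALSE]
      visited[lin] <- TRUE
    }
    frontier <- cand
  }
  flags <- character()
  w <- which(visited, arr.ind = TRUE)
  if (any(w[, 1] == 1L | w[, 1] == d[1] | w[, 2] == 1L | w[, 2] == d[2] |
          w[, 3] == 1L | w[, 3] == d[3])) {
    flags <- "boundary_leak"
    warning("grown region reaches the volume border", call. = FALSE)
  }
  roiMask(visited, source = "region_grow", flags = flags)
}

#' Automatic seed selection near an approximate centre
#'
#' Returns the voxel of maximal HU within `searchRadiusMm` of the given
#' physical point; ties are broken by the lexicographically smallest
#' (i, j, k) index. For solid nodules this lands in the bright core; for
#' ground-glass nodules it stays inside the nodule provided the search
#' radius does not exceed the nodule radius.
#'
#' @param volume a [CTVolume-class].
#' @param approxCenterMm physical point (x, y, z) in mm.
#' @param searchRadiusMm search radius in mm (default 5).
#' @return Integer voxel index (i, j, k).
#' @export
autoSeed <- function(volume, approxCenterMm, searchRadiusMm = 5) {
  v <- voxelData(volume)
  d <- dim(v)
  sp <- voxelSpacing(volume)
  org <- voxelOrigin(volume)
  p <- as.numeric(approxCenterMm) - org
  if (any(p < 0) || any(p > d * sp))
    stop("approximate centre lies outside the volume", call. = FALSE)
  lo <- pmax(1L, as.integer(floor((p - searchRadiusMm) / sp)))
  hi <- pmin(d, as.integer(ceiling((p + searchRadiusMm) / sp)) + 1L)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  cx <- (ix - 0.5) * sp[1]; cy <- (iy - 0.5) * sp[2]; cz <- (iz - 0.5) * sp[3]
  d2 <- outer(outer((cx - p[1])^2, (cy - p[2])^2, "+"), (cz - p[3])^2, "+")
  inBall <- d2 <= searchRadiusMm^2
  if (!any(inBall))
    stop("empty search window: no voxel centre within the search radius",
         call. = FALSE)
  sub <- v[ix, iy, iz]
  sub[!inBall] <- -Inf
  mx <- max(sub)
  w <- which(sub == mx, arr.ind = TRUE)
  w <- w[order(w[, 1], w[, 2], w[, 3]), , drop = FALSE]
  c(ix[w[1, 1]], iy[w[1, 2]], iz[w[1, 3]])
}

#' Dice overlap between two masks
#'
#' `2|A intersect B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b [ROIMask-class] objects or logical arrays of equal shape.
#' @return Dice coefficient in [0, 1].
#' @export
diceOverlap <- function(a, b) {
  ma <- if (is(a, "ROIMask")) maskArray(a) else a
  mb <- if (is(b, "ROIMask")) maskArray(b) else b
  stopifnot(all(dim(ma) == dim(mb)))
  denom <- sum(ma) + sum(mb)
  if (denom == 0) return(NA_real_)
  2 * sum(ma & mb) / denom
}

#' Quality control summary of a segmented mask
#'
#' Computes voxel count, physical volume, a voxel-surface sphericity
#' index `pi^(1/3) (6V)^(2/3) / A` (A from exposed voxel faces, which
#' overestimates the true area, so even a perfect sphere scores below
#' 1), and QC flags. Masks are flagged, never edited: `low_sphericity`
#' when sphericity <= 0.6, `boundary` when the mask touches the volume
#' border, `empty` when it has no voxels.
#'
#' @param mask an [ROIMask-class] or logical array.
#' @param spacingMm voxel spacing (x, y, z) in mm.
#' @return A one-row data.frame: `voxelCount`, `volumeMm3`,
#'   `sphericity`, `flags` (semicolon-separated).
#' @export
maskQC <- function(mask, spacingMm) {
  m <- if (is(mask, "ROIMask")) maskArray(mask) else mask
  d <- dim(m)
  n <- sum(m)
  if (n == 0)
    return(data.frame(voxelCount = 0L, volumeMm3 = 0, sphericity = NA_real_,
                      flags = "empty", stringsAsFactors = FALSE))
  vol <- n * prod(spacingMm)
  faceArea <- c(spacingMm[2] * spacingMm[3],
                spacingMm[1] * spacingMm[3],
                spacingMm[1] * spacingMm[2])
  area <- 0
  for (ax in 1:3) {
    shp <- shiftArray(m, 1L, ax)   # neighbour below (edge-replicated)
    shm <- shiftArray(m, -1L, ax)
    exposed <- sum(m & !shp) + sum(m & !shm)
    # edge replication hides border faces; count them explicitly
    idx <- function(a, i) switch(ax, a[i, , ], a[, i, ], a[, , i])
    exposed <- exposed + sum(idx(m, 1L)) + sum(idx(m, d[ax]))
    area <- area + exposed * faceArea[ax]
  }
  sph <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  flags <- character()
  if (sph <= 0.6) flags <- c(flags, "low_sphericity")
  w <- which(m, arr.ind = TRUE)
  if (any(w[, 1] == 1L | w[, 1] == d[1] | w[, 2] == 1L | w[, 2] == d[2] |
          w[, 3] == 1L | w[, 3] == d[3]))
    flags <- c(flags, "boundary")
  data.frame(voxelCount = n, volumeMm3 = vol, sphericity = sph,
             flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
}
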