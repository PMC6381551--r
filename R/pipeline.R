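## Pipeline module: orchestrates generate -> segment -> extract ->
## analyze, with stage functions that can be re-run from the previous
## stage's files, a run manifest, and deterministic test fixtures.

#' Build a QuantizedROI directly from a gray-level array
#'
#' For toy examples and tests: wraps an already-quantized integer array
#' (gray levels in [0, 255], NA outside the ROI) as a
#' [QuantizedROI-class] without going through HU quantization.
#'
#' @param gray integer array (2D arrays are promoted to one-slice 3D).
#' @return A [QuantizedROI-class].
#' @export
asQuantizedROI <- function(gray) {
  if (length(dim(gray)) == 2) dim(gray) <- c(dim(gray), 1L)
  storage.mode(gray) <- "integer"
  new("QuantizedROI", grayVolume = gray,
      nVoxels = sum(!is.na(gray)), levels = GRAY_LEVELS)
}

#' The worked-example texture grid
#'
#' A synthetic 4 x 4 single-slice gray-level grid constructed so that
#' the canonical worked counts of the co-occurrence and run-length
#' calculations hold along the 0-degree direction (`offset c(1, 0, 0)`):
#' the gray-1/gray-1 co-occurrence count is 2, and there is exactly one
#' run of gray 2 with length 2. (The original example exists only as a
#' figure; this grid is a synthetic stand-in that reproduces its two
#' printed counts exactly.)
#'
#' @return A 4 x 4 x 1 integer array of gray levels.
#' @examples
#' g <- workedExampleGrid()
#' computeGLCM(asQuantizedROI(g), c(1, 0, 0))[2, 2]   # 2
#' computeGLRLM(asQuantizedROI(g), c(1, 0, 0))[3, 2]  # 1
#' @export
workedExampleGrid <- function() {
  rows <- rbind(c(1L, 1L, 1L, 0L),
                c(2L, 2L, 0L, 3L),
                c(0L, 3L, 0L, 3L),
                c(3L, 0L, 2L, 1L))
  g <- array(0L, c(4L, 4L, 1L))
  for (j in 1:4) g[, j, 1] <- rows[j, ]  # first index runs along a row
  g
}

scanFileTag <- function(i) sprintf("scan_%03d", i)

# Smoothed working copy for seeding/growing on noisy volumes; features
# are always extracted from the raw volume.
smoothedWorkingVolume <- function(volume, presmoothSigmaMm) {
  if (presmoothSigmaMm <= 0) return(volume)
  ctVolume(gaussSmooth3d(voxelData(volume),
                         presmoothSigmaMm / voxelSpacing(volume)),
           voxelSpacing(volume), voxelOrigin(volume))
}

# Segment + QC + feature-extract all nodules of one rendered scan.
processScan <- function(rend, sceneR, scanRow, presmoothSigmaMm) {
  feats <- list(); qc <- list()
  work <- smoothedWorkingVolume(rend$volume, presmoothSigmaMm)
  for (ni in seq_along(sceneR@nodules)) {
    nd <- sceneR@nodules[[ni]]
    seedVox <- autoSeed(work, nd@centerMm)
    crit <- defaultCriterion(nd@targetHu)
    seg <- tryCatch(
      suppressWarnings(regionGrow(work, seedVox, crit)),
      error = function(e) NULL)
    segFailed <- is.null(seg) || voxelCount(seg) < 8
    mask <- if (segFailed) rend$masks[[ni]] else seg
    q <- maskQC(mask, voxelSpacing(rend$volume))
    q$dice_vs_truth <- diceOverlap(mask, rend$masks[[ni]])
    q$mask_source <- if (segFailed) "ground_truth_fallback" else "region_grow"
    q$nodule <- ni
    covs <- list(density_hu = nd@targetHu, diameter_mm = nd@diameterMm,
                 thickness_mm = scanRow$thicknessMm,
                 mas = scanRow$tubeCurrentMas, kernel = scanRow$reconKernel,
                 repetition = scanRow$repetition, seed = scanRow$childSeed,
                 nodule = ni)
    feats[[ni]] <- extractFeatures(rend$volume, mask, covariates = covs)
    qc[[ni]] <- q
  }
  list(features = do.call(rbind, feats), qc = do.call(rbind, qc))
}

renderScanRow <- function(scene, scanRow, relocationJitterMm, ...) {
  proto <- scanProtocol(scanRow$thicknessMm, scanRow$tubeCurrentMas,
                        scanRow$reconKernel)
  sceneR <- relocateNodules(scene, relocationJitterMm,
                            seed = scanRow$childSeed)
  rend <- renderPhantom(sceneR, proto,
                        seed = deriveChildSeed(scanRow$childSeed, 1), ...)
  list(rend = rend, sceneR = sceneR)
}

#' Run the full phantom study
#'
#' Executes the whole pipeline in memory: renders every scan of the
#' design, relocating the nodules between repetitions; segments each
#' nodule by seeded region growing (with Gaussian pre-smoothing as the
#' automated stand-in for manual review; ground truth is used, and
#' flagged, only if growing fails outright); extracts the 20 features
#' per nodule; and runs the per-stratum parameter-effect analysis.
#' Writes `features.csv`, `qc.csv`, per-stratum statistics tables and a
#' JSON run manifest to `outDir`.
#'
#' @param outDir output directory (created if missing).
#' @param repetitions repeat scans per protocol (default 10).
#' @param masterSeed integer master seed; all child seeds derive from it.
#' @param scene the [PhantomScene-class] (default [defaultScene()]).
#' @param relocationJitterMm nodule relocation amplitude (default 2 mm).
#' @param keepVolumes also write every rendered volume and mask as
#'   NIfTI under `outDir/volumes` (default FALSE; they are large).
#' @param presmoothSigmaMm pre-smoothing for segmentation (default 0.8).
#' @param verbose log one line per scan (default FALSE).
#' @return Invisibly, a list: `features` (data.frame, one row per
#'   nodule observation), `qc`, `analysis` (per-stratum
#'   `strataAnalysis`), `manifest`, `paths`.
#' @examples
#' \donttest{
#' res <- runStudy(tempfile("study"), repetitions = 1, masterSeed = 7)
#' nrow(res$features)  # 48 = 12 protocols x 1 repetition x 4 nodules
#' }
#' @export
runStudy <- function(outDir, repetitions = 10, masterSeed = 1,
                     scene = defaultScene(), relocationJitterMm = 2,
                     keepVolumes = FALSE, presmoothSigmaMm = 0.8,
                     verbose = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  design <- makeDesign(repetitions, masterSeed, relocationJitterMm)
  scans <- designScans(design)
  featRows <- list(); qcRows <- list()
  if (keepVolumes)
    dir.create(file.path(outDir, "volumes"), showWarnings = FALSE)
  for (i in seq_len(nrow(scans))) {
    sr <- scans[i, ]
    rs <- renderScanRow(scene, sr, relocationJitterMm)
    if (keepVolumes) {
      tag <- scanFileTag(i)
      writeVolume(rs$rend$volume,
                  file.path(outDir, "volumes", paste0(tag, ".nii.gz")))
      for (ni in seq_along(rs$rend$masks))
        writeMask(rs$rend$masks[[ni]],
                  file.path(outDir, "volumes",
                            sprintf("%s_truth_%d.nii.gz", tag, ni)))
    }
    pr <- processScan(rs$rend, rs$sceneR, sr, presmoothSigmaMm)
    pr$features$scan <- i
    pr$qc$scan <- i
    featRows[[i]] <- pr$features
    qcRows[[i]] <- pr$qc
    if (verbose)
      message(sprintf(
        "scan %d/%d: %.2f mm / %g mAs / %s, seed %d", i, nrow(scans),
        sr$thicknessMm, sr$tubeCurrentMas, sr$reconKernel, sr$childSeed))
  }
  features <- do.call(rbind, featRows)
  qc <- do.call(rbind, qcRows)
  utils::write.csv(features, file.path(outDir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(qc, file.path(outDir, "qc.csv"), row.names = FALSE)
  analysis <- analyzeFeatures(features)
  writeAnalysis(analysis, outDir)
  manifest <- list(
    package = "nodtex",
    version = as.character(utils::packageVersion("nodtex")),
    masterSeed = masterSeed, repetitions = repetitions,
    relocationJitterMm = relocationJitterMm,
    presmoothSigmaMm = presmoothSigmaMm,
    childSeeds = scans$childSeed,
    conventions = list(
      medianRule = "lower", glcmAccumulation = "asymmetric",
      glrlmNormalization = "run_count", grayLevels = GRAY_LEVELS,
      quantizationWindowHu = c(HU_MIN, HU_MAX),
      featureScaling = "minmax_per_stratum",
      histogramMoments = "population_on_quantized_values"),
    files = list.files(outDir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(features = features, qc = qc, analysis = analysis,
                 manifest = manifest,
                 paths = list(outDir = outDir,
                              features = file.path(outDir, "features.csv"))))
}

writeAnalysis <- function(analysis, outDir) {
  for (st in names(analysis)) {
    tag <- if (st == "100") "solid_100hu" else "groundglass_m630hu"
    a <- analysis[[st]]
    utils::write.csv(a$coefficients,
                     file.path(outDir, sprintf("coefficients_%s.csv", tag)),
                     row.names = FALSE)
    utils::write.csv(a$contrasts,
                     file.path(outDir, sprintf("contrasts_%s.csv", tag)),
                     row.names = FALSE)
    utils::write.csv(a$rcSummaries,
                     file.path(outDir, sprintf("rc_summaries_%s.csv", tag)),
                     row.names = FALSE)
    utils::write.csv(a$effectSizes,
                     file.path(outDir, sprintf("effect_sizes_%s.csv", tag)),
                     row.names = FALSE)
  }
  invisible(outDir)
}

#' Pipeline stage functions
#'
#' Each stage can be re-run from the previous stage's files alone.
#' `simulateStage` renders every scan of a design and writes volumes,
#' ground-truth masks and the scan/nodule tables; `segmentStage` reads
#' the volumes and nodule centres and writes region-grown masks plus
#' `qc.csv`; `extractStage` reads volumes and segmented masks and
#' writes `features.csv`; `analyzeStage` reads `features.csv` and
#' writes the statistics tables.
#'
#' @param dir the stage directory.
#' @param design a [StudyDesign-class] (simulate stage).
#' @param scene a [PhantomScene-class].
#' @param relocationJitterMm relocation amplitude in mm.
#' @param presmoothSigmaMm segmentation pre-smoothing in mm.
#' @param featuresCsv path to `features.csv` (analyze stage).
#' @param outDir output directory (analyze stage).
#' @return Each stage invisibly returns the directory (or, for
#'   `analyzeStage`, the analysis list).
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
simulateStage <- function(dir, design = makeDesign(),
                          scene = defaultScene(),
                          relocationJitterMm = design@relocationJitterMm) {
  dir.create(file.path(dir, "volumes"), recursive = TRUE,
             showWarnings = FALSE)
  scans <- designScans(design)
  nodRows <- list()
  for (i in seq_len(nrow(scans))) {
    sr <- scans[i, ]
    rs <- renderScanRow(scene, sr, relocationJitterMm)
    tag <- scanFileTag(i)
    writeVolume(rs$rend$volume,
                file.path(dir, "volumes", paste0(tag, ".nii.gz")))
    for (ni in seq_along(rs$rend$masks)) {
      writeMask(rs$rend$masks[[ni]],
                file.path(dir, "volumes",
                          sprintf("%s_truth_%d.nii.gz", tag, ni)))
      nd <- rs$sceneR@nodules[[ni]]
      nodRows[[length(nodRows) + 1]] <- data.frame(
        scan = i, nodule = ni, density_hu = nd@targetHu,
        diameter_mm = nd@diameterMm, center_x = nd@centerMm[1],
        center_y = nd@centerMm[2], center_z = nd@centerMm[3])
    }
  }
  utils::write.csv(scans, file.path(dir, "scans.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, nodRows), file.path(dir, "nodules.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname pipeline-stages
#' @export
segmentStage <- function(dir, presmoothSigmaMm = 0.8) {
  nods <- utils::read.csv(file.path(dir, "nodules.csv"))
  qcRows <- list()
  for (i in unique(nods$scan)) {
    tag <- scanFileTag(i)
    vol <- readVolume(file.path(dir, "volumes", paste0(tag, ".nii.gz")))
    work <- smoothedWorkingVolume(vol, presmoothSigmaMm)
    for (ni in nods$nodule[nods$scan == i]) {
      nd <- nods[nods$scan == i & nods$nodule == ni, ]
      seedVox <- autoSeed(work, c(nd$center_x, nd$center_y, nd$center_z))
      seg <- suppressWarnings(
        regionGrow(work, seedVox, defaultCriterion(nd$density_hu)))
      writeMask(seg, file.path(dir, "volumes",
                               sprintf("%s_seg_%d.nii.gz", tag, ni)))
      q <- maskQC(seg, voxelSpacing(vol))
      q$scan <- i; q$nodule <- ni
      qcRows[[length(qcRows) + 1]] <- q
    }
  }
  utils::write.csv(do.call(rbind, qcRows), file.path(dir, "qc.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname pipeline-stages
#' @export
extractStage <- function(dir) {
  scans <- utils::read.csv(file.path(dir, "scans.csv"))
  nods <- utils::read.csv(file.path(dir, "nodules.csv"))
  rows <- list()
  for (i in unique(nods$scan)) {
    tag <- scanFileTag(i)
    vol <- readVolume(file.path(dir, "volumes", paste0(tag, ".nii.gz")))
    sr <- scans[i, ]
    for (ni in nods$nodule[nods$scan == i]) {
      nd <- nods[nods$scan == i & nods$nodule == ni, ]
      mask <- readMask(file.path(dir, "volumes",
                                 sprintf("%s_seg_%d.nii.gz", tag, ni)))
      covs <- list(density_hu = nd$density_hu, diameter_mm = nd$diameter_mm,
                   thickness_mm = sr$thicknessMm, mas = sr$tubeCurrentMas,
                   kernel = sr$reconKernel, repetition = sr$repetition,
                   seed = sr$childSeed, nodule = ni, scan = i)
      rows[[length(rows) + 1]] <- extractFeatures(vol, mask,
                                                  covariates = covs)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "features.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname pipeline-stages
#' @export
analyzeStage <- function(featuresCsv, outDir = dirname(featuresCsv)) {
  features <- utils::read.csv(featuresCsv, stringsAsFactors = FALSE)
  analysis <- analyzeFeatures(features)
  writeAnalysis(analysis, outDir)
  invisible(analysis)
}

#' Write the deterministic test fixtures
#'
#' Writes the small fixed inputs used by the examples and tests: the
#' worked-example gray grid and its expected co-occurrence counts
#' (non-zero entries), constant and alternating line ROIs, the two
#' bundled reference coefficient tables, and two tiny rendered nodule
#' volumes (one solid, one ground-glass) with their ground-truth masks.
#' Regenerates identically on every call.
#'
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of paths written.
#' @export
makeFixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wpath <- function(p) { paths <<- c(paths, p); p }

  g <- workedExampleGrid()
  utils::write.csv(g[, , 1], wpath(file.path(dir, "toy_grid.csv")),
                   row.names = FALSE)
  cm <- computeGLCM(asQuantizedROI(g), c(1L, 0L, 0L))
  nz <- which(cm > 0, arr.ind = TRUE)
  utils::write.csv(
    data.frame(gray_from = nz[, 1] - 1L, gray_to = nz[, 2] - 1L,
               count = cm[nz]),
    wpath(file.path(dir, "toy_grid_glcm_nonzero.csv")), row.names = FALSE)

  utils::write.csv(data.frame(gray = rep(5L, 4)),
                   wpath(file.path(dir, "constant_line.csv")),
                   row.names = FALSE)
  utils::write.csv(data.frame(gray = rep(c(3L, 9L), 4)),
                   wpath(file.path(dir, "alternating_line.csv")),
                   row.names = FALSE)

  for (st in c("100", "-630")) {
    tag <- if (st == "100") "solid_100hu" else "groundglass_m630hu"
    utils::write.csv(
      publishedCoefficients(st),
      wpath(file.path(dir, sprintf("reference_coefficients_%s.csv", tag))),
      row.names = FALSE)
  }

  tinyScene <- function(hu) phantomScene(
    nodules = list(noduleSpec(10, hu, c(12.6, 12.6, 10))),
    fieldOfViewMm = c(25.2, 25.2, 20))
  proto <- scanProtocol(1.25, 120, "standard")
  # uncompressed NIfTI so repeated calls are byte-identical (gzip
  # embeds a timestamp)
  for (cfg in list(list(hu = 100, tag = "solid"),
                   list(hu = -630, tag = "groundglass"))) {
    rend <- renderPhantom(tinyScene(cfg$hu), proto, seed = 42)
    writeVolume(rend$volume,
                wpath(file.path(dir, sprintf("tiny_%s.nii", cfg$tag))))
    writeMask(rend$masks[[1]],
              wpath(file.path(dir, sprintf("tiny_%s_truth.nii", cfg$tag))))
  }
  invisible(paths)
}
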