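## Synthetic phantom module: the factorial scan design, the CT noise
## model, and the renderer that turns a PhantomScene + ScanProtocol into
## a CT-like volume with ground-truth masks.

#' Enumerate the twelve scan protocols
#'
#' Full factorial of slice thickness (1.25, 2.5, 5.0 mm), tube current
#' (30, 120 mAs) and reconstruction kernel (lung, standard).
#'
#' @return A data.frame with 12 rows and columns `thicknessMm`,
#'   `tubeCurrentMas`, `reconKernel`.
#' @export
allProtocols <- function() {
  g <- expand.grid(thicknessMm = THICKNESS_LEVELS,
                   tubeCurrentMas = MAS_LEVELS,
                   reconKernel = KERNEL_LEVELS,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[order(g$thicknessMm, g$tubeCurrentMas, g$reconKernel), , drop = FALSE] ->
    g
  rownames(g) <- NULL
  g
}

# Deterministic, splittable child-seed derivation: every scan gets its
# own seed from (masterSeed, scanIndex), kept below 2^31.
deriveChildSeed <- function(masterSeed, index) {
  m <- as.numeric(masterSeed) %% 2147483647
  as.integer((m * 48271 + as.numeric(index) * 536870909) %% 2147483647)
}

#' Build the study design
#'
#' Crosses the 12 protocols with `repetitions` repeat scans. Each
#' (protocol, repetition) entry carries a child seed derived from
#' `masterSeed`, so any single scan can be reproduced in isolation.
#'
#' @param repetitions number of repeat scans per protocol (default 10,
#'   as in the study design; 0 gives an empty scan list).
#' @param masterSeed integer master seed.
#' @param relocationJitterMm amplitude (mm) of the uniform nodule
#'   relocation applied between repetitions (default 2 mm).
#' @return A [StudyDesign-class] object.
#' @examples
#' d <- makeDesign(repetitions = 10, masterSeed = 1)
#' nrow(designScans(d))      # 120
#' nrow(designProtocols(d))  # 12
#' @export
makeDesign <- function(repetitions = 10, masterSeed = 1,
                       relocationJitterMm = 2) {
  if (length(repetitions) != 1 || is.na(repetitions) || repetitions < 0 ||
      repetitions != round(repetitions))
    stop("repetitions must be a nonnegative integer", call. = FALSE)
  protos <- allProtocols()
  reps <- as.integer(repetitions)
  if (reps > 0) {
    scans <- protos[rep(seq_len(nrow(protos)), each = reps), , drop = FALSE]
    scans$repetition <- rep(seq_len(reps), times = nrow(protos))
    rownames(scans) <- NULL
    scans$childSeed <- deriveChildSeed(masterSeed, seq_len(nrow(scans)))
  } else {
    scans <- protos[0, , drop = FALSE]
    scans$repetition <- integer(0)
    scans$childSeed <- integer(0)
  }
  new("StudyDesign", protocols = protos, scans = scans,
      repetitions = as.numeric(reps),
      relocationJitterMm = as.numeric(relocationJitterMm),
      masterSeed = as.numeric(masterSeed))
}

#' Image-noise standard deviation of a protocol
#'
#' Quantum-noise model for the rendered volumes:
#' `sigma = sigmaRef * sqrt(masRef / mAs) * sqrt(thicknessRef / T) * k(kernel)`.
#' Noise falls as the square root of tube current and of slice
#' thickness, and the sharp lung kernel carries more noise than the
#' smooth standard kernel. The constants are calibrated only to give the
#' qualitative orderings expected of CT reconstructions.
#'
#' @param protocol a [ScanProtocol-class], or a list with elements
#'   `thicknessMm`, `tubeCurrentMas`, `reconKernel` (for exploring
#'   non-standard settings).
#' @param sigmaRef reference noise SD in HU (default 12) at
#'   `masRef`/`thicknessRef` with the standard kernel.
#' @param masRef,thicknessRef reference tube current (120 mAs) and slice
#'   thickness (5.0 mm).
#' @param kernelFactors named multipliers per kernel
#'   (default `c(lung = 2, standard = 1)`).
#' @return Noise standard deviation in HU.
#' @examples
#' noiseSigma(scanProtocol(5.0, 120, "standard"))  # 12
#' noiseSigma(scanProtocol(5.0, 30, "standard"))   # 24
#' noiseSigma(scanProtocol(1.25, 120, "lung"))     # 48
#' @export
noiseSigma <- function(protocol, sigmaRef = 12, masRef = 120,
                       thicknessRef = 5,
                       kernelFactors = c(lung = 2, standard = 1)) {
  if (is(protocol, "ScanProtocol")) {
    th <- protocol@thicknessMm
    mas <- protocol@tubeCurrentMas
    kern <- protocol@reconKernel
  } else {
    th <- protocol$thicknessMm
    mas <- protocol$tubeCurrentMas
    kern <- protocol$reconKernel
  }
  if (is.null(th) || is.null(mas) || th <= 0 || mas <= 0)
    stop("slice thickness and tube current must be positive", call. = FALSE)
  if (!kern %in% names(kernelFactors))
    stop("unknown reconstruction kernel: ", kern, call. = FALSE)
  sigmaRef * sqrt(masRef / mas) * sqrt(thicknessRef / th) *
    unname(kernelFactors[kern])
}

#' The default phantom scene of the study
#'
#' Four spherical nodules — 10 and 12 mm diameters at +100 HU (solid)
#' and -630 HU (ground-glass) — embedded in a homogeneous -850 HU
#' lung-like background box of 70 x 70 x 40 mm.
#'
#' @param lungHu background attenuation (default -850 HU).
#' @return A [PhantomScene-class] object with four nodules.
#' @export
defaultScene <- function(lungHu = -850) {
  phantomScene(
    nodules = list(
      noduleSpec(10, 100, c(18, 18, 20)),
      noduleSpec(12, 100, c(52, 18, 20)),
      noduleSpec(10, -630, c(18, 52, 20)),
      noduleSpec(12, -630, c(52, 52, 20))
    ),
    lungHu = lungHu, bodyHu = 40, fieldOfViewMm = c(70, 70, 40)
  )
}

#' Relocate the nodules of a scene
#'
#' Emulates repositioning of the nodule inserts between repeat scans:
#' each centre is shifted by an independent uniform jitter in
#' `[-jitterMm, jitterMm]` per axis. Diameters and target attenuations
#' are untouched.
#'
#' @param scene a [PhantomScene-class].
#' @param jitterMm jitter amplitude in mm.
#' @param seed integer seed for the jitter draw.
#' @return A new [PhantomScene-class]; errors if a jittered nodule no
#'   longer fits inside the field of view.
#' @export
relocateNodules <- function(scene, jitterMm, seed) {
  if (jitterMm < 0) stop("jitterMm must be nonnegative", call. = FALSE)
  set.seed(seed)
  nods <- lapply(scene@nodules, function(nd) {
    noduleSpec(nd@diameterMm, nd@targetHu,
               nd@centerMm + stats::runif(3, -jitterMm, jitterMm))
  })
  phantomScene(nods, lungHu = scene@lungHu, bodyHu = scene@bodyHu,
               fieldOfViewMm = scene@fieldOfViewMm)
}

# Point-spread-function settings for the two reconstruction kernels.
psfDefaults <- function() {
  list(standardSigmaMm = 0.45,  # smooth kernel: ~1.05 mm FWHM in-plane
       lungSigmaMm = 0.25,      # sharp kernel: ~0.6 mm FWHM ...
       lungEdgeBoost = 0.3,     # ... plus unsharp-mask edge enhancement
       lungEdgeSigmaMm = 0.7)
}

# Heterogeneity texture for one nodule, evaluated at the supersample
# grid points. Generated on a fixed 1 mm isotropic lattice and smoothed
# to the requested correlation length so thick slices genuinely average
# fine structure down.
noduleTexture <- function(center, radius, sdHu, corrMm, xs, ys, zs) {
  pad <- 2 + 2 * corrMm
  lat <- lapply(center, function(c0)
    seq(floor(c0 - radius - pad), ceiling(c0 + radius + pad), by = 1))
  field <- array(stats::rnorm(prod(lengths(lat))), dim = lengths(lat))
  field <- gaussSmooth3d(field, rep(corrMm, 3))
  field <- field * (sdHu / stats::sd(field))
  gridTrilinear(field, lat[[1]], lat[[2]], lat[[3]], xs, ys, zs)
}

#' Render the phantom under a scan protocol
#'
#' Produces a CT-like volume of the scene: nodules are rasterized on a
#' supersampled grid (at most `supersampleMaxMm` per axis) and
#' block-averaged to the protocol grid, so partial-volume dilution grows
#' with slice thickness; an in-plane point-spread blur emulates the
#' reconstruction kernel (standard: wide Gaussian; lung: narrow Gaussian
#' plus an unsharp-mask edge-enhancement term); and zero-mean Gaussian
#' noise with SD [noiseSigma()] of the protocol is added. Ground-truth
#' masks are returned on the protocol grid (a voxel belongs to a nodule
#' when at least half of its subsamples fall inside the sphere).
#'
#' @param scene a [PhantomScene-class].
#' @param protocol a [ScanProtocol-class]; its slice thickness becomes
#'   the z voxel spacing.
#' @param seed integer seed; the render is bit-reproducible given
#'   (scene, protocol, seed).
#' @param inPlaneMm in-plane pixel spacing (default 0.7 mm, typical of a
#'   thorax field of view on a 512 grid).
#' @param noiseScale multiplier on the noise SD; 0 gives a noise-free
#'   render.
#' @param heterogeneitySdHu SD (HU) of the mild textured heterogeneity
#'   inside each nodule (default 5; 0 disables it).
#' @param heterogeneityCorrMm correlation length (mm) of that texture.
#' @param supersampleMaxMm maximum supersample spacing (default 0.25 mm).
#' @param psf list of point-spread settings, see `nodtex:::psfDefaults`.
#' @return `list(volume = CTVolume, masks = list of ROIMask)`, one
#'   ground-truth mask per nodule, in scene order.
#' @export
renderPhantom <- function(scene, protocol, seed, inPlaneMm = 0.7,
                          noiseScale = 1, heterogeneitySdHu = 5,
                          heterogeneityCorrMm = 2,
                          supersampleMaxMm = 0.25, psf = psfDefaults()) {
  validObject(scene)
  validObject(protocol)
  sp <- c(inPlaneMm, inPlaneMm, protocol@thicknessMm)
  nvox <- scene@fieldOfViewMm / sp
  if (any(abs(nvox - round(nvox)) > 1e-6))
    stop("field of view is not an integer number of voxels at this spacing",
         call. = FALSE)
  nvox <- as.integer(round(nvox))
  set.seed(seed)
  vol <- array(scene@lungHu, dim = nvox)
  masks <- vector("list", length(scene@nodules))

  f <- pmax(1L, as.integer(ceiling(sp / supersampleMaxMm)))
  for (ni in seq_along(scene@nodules)) {
    nd <- scene@nodules[[ni]]
    r <- nd@diameterMm / 2
    c0 <- nd@centerMm
    if (any(c0 - r < 0) || any(c0 + r > scene@fieldOfViewMm))
      stop("nodule lies outside the field of view", call. = FALSE)
    lo <- pmax(1L, as.integer(floor((c0 - r) / sp)))
    hi <- pmin(nvox, as.integer(ceiling((c0 + r) / sp)) + 1L)
    nb <- hi - lo + 1L
    # supersample centres along each axis
    subAxis <- function(d) {
      (lo[d] - 1) * sp[d] +
        (seq_len(nb[d] * f[d]) - 0.5) * sp[d] / f[d]
    }
    xs <- subAxis(1); ys <- subAxis(2); zs <- subAxis(3)
    d2 <- outer(outer((xs - c0[1])^2, (ys - c0[2])^2, "+"),
                (zs - c0[3])^2, "+")
    inside <- (d2 <= r^2) * 1
    contrib <- inside * (nd@targetHu - scene@lungHu)
    if (heterogeneitySdHu > 0) {
      tex <- noduleTexture(c0, r, heterogeneitySdHu, heterogeneityCorrMm,
                           xs, ys, zs)
      contrib <- contrib + inside * tex
    }
    occ <- blockMean3d(inside, f)
    delta <- blockMean3d(contrib, f)
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    vol[ix, iy, iz] <- vol[ix, iy, iz] + delta
    gt <- array(FALSE, dim = nvox)
    gt[ix, iy, iz] <- occ >= 0.5
    masks[[ni]] <- roiMask(gt, source = "ground_truth")
  }

  # reconstruction-kernel point spread (in-plane)
  if (protocol@reconKernel == "standard") {
    s <- psf$standardSigmaMm / inPlaneMm
    vol <- gaussSmooth3d(vol, c(s, s, 0))
  } else {
    s <- psf$lungSigmaMm / inPlaneMm
    vol <- gaussSmooth3d(vol, c(s, s, 0))
    se <- psf$lungEdgeSigmaMm / inPlaneMm
    vol <- vol + psf$lungEdgeBoost * (vol - gaussSmooth3d(vol, c(se, se, 0)))
  }

  if (noiseScale > 0) {
    sigma <- noiseSigma(protocol)
    vol <- vol + stats::rnorm(length(vol), 0, sigma * noiseScale)
  }

  list(volume = ctVolume(vol, spacingMm = sp), masks = masks)
}
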