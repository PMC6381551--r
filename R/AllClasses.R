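## Core S4 classes shared by every stage of the phantom pipeline.

# CT display window stored in 12 bits: 4096 integer levels.
HU_MIN <- -1024
HU_MAX <- 3071
GRAY_LEVELS <- 256L

THICKNESS_LEVELS <- c(1.25, 2.5, 5.0)
MAS_LEVELS <- c(30, 120)
KERNEL_LEVELS <- c("lung", "standard")

#' ScanProtocol: one cell of the factorial reconstruction design
#'
#' A scan protocol is one combination of slice thickness, tube
#' current-time product (mAs) and reconstruction kernel. The study design
#' crosses three thicknesses (1.25, 2.5, 5.0 mm), two tube currents
#' (30, 120 mAs) and two kernels ("lung" = sharp, "standard" = smooth),
#' giving twelve distinct protocols.
#'
#' @slot thicknessMm slice thickness in mm; also the z voxel spacing of
#'   any volume rendered under this protocol.
#' @slot tubeCurrentMas tube current-time product in mAs.
#' @slot reconKernel reconstruction kernel, `"lung"` or `"standard"`.
#' @seealso [scanProtocol()], [allProtocols()], [noiseSigma()]
#' @export
setClass("ScanProtocol",
  representation(
    thicknessMm = "numeric",
    tubeCurrentMas = "numeric",
    reconKernel = "character"
  )
)

setValidity("ScanProtocol", function(object) {
  msg <- character()
  if (length(object@thicknessMm) != 1 ||
      !any(abs(object@thicknessMm - THICKNESS_LEVELS) < 1e-9))
    msg <- c(msg, sprintf("thicknessMm must be one of %s",
                          paste(THICKNESS_LEVELS, collapse = ", ")))
  if (length(object@tubeCurrentMas) != 1 ||
      !object@tubeCurrentMas %in% MAS_LEVELS)
    msg <- c(msg, sprintf("tubeCurrentMas must be one of %s",
                          paste(MAS_LEVELS, collapse = ", ")))
  if (length(object@reconKernel) != 1 ||
      !object@reconKernel %in% KERNEL_LEVELS)
    msg <- c(msg, "reconKernel must be 'lung' or 'standard'")
  if (length(msg)) msg else TRUE
})

#' Construct a scan protocol
#'
#' @param thicknessMm slice thickness in mm (1.25, 2.5 or 5.0).
#' @param tubeCurrentMas tube current in mAs (30 or 120).
#' @param reconKernel `"lung"` (sharp) or `"standard"` (smooth).
#' @return A [ScanProtocol-class] object.
#' @examples
#' scanProtocol(1.25, 120, "lung")
#' @export
scanProtocol <- function(thicknessMm, tubeCurrentMas, reconKernel) {
  new("ScanProtocol", thicknessMm = as.numeric(thicknessMm),
      tubeCurrentMas = as.numeric(tubeCurrentMas),
      reconKernel = as.character(reconKernel))
}

#' NoduleSpec: a spherical nodule phantom
#'
#' Describes one spherical nodule insert: its diameter, target
#' attenuation and centre position in physical (mm) coordinates. The
#' study uses 10 and 12 mm nodules at +100 HU (solid) and -630 HU
#' (ground-glass).
#'
#' @slot diameterMm sphere diameter in mm (> 0).
#' @slot targetHu nominal attenuation of the nodule material, in HU.
#' @slot centerMm centre position (x, y, z) in mm.
#' @export
setClass("NoduleSpec",
  representation(diameterMm = "numeric", targetHu = "numeric",
                 centerMm = "numeric")
)

setValidity("NoduleSpec", function(object) {
  msg <- character()
  if (length(object@diameterMm) != 1 || object@diameterMm <= 0)
    msg <- c(msg, "diameterMm must be a single positive number")
  if (length(object@targetHu) != 1)
    msg <- c(msg, "targetHu must be a single number")
  if (length(object@centerMm) != 3)
    msg <- c(msg, "centerMm must have length 3")
  if (length(msg)) msg else TRUE
})

#' Construct a nodule specification
#'
#' @param diameterMm sphere diameter in mm.
#' @param targetHu nominal nodule attenuation in HU.
#' @param centerMm centre (x, y, z) in mm.
#' @return A [NoduleSpec-class] object.
#' @export
noduleSpec <- function(diameterMm, targetHu, centerMm) {
  new("NoduleSpec", diameterMm = as.numeric(diameterMm),
      targetHu = as.numeric(targetHu), centerMm = as.numeric(centerMm))
}

#' PhantomScene: the digital thorax phantom
#'
#' A homogeneous lung-like background box with spherical nodules
#' embedded in it. This is the digital stand-in for the physical
#' anthropomorphic thorax phantom; it carries no vasculature or body
#' wall structure by default.
#'
#' @slot lungHu background attenuation of the lung field (must be
#'   air-like, < -500 HU).
#' @slot bodyHu attenuation assigned outside the lung field (unused when
#'   the lung field fills the whole volume).
#' @slot nodules list of [NoduleSpec-class] objects.
#' @slot fieldOfViewMm extent (x, y, z) of the rendered volume in mm.
#' @export
setClass("PhantomScene",
  representation(lungHu = "numeric", bodyHu = "numeric",
                 nodules = "list", fieldOfViewMm = "numeric")
)

setValidity("PhantomScene", function(object) {
  msg <- character()
  if (object@lungHu >= -500)
    msg <- c(msg, "lungHu must be < -500 (air-like background)")
  if (length(object@fieldOfViewMm) != 3 || any(object@fieldOfViewMm <= 0))
    msg <- c(msg, "fieldOfViewMm must be 3 positive numbers")
  for (nd in object@nodules) {
    if (!is(nd, "NoduleSpec")) {
      msg <- c(msg, "nodules must be a list of NoduleSpec objects")
      break
    }
    if (nd@targetHu <= object@lungHu)
      msg <- c(msg, "nodule targetHu must exceed the lung background")
    r <- nd@diameterMm / 2
    if (any(nd@centerMm - r < 0) ||
        any(nd@centerMm + r > object@fieldOfViewMm))
      msg <- c(msg, sprintf(
        "nodule at (%s) mm does not fit inside the field of view",
        paste(signif(nd@centerMm, 4), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a phantom scene
#'
#' @param nodules list of [NoduleSpec-class] objects.
#' @param lungHu lung-field background attenuation in HU.
#' @param bodyHu attenuation outside the lung field in HU.
#' @param fieldOfViewMm volume extent (x, y, z) in mm.
#' @return A [PhantomScene-class] object.
#' @seealso [defaultScene()] for the study configuration.
#' @export
phantomScene <- function(nodules, lungHu = -850, bodyHu = 40,
                         fieldOfViewMm = c(70, 70, 40)) {
  new("PhantomScene", lungHu = as.numeric(lungHu),
      bodyHu = as.numeric(bodyHu), nodules = nodules,
      fieldOfViewMm = as.numeric(fieldOfViewMm))
}

#' CTVolume: a HU-valued voxel grid with anisotropic spacing
#'
#' @slot voxels 3D numeric array of attenuations in HU, clamped to the
#'   representable window [-1024, 3071] (4096 integer levels when
#'   stored).
#' @slot spacingMm voxel spacing (x, y, z) in mm; the z spacing equals
#'   the slice thickness of the protocol the volume was rendered under.
#' @slot originMm physical position of the corner of the first voxel.
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacingMm = "numeric",
                 originMm = "numeric")
)

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacingMm) != 3 || any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be 3 strictly positive numbers")
  if (length(object@originMm) != 3)
    msg <- c(msg, "originMm must have length 3")
  rng <- range(object@voxels)
  if (is.finite(rng[1]) && (rng[1] < HU_MIN - 1e-6 || rng[2] > HU_MAX + 1e-6))
    msg <- c(msg, sprintf("voxel values must lie in [%d, %d] HU",
                          HU_MIN, HU_MAX))
  if (length(msg)) msg else TRUE
})

#' Construct a CT volume
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacingMm voxel spacing (x, y, z) in mm.
#' @param originMm physical origin in mm.
#' @param clamp clamp values into the representable HU window
#'   [-1024, 3071] (default TRUE).
#' @return A [CTVolume-class] object.
#' @export
ctVolume <- function(voxels, spacingMm, originMm = c(0, 0, 0),
                     clamp = TRUE) {
  v <- voxels
  if (clamp) v <- pmin(pmax(v, HU_MIN), HU_MAX)
  new("CTVolume", voxels = v, spacingMm = as.numeric(spacingMm),
      originMm = as.numeric(originMm))
}

#' ROIMask: a binary voxel mask on a CT volume grid
#'
#' @slot mask 3D logical array, same shape as the volume it refers to.
#' @slot source provenance of the mask: `"ground_truth"` (analytic
#'   occupancy from the renderer) or `"region_grow"` (segmentation).
#' @slot flags character vector of QC/warning flags (e.g.
#'   `"boundary_leak"` when a grown region touched the volume border).
#' @export
setClass("ROIMask",
  representation(mask = "array", source = "character", flags = "character")
)

setValidity("ROIMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3 || !is.logical(object@mask))
    msg <- c(msg, "mask must be a 3D logical array")
  if (length(object@source) != 1 ||
      !object@source %in% c("ground_truth", "region_grow"))
    msg <- c(msg, "source must be 'ground_truth' or 'region_grow'")
  if (length(msg)) msg else TRUE
})

#' Construct an ROI mask
#'
#' @param mask 3D logical array.
#' @param source `"ground_truth"` or `"region_grow"`.
#' @param flags optional character vector of QC flags.
#' @return An [ROIMask-class] object.
#' @export
roiMask <- function(mask, source = "ground_truth", flags = character()) {
  storage.mode(mask) <- "logical"
  new("ROIMask", mask = mask, source = source, flags = flags)
}

#' GrowCriterion: the voxel-inclusion rule for region growing
#'
#' In `"fixed_interval"` mode a voxel is accepted when its HU lies in
#' `[lowHu, highHu]`. In `"seed_adaptive"` mode the interval is
#' `[m - k s, m + k s]` where m and s are the mean and SD of the 3x3x3
#' neighbourhood of the seed, frozen before growth starts.
#'
#' @slot mode `"fixed_interval"` or `"seed_adaptive"`.
#' @slot lowHu,highHu the fixed inclusion interval in HU.
#' @slot adaptK the SD multiple k for the adaptive interval.
#' @export
setClass("GrowCriterion",
  representation(mode = "character", lowHu = "numeric", highHu = "numeric",
                 adaptK = "numeric")
)

setValidity("GrowCriterion", function(object) {
  msg <- character()
  if (!object@mode %in% c("fixed_interval", "seed_adaptive"))
    msg <- c(msg, "mode must be 'fixed_interval' or 'seed_adaptive'")
  if (object@mode == "fixed_interval" && !(object@lowHu < object@highHu))
    msg <- c(msg, "lowHu must be < highHu in fixed_interval mode")
  if (object@mode == "seed_adaptive" && object@adaptK <= 0)
    msg <- c(msg, "adaptK must be > 0 in seed_adaptive mode")
  if (length(msg)) msg else TRUE
})

#' Construct a region-growing criterion
#'
#' @param mode `"fixed_interval"` or `"seed_adaptive"`.
#' @param lowHu,highHu inclusion interval (fixed mode) in HU.
#' @param adaptK SD multiple (adaptive mode).
#' @return A [GrowCriterion-class] object.
#' @examples
#' growCriterion("fixed_interval", -200, 400)   # solid nodules
#' growCriterion("fixed_interval", -800, -400)  # ground-glass nodules
#' @export
growCriterion <- function(mode = c("fixed_interval", "seed_adaptive"),
                          lowHu = -Inf, highHu = Inf, adaptK = 2.5) {
  mode <- match.arg(mode)
  new("GrowCriterion", mode = mode, lowHu = as.numeric(lowHu),
      highHu = as.numeric(highHu), adaptK = as.numeric(adaptK))
}

#' StudyDesign: the full factorial scan plan
#'
#' Twelve protocols crossed with repeated scans; each (protocol,
#' repetition) entry carries a deterministically derived child seed so
#' any single scan is reproducible in isolation.
#'
#' @slot protocols data.frame of the 12 distinct protocols.
#' @slot scans data.frame with one row per scan: protocol columns,
#'   repetition index and child seed.
#' @slot repetitions number of repeat scans per protocol.
#' @slot relocationJitterMm amplitude (mm) of the uniform nodule
#'   relocation between repetitions.
#' @slot masterSeed the integer seed every child seed derives from.
#' @export
setClass("StudyDesign",
  representation(protocols = "data.frame", scans = "data.frame",
                 repetitions = "numeric", relocationJitterMm = "numeric",
                 masterSeed = "numeric")
)

#' QuantizedROI: gray-level quantized voxels of one ROI
#'
#' Holds the 256-level quantization of the masked voxels, cropped to the
#' bounding box of the mask. Voxels outside the mask are NA.
#'
#' @slot grayVolume 3D integer array on the mask bounding box; masked
#'   voxels carry gray levels in [0, 255], outside voxels are NA.
#' @slot nVoxels number of masked voxels.
#' @slot levels number of gray levels (always 256).
#' @export
setClass("QuantizedROI",
  representation(grayVolume = "array", nVoxels = "integer",
                 levels = "integer")
)

setValidity("QuantizedROI", function(object) {
  g <- object@grayVolume[!is.na(object@grayVolume)]
  msg <- character()
  if (length(g) != object@nVoxels)
    msg <- c(msg, "nVoxels must equal the number of non-NA voxels")
  if (length(g) && (min(g) < 0 || max(g) >= object@levels))
    msg <- c(msg, "gray levels must lie in [0, levels - 1]")
  if (length(msg)) msg else TRUE
})
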