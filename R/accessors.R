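## Accessor generics and show() methods.

#' @name accessors
#' @title Accessors for nodtex S4 objects
#' @description Slot accessors: use these rather than `@`.
#' @param object a nodtex S4 object.
#' @return The slot value; see the individual class pages.
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setMethod("voxelData", "CTVolume", function(object) object@voxels)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CTVolume", function(object) object@spacingMm)

#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(object) standardGeneric("voxelOrigin"))
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "CTVolume", function(object) object@originMm)

#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setMethod("maskArray", "ROIMask", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("voxelCount", function(object) standardGeneric("voxelCount"))
#' @rdname accessors
#' @export
setMethod("voxelCount", "ROIMask", function(object) sum(object@mask))
#' @rdname accessors
#' @export
setMethod("voxelCount", "QuantizedROI", function(object) object@nVoxels)

#' @rdname accessors
#' @export
setGeneric("maskSource", function(object) standardGeneric("maskSource"))
#' @rdname accessors
#' @export
setMethod("maskSource", "ROIMask", function(object) object@source)

#' @rdname accessors
#' @export
setGeneric("maskFlags", function(object) standardGeneric("maskFlags"))
#' @rdname accessors
#' @export
setMethod("maskFlags", "ROIMask", function(object) object@flags)

#' @rdname accessors
#' @export
setGeneric("thicknessMm", function(object) standardGeneric("thicknessMm"))
#' @rdname accessors
#' @export
setMethod("thicknessMm", "ScanProtocol", function(object) object@thicknessMm)

#' @rdname accessors
#' @export
setGeneric("tubeCurrentMas",
           function(object) standardGeneric("tubeCurrentMas"))
#' @rdname accessors
#' @export
setMethod("tubeCurrentMas", "ScanProtocol",
          function(object) object@tubeCurrentMas)

#' @rdname accessors
#' @export
setGeneric("reconKernel", function(object) standardGeneric("reconKernel"))
#' @rdname accessors
#' @export
setMethod("reconKernel", "ScanProtocol", function(object) object@reconKernel)

#' @rdname accessors
#' @export
setGeneric("grayVolume", function(object) standardGeneric("grayVolume"))
#' @rdname accessors
#' @export
setMethod("grayVolume", "QuantizedROI", function(object) object@grayVolume)

#' @rdname accessors
#' @export
setGeneric("grayValues", function(object) standardGeneric("grayValues"))
#' @rdname accessors
#' @export
setMethod("grayValues", "QuantizedROI", function(object)
  object@grayVolume[!is.na(object@grayVolume)])

#' @rdname accessors
#' @export
setGeneric("designScans", function(object) standardGeneric("designScans"))
#' @rdname accessors
#' @export
setMethod("designScans", "StudyDesign", function(object) object@scans)

#' @rdname accessors
#' @export
setGeneric("designProtocols",
           function(object) standardGeneric("designProtocols"))
#' @rdname accessors
#' @export
setMethod("designProtocols", "StudyDesign", function(object) object@protocols)

#' @rdname accessors
#' @export
setGeneric("sceneNodules", function(object) standardGeneric("sceneNodules"))
#' @rdname accessors
#' @export
setMethod("sceneNodules", "PhantomScene", function(object) object@nodules)

setMethod("show", "ScanProtocol", function(object) {
  cat(sprintf("ScanProtocol: %.2f mm / %g mAs / %s kernel\n",
              object@thicknessMm, object@tubeCurrentMas,
              object@reconKernel))
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], object@spacingMm[1], object@spacingMm[2],
              object@spacingMm[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(object@voxels),
              max(object@voxels)))
})

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask (%s): %d voxels of %s", object@source,
              sum(object@mask), paste(dim(object@mask), collapse = " x ")))
  if (length(object@flags))
    cat(sprintf("  [flags: %s]", paste(object@flags, collapse = ", ")))
  cat("\n")
})

setMethod("show", "PhantomScene", function(object) {
  cat(sprintf("PhantomScene: lung %g HU, FOV %s mm, %d nodule(s)\n",
              object@lungHu,
              paste(object@fieldOfViewMm, collapse = " x "),
              length(object@nodules)))
  for (nd in object@nodules)
    cat(sprintf("  %g mm @ %+g HU, centre (%s) mm\n", nd@diameterMm,
                nd@targetHu, paste(signif(nd@centerMm, 4), collapse = ", ")))
})

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf(
    "StudyDesign: %d protocols x %g repetition(s) = %d scans (seed %g)\n",
    nrow(object@protocols), object@repetitions, nrow(object@scans),
    object@masterSeed))
})

setMethod("show", "QuantizedROI", function(object) {
  cat(sprintf("QuantizedROI: %d voxels, %d gray levels\n",
              object@nVoxels, object@levels))
})
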