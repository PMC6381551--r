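## Volume/mask I/O: NIfTI with spacing metadata, via RNifti.

#' Write / read CT volumes and masks as NIfTI
#'
#' Volumes are stored HU-valued with the voxel spacing in the NIfTI
#' pixdim; masks as uint8 on the same grid.
#'
#' @param volume a [CTVolume-class].
#' @param mask an [ROIMask-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param source mask provenance to attach when reading
#'   (`"ground_truth"` or `"region_grow"`).
#' @return `writeVolume`/`writeMask` return the path invisibly;
#'   `readVolume` returns a [CTVolume-class], `readMask` an
#'   [ROIMask-class].
#' @name volume-io
NULL

#' @rdname volume-io
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(voxelData(volume))
  RNifti::pixdim(img) <- voxelSpacing(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname volume-io
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  ctVolume(array(as.vector(img), dim = dim(img)),
           spacingMm = RNifti::pixdim(img))
}

#' @rdname volume-io
#' @export
writeMask <- function(mask, path) {
  arr <- maskArray(mask) * 1L
  img <- RNifti::asNifti(arr)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname volume-io
#' @export
readMask <- function(path, source = "region_grow") {
  img <- RNifti::readNifti(path)
  roiMask(array(as.vector(img) > 0, dim = dim(img)), source = source)
}

#' Reference regression-coefficient tables of the phantom study
#'
#' The published per-feature regression coefficients (constant plus the
#' four dummy coefficients) for the solid (+100 HU) and ground-glass
#' (-630 HU) nodule strata, bundled as plain-text example data. Used as
#' worked-example inputs for the |RC| summaries; significance flags
#' (p <= 0.05) are carried in the `sig_*` columns.
#'
#' @param stratum `"100"` (solid) or `"-630"` (ground-glass).
#' @return A 20-row data.frame: `feature`, `constant`,
#'   `thickness_2.5`, `thickness_1.25`, `mas_120`, `kernel_standard`
#'   and the corresponding `sig_*` 0/1 columns.
#' @examples
#' rcSummary(publishedCoefficients("100")$thickness_2.5)
#' @export
publishedCoefficients <- function(stratum = c("100", "-630")) {
  stratum <- match.arg(stratum)
  fname <- if (stratum == "100") "reference_coefficients_solid_100hu.csv"
           else "reference_coefficients_groundglass_m630hu.csv"
  path <- system.file("extdata", fname, package = "nodtex",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
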