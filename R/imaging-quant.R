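# qEASL viable-tumor quantification: enhancement map, parenchymal
# threshold, supra-threshold segmentation within Seg1, and volume in cm^3.

#' Create a 3D scalar volume
#'
#' @param values 3D numeric array of intensities.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) physical offset in mm.
#' @return A [ScalarVolume3D-class] object.
#' @examples
#' v <- ScalarVolume3D(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
#' @export
ScalarVolume3D <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ScalarVolume3D", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a binary 3D mask
#'
#' @param values 3D array of 0/1 (logical arrays are coerced).
#' @param spacing numeric(3) voxel size in mm.
#' @return A [BinaryMask3D-class] object.
#' @export
BinaryMask3D <- function(values, spacing = c(1, 1, 1)) {
  v <- array(as.numeric(values), dim = dim(values))
  new("BinaryMask3D", values = v, spacing = as.numeric(spacing))
}

#' Create a reference point set
#'
#' @param points matrix (or data.frame) of 1-based voxel indices, one row
#'   per point, columns (i, j, k). At least 3 points are required.
#' @param neighborhoodRadius half-width, in voxels, of the cubic
#'   neighborhood averaged around each point; `0` samples the single voxel,
#'   the default `1` a 3x3x3 block.
#' @return A [ReferencePointSet-class] object.
#' @export
ReferencePointSet <- function(points, neighborhoodRadius = 1L) {
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  colnames(p) <- c("i", "j", "k")
  new("ReferencePointSet", points = p,
      neighborhoodRadius = as.integer(neighborhoodRadius))
}

.checkSameGrid <- function(a, b, what = "volumes") {
  if (!identical(dim(a@values), dim(b@values)))
    stop("dimension mismatch: ", what, " must share the same grid shape")
  if (any(abs(a@spacing - b@spacing) > 1e-8))
    stop("spacing mismatch: ", what, " must share the same voxel spacing")
  invisible(TRUE)
}

#' Subtract the unenhanced volume from the enhanced volume
#'
#' Removes the background signal by voxelwise subtraction, producing the
#' arterial enhancement map on which the parenchymal threshold and the
#' viable-tumor segmentation are defined. Values may be negative.
#'
#' @param enhanced,unenhanced co-registered [ScalarVolume3D-class] objects
#'   on the same grid.
#' @return A [ScalarVolume3D-class] enhancement map.
#' @export
setMethod("subtractBackground", signature("ScalarVolume3D", "ScalarVolume3D"),
  function(enhanced, unenhanced) {
    .checkSameGrid(enhanced, unenhanced, "enhanced/unenhanced volumes")
    new("ScalarVolume3D", values = enhanced@values - unenhanced@values,
        spacing = enhanced@spacing, origin = enhanced@origin)
  })

.checkRefs <- function(enhMap, refs) {
  d <- dim(enhMap@values)
  p <- refs@points
  if (nrow(p) < 3L) stop("at least 3 reference points are required")
  if (any(p < 1) || any(p[, 1] > d[1]) || any(p[, 2] > d[2]) ||
      any(p[, 3] > d[3]))
    stop("reference point out of volume bounds")
  invisible(TRUE)
}

#' Parenchymal enhancement threshold from reference points
#'
#' The threshold is the arithmetic mean of the enhancement values sampled
#' at each healthy-tissue reference point; each point's value is the mean
#' over its cubic neighborhood (clipped at the volume boundary), so that
#' radius 0 reproduces literal single-voxel sampling.
#'
#' @param enhMap [ScalarVolume3D-class] enhancement map (enhanced minus
#'   unenhanced).
#' @param refs [ReferencePointSet-class] of healthy-parenchyma points.
#' @return The threshold, a single number in the units of `enhMap`.
#' @export
setMethod("parenchymaThreshold", signature("ScalarVolume3D", "ReferencePointSet"),
  function(enhMap, refs) {
    .checkRefs(enhMap, refs)
    d <- dim(enhMap@values)
    r <- refs@neighborhoodRadius
    ptVals <- apply(refs@points, 1L, function(p) {
      ii <- max(1L, p[1] - r):min(d[1], p[1] + r)
      jj <- max(1L, p[2] - r):min(d[2], p[2] + r)
      kk <- max(1L, p[3] - r):min(d[3], p[3] + r)
      mean(enhMap@values[ii, jj, kk])
    })
    mean(ptVals)
  })

#' Segment viable tumor within Seg1
#'
#' Marks the voxels inside the whole-tumor segmentation whose enhancement
#' is strictly greater than the parenchymal threshold, yielding the
#' viable-tumor segmentation (Seg2).
#'
#' @param enhMap [ScalarVolume3D-class] enhancement map.
#' @param seg1 [BinaryMask3D-class] whole-tumor mask on the same grid.
#' @param threshold parenchymal enhancement threshold.
#' @return A [BinaryMask3D-class], a voxelwise subset of `seg1`.
#' @export
setMethod("segmentViable",
  signature("ScalarVolume3D", "BinaryMask3D", "numeric"),
  function(enhMap, seg1, threshold) {
    .checkSameGrid(enhMap, seg1, "enhancement map and Seg1")
    v <- (seg1@values == 1) & (enhMap@values > threshold)
    new("BinaryMask3D", values = array(as.numeric(v), dim = dim(v)),
        spacing = seg1@spacing)
  })

#' Volume of a binary mask in cm^3
#'
#' Voxel count times the physical voxel volume (product of spacings in
#' mm^3), converted to cm^3. Anisotropic spacing is supported.
#'
#' @param mask a [BinaryMask3D-class].
#' @return Volume in cm^3.
#' @export
setMethod("maskVolume", "BinaryMask3D", function(mask) {
  sum(mask@values) * prod(mask@spacing) / 1000
})

#' Quantify viable tumor volume (qEASL)
#'
#' Runs the full volumetric quantification: subtracts the unenhanced from
#' the enhanced volume, estimates the parenchymal enhancement threshold
#' from the reference points, segments the supra-threshold voxels within
#' Seg1, and measures the resulting viable tumor volume. Deterministic
#' given its inputs.
#'
#' @param enhanced,unenhanced co-registered [ScalarVolume3D-class] volumes.
#' @param seg1 [BinaryMask3D-class] whole-tumor segmentation.
#' @param refs [ReferencePointSet-class] healthy-parenchyma points.
#' @return A [ViableVolumeResult-class] with the threshold, the Seg2 mask
#'   and the viable tumor volume in cm^3.
#' @examples
#' ph <- generatePhantom(phantomSpec(dim = c(32, 32, 32), seed = 1L))
#' quantifyViableTumor(ph$enhanced, ph$unenhanced, ph$seg1, ph$refPoints)
#' @export
setMethod("quantifyViableTumor",
  signature("ScalarVolume3D", "ScalarVolume3D", "BinaryMask3D",
            "ReferencePointSet"),
  function(enhanced, unenhanced, seg1, refs) {
    enhMap <- subtractBackground(enhanced, unenhanced)
    thr <- parenchymaThreshold(enhMap, refs)
    s2 <- segmentViable(enhMap, seg1, thr)
    new("ViableVolumeResult", threshold = thr, seg2 = s2,
        vtvCm3 = maskVolume(s2))
  })

# ---- NIfTI and CSV interfaces ----

#' Read and write volumes and masks as NIfTI
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()].
#' Voxel spacing is taken from (and written to) the NIfTI header pixdims;
#' the origin from the translation part of the xform.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param volume a [ScalarVolume3D-class].
#' @param mask a [BinaryMask3D-class].
#' @return `readVolume()` a [ScalarVolume3D-class]; `readMask()` a
#'   [BinaryMask3D-class]; the writers return `path` invisibly.
#' @name nifti-io
NULL

#' @rdname nifti-io
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI volume: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  orig <- tryCatch(as.numeric(RNifti::xform(img)[1:3, 4]),
                   error = function(e) c(0, 0, 0))
  ScalarVolume3D(array(as.numeric(img), dim = dim(img)), spacing = sp,
                 origin = orig)
}

#' @rdname nifti-io
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@values)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti-io
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI mask: ", path)
  v <- array(as.numeric(img), dim = dim(img))
  if (!all(v %in% c(0, 1)))
    v <- array(as.numeric(v > 0.5), dim = dim(v))
  BinaryMask3D(v, spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname nifti-io
#' @export
writeMask <- function(mask, path) {
  img <- RNifti::asNifti(mask@values)
  RNifti::pixdim(img) <- mask@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read reference points from CSV
#'
#' The CSV holds 0-based integer voxel coordinates in columns `x`, `y`,
#' `z` (one row per point); they are converted to the package's 1-based
#' indexing.
#'
#' @param path CSV file path.
#' @param neighborhoodRadius passed to [ReferencePointSet()].
#' @return A [ReferencePointSet-class].
#' @export
readReferencePoints <- function(path, neighborhoodRadius = 1L) {
  tab <- read.csv(path)
  if (!all(c("x", "y", "z") %in% names(tab)))
    stop("reference point CSV needs columns x, y, z (0-based voxel indices)")
  ReferencePointSet(cbind(tab$x, tab$y, tab$z) + 1L,
                    neighborhoodRadius = neighborhoodRadius)
}
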