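#' @rdname subtractBackground
#' @export
setGeneric("subtractBackground",
           function(enhanced, unenhanced) standardGeneric("subtractBackground"))

#' @rdname parenchymaThreshold
#' @export
setGeneric("parenchymaThreshold",
           function(enhMap, refs) standardGeneric("parenchymaThreshold"))

#' @rdname segmentViable
#' @export
setGeneric("segmentViable",
           function(enhMap, seg1, threshold) standardGeneric("segmentViable"))

#' @rdname maskVolume
#' @export
setGeneric("maskVolume", function(mask) standardGeneric("maskVolume"))

#' @rdname quantifyViableTumor
#' @export
setGeneric("quantifyViableTumor",
           function(enhanced, unenhanced, seg1, refs)
             standardGeneric("quantifyViableTumor"))

#' @rdname hazardCurve
#' @export
setGeneric("hazardCurve",
           function(fit, vc = NULL, conf = TRUE) standardGeneric("hazardCurve"))

#' @rdname findUnitHrCrossing
#' @export
setGeneric("findUnitHrCrossing",
           function(fit, ...) standardGeneric("findUnitHrCrossing"))

#' @rdname linearPredictor
#' @export
setGeneric("linearPredictor",
           function(spec, patient) standardGeneric("linearPredictor"))

#' @rdname generatePhantom
#' @export
setGeneric("generatePhantom", function(spec) standardGeneric("generatePhantom"))

#' @rdname generateCohort
#' @export
setGeneric("generateCohort", function(spec) standardGeneric("generateCohort"))

# ---- accessors ----

#' Accessors for imaging and model objects
#'
#' Small accessor generics: `volumeData()` returns the raw 3D array of a
#' volume or mask, `voxelSpacing()` the per-axis voxel size in mm, `vtv()`
#' the viable tumor volume in cm^3, `seg2()` the viable-tumor mask,
#' `enhancementThreshold()` the parenchymal threshold, `cutoffPercent()`
#' the derived response cutoff, `splineKnots()` the spline knot locations,
#' and `modelTerms()` the coefficient table of a Cox model specification.
#'
#' @param x an object of the matching class.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("vtv", function(x) standardGeneric("vtv"))
#' @rdname accessors
#' @export
setGeneric("seg2", function(x) standardGeneric("seg2"))
#' @rdname accessors
#' @export
setGeneric("enhancementThreshold",
           function(x) standardGeneric("enhancementThreshold"))
#' @rdname accessors
#' @export
setGeneric("cutoffPercent", function(x) standardGeneric("cutoffPercent"))
#' @rdname accessors
#' @export
setGeneric("splineKnots", function(x) standardGeneric("splineKnots"))
#' @rdname accessors
#' @export
setGeneric("modelTerms", function(x) standardGeneric("modelTerms"))

setMethod("volumeData", "ScalarVolume3D", function(x) x@values)
setMethod("volumeData", "BinaryMask3D", function(x) x@values)
setMethod("voxelSpacing", "ScalarVolume3D", function(x) x@spacing)
setMethod("voxelSpacing", "BinaryMask3D", function(x) x@spacing)
setMethod("vtv", "ViableVolumeResult", function(x) x@vtvCm3)
setMethod("seg2", "ViableVolumeResult", function(x) x@seg2)
setMethod("enhancementThreshold", "ViableVolumeResult", function(x) x@threshold)
setMethod("cutoffPercent", "CutoffResult", function(x) x@cutoffPercent)
setMethod("splineKnots", "SplineHazardFit", function(x) x@knots)
setMethod("splineKnots", "CutoffResult", function(x) x@fit@knots)
setMethod("modelTerms", "CoxModelSpec", function(x) x@terms)

# ---- show methods ----

setMethod("show", "ScalarVolume3D", function(object) {
  d <- dim(object@values)
  cat("ScalarVolume3D:", paste(d, collapse = " x "), "voxels, spacing",
      paste(signif(object@spacing, 4), collapse = " x "), "mm\n")
  cat("  intensity range:",
      paste(signif(range(object@values), 5), collapse = " .. "), "\n")
})

setMethod("show", "BinaryMask3D", function(object) {
  d <- dim(object@values)
  cat("BinaryMask3D:", paste(d, collapse = " x "), "voxels,",
      sum(object@values), "foreground voxels\n")
})

setMethod("show", "ViableVolumeResult", function(object) {
  cat("ViableVolumeResult\n")
  cat("  enhancement threshold:", signif(object@threshold, 5), "\n")
  cat("  viable tumor volume  :", signif(object@vtvCm3, 5), "cm^3\n")
})

setMethod("show", "SplineHazardFit", function(object) {
  cat("SplineHazardFit (restricted cubic spline Cox model of VC)\n")
  cat("  knots     :", paste(signif(object@knots, 4), collapse = ", "), "\n")
  cat("  reference :", signif(object@referenceValue, 4),
      "% (HR = 1 comparator)\n")
  cat("  n used    :", object@nUsed, "\n")
})

setMethod("show", "CutoffResult", function(object) {
  cat("CutoffResult\n")
  cat("  cutoff: VC =", signif(object@cutoffPercent, 4), "% (HR = 1 crossing)\n")
  if (length(object@roots) > 1L)
    cat("  all crossings:", paste(signif(object@roots, 4), collapse = ", "), "\n")
  cat("  n used:", object@nUsed, "\n")
})

setMethod("show", "CoxModelSpec", function(object) {
  cat("CoxModelSpec (response marker:",
      if (nzchar(object@responseMarker)) object@responseMarker else "none",
      ")\n")
  print(object@terms, row.names = FALSE)
})
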