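#' @import methods
#' @importFrom stats median quantile qnorm pnorm pchisq rnorm runif rexp rbinom
#'   lm coef vcov sd uniroot binom.test mcnemar.test complete.cases setNames
#' @importFrom utils read.csv write.csv head
NULL

#' 3D scalar intensity volume
#'
#' A 3D grid of signal intensities (arbitrary units) with physical voxel
#' spacing, the container for arterial-phase enhanced and unenhanced images
#' and for the enhancement map obtained by subtracting them.
#'
#' @slot values 3D numeric array of intensities.
#' @slot spacing numeric(3), per-axis voxel size in mm (all > 0).
#' @slot origin numeric(3), physical offset of the first voxel in mm.
#' @export
setClass("ScalarVolume3D",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("ScalarVolume3D", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  else if (any(dim(object@values) < 1L))
    msg <- c(msg, "every axis must have length >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite values (mm)")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "all voxel values must be finite")
  if (length(msg)) msg else TRUE
})

#' Binary 3D mask
#'
#' A 3D array of 0/1 voxels sharing the grid of a companion
#' [ScalarVolume3D]. Houses the whole-tumor segmentation (Seg1) and the
#' viable-tumor segmentation (Seg2).
#'
#' @slot values 3D array with values in \{0, 1\}.
#' @slot spacing numeric(3), per-axis voxel size in mm.
#' @export
setClass("BinaryMask3D",
  representation(values = "array", spacing = "numeric"),
  prototype(spacing = c(1, 1, 1))
)

setValidity("BinaryMask3D", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (!all(object@values %in% c(0, 1)))
    msg <- c(msg, "mask values must be 0 or 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive finite values (mm)")
  if (length(msg)) msg else TRUE
})

#' Healthy-parenchyma reference points
#'
#' Voxel coordinates of points in surrounding healthy liver tissue used to
#' estimate the parenchymal enhancement threshold. Each point is sampled as
#' the mean over a cubic neighborhood of the configured radius (radius 0 =
#' the single voxel).
#'
#' @slot points integer matrix, one row per point, columns (i, j, k), 1-based
#'   voxel indices.
#' @slot neighborhoodRadius non-negative integer, half-width of the cubic
#'   sampling neighborhood in voxels.
#' @export
setClass("ReferencePointSet",
  representation(points = "matrix", neighborhoodRadius = "integer"),
  prototype(neighborhoodRadius = 1L)
)

setValidity("ReferencePointSet", function(object) {
  msg <- character()
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3L)
    msg <- c(msg, "'points' must be a numeric matrix with 3 columns")
  else {
    if (nrow(p) < 3L)
      msg <- c(msg, "at least 3 reference points are required")
    if (any(p != round(p)) || any(p < 1))
      msg <- c(msg, "points must be positive integer voxel indices (1-based)")
  }
  if (length(object@neighborhoodRadius) != 1L || object@neighborhoodRadius < 0L)
    msg <- c(msg, "'neighborhoodRadius' must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Result of viable-tumor quantification
#'
#' @slot threshold the parenchymal enhancement threshold, in the units of the
#'   enhancement map.
#' @slot seg2 [BinaryMask3D] of viable tumor (supra-threshold voxels within
#'   Seg1).
#' @slot vtvCm3 viable tumor volume in cm^3.
#' @export
setClass("ViableVolumeResult",
  representation(threshold = "numeric", seg2 = "BinaryMask3D",
                 vtvCm3 = "numeric")
)

setValidity("ViableVolumeResult", function(object) {
  if (length(object@vtvCm3) != 1L || object@vtvCm3 < 0)
    return("'vtvCm3' must be a single non-negative number")
  TRUE
})

#' Fitted spline hazard curve for volume change
#'
#' A Cox proportional-hazards fit of overall survival on a four-knot
#' restricted cubic spline basis of the percent viable-volume change (VC).
#' The log relative hazard is linear beyond the boundary knots; hazard
#' ratios are expressed against a reference VC value (default: the cohort
#' median), at which HR = 1 by construction.
#'
#' @slot knots numeric, strictly increasing knot locations on the VC scale.
#' @slot coefficients numeric, spline-basis coefficients of the log relative
#'   hazard (linear term first).
#' @slot referenceValue VC value against which hazard ratios are expressed.
#' @slot vcRange observed range of VC in the fitting data.
#' @slot fit the underlying [survival::coxph()] fit (or `NULL` for curves
#'   built directly from coefficients).
#' @slot nUsed number of records used in the fit.
#' @export
setClass("SplineHazardFit",
  representation(knots = "numeric", coefficients = "numeric",
                 referenceValue = "numeric", vcRange = "numeric",
                 fit = "ANY", nUsed = "integer")
)

setValidity("SplineHazardFit", function(object) {
  msg <- character()
  if (is.unsorted(object@knots, strictly = TRUE))
    msg <- c(msg, "'knots' must be strictly increasing")
  if (length(object@coefficients) != length(object@knots) - 1L)
    msg <- c(msg, "need k - 1 coefficients for k knots (linear + k - 2 nonlinear)")
  if (length(object@vcRange) != 2L || diff(object@vcRange) < 0)
    msg <- c(msg, "'vcRange' must be an increasing pair")
  if (length(msg)) msg else TRUE
})

#' Data-driven volumetric response cutoff
#'
#' @slot cutoffPercent VC value at which the fitted hazard ratio of death
#'   crosses 1; adopted as the mqEASL responder cutoff.
#' @slot roots all HR = 1 crossings found in the observed VC range.
#' @slot curve data.frame of curve samples: vc, hr, lower, upper.
#' @slot nUsed number of patients used (after new-lesion exclusion).
#' @slot fit the [SplineHazardFit] the cutoff was read from.
#' @export
setClass("CutoffResult",
  representation(cutoffPercent = "numeric", roots = "numeric",
                 curve = "data.frame", nUsed = "integer",
                 fit = "SplineHazardFit")
)

#' Cox model specification as a named linear predictor
#'
#' An ordered set of (covariate, coding, coefficient) terms defining a
#' linear predictor, e.g. the diameter-based (mRECIST) and volume-based
#' (mqEASL) prognostic models. `subsequent_treatment` is coded ordinal
#' 0-3 (none / locoregional / systemic / combined); all other covariates
#' are binary 0/1.
#'
#' @slot terms data.frame with columns `name`, `coding` ("binary" or
#'   "ordinal") and `coefficient`.
#' @slot responseMarker which responder definition the model uses:
#'   "mrecist" or "mqeasl" (or "" when not applicable).
#' @slot fit the underlying [survival::coxph()] fit, or `NULL` for models
#'   specified directly by their printed coefficients.
#' @export
setClass("CoxModelSpec",
  representation(terms = "data.frame", responseMarker = "character",
                 fit = "ANY")
)

setValidity("CoxModelSpec", function(object) {
  msg <- character()
  if (!all(c("name", "coding", "coefficient") %in% names(object@terms)))
    msg <- c(msg, "'terms' needs columns name, coding, coefficient")
  else {
    if (!all(object@terms$coding %in% c("binary", "ordinal")))
      msg <- c(msg, "coding must be 'binary' or 'ordinal'")
    if (any(!is.finite(object@terms$coefficient)))
      msg <- c(msg, "coefficients must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a 3D tumor phantom
#'
#' Defines a voxelized ellipsoid tumor inside homogeneous liver parenchyma.
#' A concentric inner ellipsoid is necrotic; the outer shell is viable, its
#' volume fraction set by `viableFraction`. Intensities are chosen so the
#' parenchymal enhancement threshold separates viable from necrotic tissue
#' by construction: viable enhancement > parenchyma enhancement > necrotic
#' enhancement.
#'
#' @slot dim integer(3), grid shape in voxels.
#' @slot spacing numeric(3), voxel size in mm.
#' @slot center numeric(3), ellipsoid center in mm (physical coordinates).
#' @slot semiAxes numeric(3), ellipsoid semi-axes in mm.
#' @slot viableFraction fraction of tumor volume that is viable, in [0, 1].
#' @slot parenchymaUnenhanced mean unenhanced intensity everywhere.
#' @slot parenchymaEnhancement mean arterial enhancement of healthy liver.
#' @slot viableEnhancement mean enhancement of viable tumor.
#' @slot necroticEnhancement mean enhancement of necrotic tumor.
#' @slot noiseSd Gaussian noise standard deviation added independently to
#'   each volume.
#' @slot seed RNG seed; the generator is a pure function of spec + seed.
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", spacing = "numeric", center = "numeric",
                 semiAxes = "numeric", viableFraction = "numeric",
                 parenchymaUnenhanced = "numeric",
                 parenchymaEnhancement = "numeric",
                 viableEnhancement = "numeric",
                 necroticEnhancement = "numeric",
                 noiseSd = "numeric", seed = "integer")
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@viableFraction < 0 || object@viableFraction > 1)
    msg <- c(msg, "'viableFraction' must lie in [0, 1]")
  if (!(object@viableEnhancement > object@parenchymaEnhancement &&
        object@parenchymaEnhancement > object@necroticEnhancement))
    msg <- c(msg, paste("need viableEnhancement > parenchymaEnhancement >",
                        "necroticEnhancement for a discriminative threshold"))
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic survival cohort
#'
#' Generates patient records on the cohort schema: baseline/follow-up
#' diameter sums and viable volumes, new-lesion and complete-disappearance
#' flags, binary metastasis and portal-vein-tumor-thrombus covariates, an
#' ordinal subsequent-treatment category, and right-censored overall
#' survival. Viable-volume change is tied to diameter change through the
#' empirical linear relation VC = a * EVC + b (EVC the cube-law expected
#' volume change) plus Gaussian noise, clipped at -100. The log hazard is
#' log h0 + bm*metastasis + bp*pvtt + bs*subsequent_treatment + g(VC), with
#' g either a linear ramp in VC (hazardModel "spline") or a responder-level
#' effect (hazardModel "responder"). The diameter-change distribution is
#' located so the cohort median of VC sits at `crossing`, which plants the
#' protective HR = 1 boundary there.
#'
#' @slot n number of patients.
#' @slot pMetastasis,pPvtt covariate prevalences.
#' @slot pSubsequent length-4 probabilities of subsequent-treatment
#'   categories 0-3.
#' @slot pNewLesion probability of new intrahepatic lesions at follow-up.
#' @slot pCompleteDisappearance probability of complete disappearance of
#'   target enhancement (forces DC = VC = -100).
#' @slot dBaselineMeanlog,dBaselineSdlog log-normal parameters of the
#'   baseline diameter sum (cm).
#' @slot dcSd standard deviation of the percent diameter change draw.
#' @slot vcSlope,vcIntercept,vcNoiseSd the VC = slope * EVC + intercept +
#'   N(0, sd) relation.
#' @slot crossing planted VC value (percent) of the HR = 1 boundary.
#' @slot hazardModel "spline" (hazard linear in VC) or "responder" (hazard
#'   depends on the volumetric responder label).
#' @slot betaMetastasis,betaPvtt,betaSubsequent covariate log-hazard
#'   effects.
#' @slot betaVc per-percent log-hazard slope of VC about the crossing
#'   (hazardModel "spline").
#' @slot betaResponder responder log-hazard effect (hazardModel
#'   "responder").
#' @slot baselineRates,baselineBreaks piecewise-constant baseline hazard:
#'   rates per month on intervals split at `baselineBreaks`.
#' @slot censorRate exponential censoring rate per month.
#' @slot followupMax administrative censoring horizon in months.
#' @slot seed RNG seed.
#' @export
setClass("CohortSpec",
  representation(n = "integer",
                 pMetastasis = "numeric", pPvtt = "numeric",
                 pSubsequent = "numeric", pNewLesion = "numeric",
                 pCompleteDisappearance = "numeric",
                 dBaselineMeanlog = "numeric", dBaselineSdlog = "numeric",
                 dcSd = "numeric",
                 vcSlope = "numeric", vcIntercept = "numeric",
                 vcNoiseSd = "numeric",
                 crossing = "numeric", hazardModel = "character",
                 betaMetastasis = "numeric", betaPvtt = "numeric",
                 betaSubsequent = "numeric", betaVc = "numeric",
                 betaResponder = "numeric",
                 baselineRates = "numeric", baselineBreaks = "numeric",
                 censorRate = "numeric", followupMax = "numeric",
                 seed = "integer")
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  probs <- c(object@pMetastasis, object@pPvtt, object@pNewLesion,
             object@pCompleteDisappearance, object@pSubsequent)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  if (abs(sum(object@pSubsequent) - 1) > 1e-8)
    msg <- c(msg, "'pSubsequent' must sum to 1")
  if (object@n < 1L) msg <- c(msg, "'n' must be >= 1")
  if (!object@hazardModel %in% c("spline", "responder"))
    msg <- c(msg, "'hazardModel' must be 'spline' or 'responder'")
  if (object@crossing >= 0 || object@crossing <= -100)
    msg <- c(msg, "'crossing' must lie in (-100, 0)")
  if (any(object@baselineRates <= 0))
    msg <- c(msg, "'baselineRates' must be positive")
  if (length(object@baselineRates) != length(object@baselineBreaks) + 1L)
    msg <- c(msg, "need one more baseline rate than breakpoints")
  if (length(msg)) msg else TRUE
})
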