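# Generators: 3D tumor phantoms with known viable volume, and survival
# cohorts with known covariate effects and a planted protective HR = 1
# boundary on the volume-change scale. Both are pure functions of their
# spec + seed.

#' Construct a phantom specification
#'
#' Defaults model a roughly 3 cm lesion on an isotropic 1 mm grid inside
#' homogeneous parenchyma, with intensities (arbitrary units) chosen so
#' the parenchymal enhancement threshold cleanly separates viable shell
#' from necrotic core: parenchyma enhances by 80, viable tumor by 120,
#' necrosis by 10.
#'
#' @param dim grid shape in voxels (default 48^3).
#' @param spacing voxel size in mm.
#' @param center ellipsoid center in mm; default the grid center.
#' @param semiAxes ellipsoid semi-axes in mm.
#' @param viableFraction viable (outer-shell) fraction of tumor volume.
#' @param parenchymaUnenhanced,parenchymaEnhancement,viableEnhancement,necroticEnhancement
#'   intensity means (see [PhantomSpec-class]).
#' @param noiseSd Gaussian noise sd added to each volume.
#' @param seed RNG seed.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(48L, 48L, 48L), spacing = c(1, 1, 1),
                        center = NULL, semiAxes = c(16, 13, 11),
                        viableFraction = 0.6,
                        parenchymaUnenhanced = 100,
                        parenchymaEnhancement = 80,
                        viableEnhancement = 120,
                        necroticEnhancement = 10,
                        noiseSd = 0, seed = 1L) {
  dim <- as.integer(dim)
  if (is.null(center)) center <- (dim - 1) / 2 * spacing
  new("PhantomSpec", dim = dim, spacing = as.numeric(spacing),
      center = as.numeric(center), semiAxes = as.numeric(semiAxes),
      viableFraction = viableFraction,
      parenchymaUnenhanced = parenchymaUnenhanced,
      parenchymaEnhancement = parenchymaEnhancement,
      viableEnhancement = viableEnhancement,
      necroticEnhancement = necroticEnhancement,
      noiseSd = noiseSd, seed = as.integer(seed))
}

# voxel-center physical coordinates along one axis
.axisCoords <- function(n, sp) (seq_len(n) - 1) * sp

#' Generate a 3D tumor phantom
#'
#' Voxelizes the tumor ellipsoid (Seg1 ground truth) and a concentric
#' inner ellipsoid scaled by `(1 - viableFraction)^(1/3)` so the necrotic
#' core occupies the stated volume fraction; the remaining shell is
#' viable. Builds unenhanced and arterial-phase enhanced volumes from the
#' spec intensities, adds independent Gaussian noise to each, and returns
#' the construction truth alongside, including three healthy-parenchyma
#' reference points placed away from the tumor.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list: `enhanced`, `unenhanced` ([ScalarVolume3D-class]),
#'   `seg1`, `viableMask` ([BinaryMask3D-class]), `trueVtvCm3`,
#'   `refPoints` ([ReferencePointSet-class]), and `spec`.
#' @export
setMethod("generatePhantom", "PhantomSpec", function(spec) {
  d <- spec@dim; sp <- spec@spacing
  ext <- (d - 1) * sp
  if (any(spec@center - spec@semiAxes < 0) ||
      any(spec@center + spec@semiAxes > ext))
    stop("tumor ellipsoid does not fit inside the grid")
  cx <- .axisCoords(d[1], sp[1]); cy <- .axisCoords(d[2], sp[2])
  cz <- .axisCoords(d[3], sp[3])
  X <- array(rep(cx, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(cz, each = d[1] * d[2]), dim = d)
  q <- ((X - spec@center[1]) / spec@semiAxes[1])^2 +
       ((Y - spec@center[2]) / spec@semiAxes[2])^2 +
       ((Z - spec@center[3]) / spec@semiAxes[3])^2
  seg1 <- q <= 1
  s <- (1 - spec@viableFraction)^(1 / 3)
  core <- if (s > 0) q <= s^2 else array(FALSE, dim = d)
  viable <- seg1 & !core
  enhancement <- array(spec@parenchymaEnhancement, dim = d)
  enhancement[core] <- spec@necroticEnhancement
  enhancement[viable] <- spec@viableEnhancement
  unenh <- array(spec@parenchymaUnenhanced, dim = d)
  noise <- withSeed(spec@seed, list(
    u = array(rnorm(prod(d), 0, spec@noiseSd), dim = d),
    e = array(rnorm(prod(d), 0, spec@noiseSd), dim = d)))
  if (spec@noiseSd == 0) noise <- list(u = 0, e = 0)
  unenhanced <- ScalarVolume3D(unenh + noise$u, spacing = sp)
  enhanced <- ScalarVolume3D(unenh + enhancement + noise$e, spacing = sp)
  # three reference points in parenchyma near opposite corners
  margin <- 3L
  pts <- rbind(c(margin, margin, margin),
               c(d[1] - margin, margin, d[3] - margin),
               c(margin, d[2] - margin, d[3] - margin))
  refs <- ReferencePointSet(pts, neighborhoodRadius = 1L)
  list(enhanced = enhanced, unenhanced = unenhanced,
       seg1 = BinaryMask3D(seg1, spacing = sp),
       viableMask = BinaryMask3D(viable, spacing = sp),
       trueVtvCm3 = sum(viable) * prod(sp) / 1000,
       refPoints = refs, spec = spec)
})

#' Construct a cohort specification
#'
#' Defaults emulate the study conditions: covariate prevalences from the
#' pooled baseline table (metastasis 0.20, PVTT 0.18, subsequent
#' treatment 52/29/9/9%), a complete-disappearance (CR) probability of
#' 0.18 and a new-lesion probability of 0.12; viable-volume change tied
#' to diameter change through VC = 1.88 x EVC + 69.75 plus N(0, 50)
#' noise — a residual scale consistent with the worked single-patient
#' example, where cube-law expectation and measured volume change
#' disagree by ~40 points, and yielding only moderate mRECIST/mqEASL
#' agreement as observed clinically; proportional-hazards survival with
#' Model-2-scale covariate
#' effects, an exponential baseline with median 20 months, exponential
#' censoring plus an administrative horizon giving roughly 18% censoring.
#' The diameter-change distribution is located so the cohort median VC —
#' and hence the planted protective HR = 1 boundary — sits at `crossing`.
#'
#' @param n cohort size.
#' @param crossing planted HR = 1 crossing on the VC scale (default -57).
#' @param hazardModel `"spline"` (log hazard linear in VC about the
#'   crossing) or `"responder"` (log hazard shifts with the volumetric
#'   responder label).
#' @param betaMetastasis,betaPvtt,betaSubsequent,betaVc,betaResponder
#'   log-hazard effects.
#' @param pMetastasis,pPvtt,pSubsequent,pNewLesion,pCompleteDisappearance
#'   prevalences.
#' @param dBaselineMeanlog,dBaselineSdlog,dcSd diameter distributions.
#' @param vcSlope,vcIntercept,vcNoiseSd the EVC-to-VC relation.
#' @param baselineRates,baselineBreaks piecewise-constant baseline hazard.
#' @param censorRate,followupMax censoring model.
#' @param seed RNG seed.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(n = 500L, crossing = -57, hazardModel = "spline",
                       betaMetastasis = 1.88, betaPvtt = 0.92,
                       betaSubsequent = -0.36, betaVc = 0.02,
                       betaResponder = -1.41,
                       pMetastasis = 0.20, pPvtt = 0.18,
                       pSubsequent = c(0.52, 0.295, 0.0925, 0.0925),
                       pNewLesion = 0.12, pCompleteDisappearance = 0.18,
                       dBaselineMeanlog = log(7), dBaselineSdlog = 0.45,
                       dcSd = 25,
                       vcSlope = 1.88, vcIntercept = 69.75, vcNoiseSd = 50,
                       baselineRates = log(2) / 20, baselineBreaks = numeric(),
                       censorRate = 0.006, followupMax = 96,
                       seed = 1L) {
  new("CohortSpec", n = as.integer(n), pMetastasis = pMetastasis,
      pPvtt = pPvtt, pSubsequent = pSubsequent, pNewLesion = pNewLesion,
      pCompleteDisappearance = pCompleteDisappearance,
      dBaselineMeanlog = dBaselineMeanlog, dBaselineSdlog = dBaselineSdlog,
      dcSd = dcSd, vcSlope = vcSlope, vcIntercept = vcIntercept,
      vcNoiseSd = vcNoiseSd, crossing = crossing, hazardModel = hazardModel,
      betaMetastasis = betaMetastasis, betaPvtt = betaPvtt,
      betaSubsequent = betaSubsequent, betaVc = betaVc,
      betaResponder = betaResponder, baselineRates = baselineRates,
      baselineBreaks = baselineBreaks, censorRate = censorRate,
      followupMax = followupMax, seed = as.integer(seed))
}

# Diameter-change location that puts the population median VC at the
# planted crossing. The median of VC = a*EVC(DC) + b + noise is not the
# transform of the median DC (EVC is convex and the -100 clip is
# one-sided), so the location is solved numerically from
#   P(VC <= crossing) = pCR + (1 - pCR) * E_DC[ Phi((c - m(DC)) / sigma) ]
# with m(DC) = a*EVC(clip(DC)) + b, DC ~ N(mu, sd), which is exact up to
# quadrature error and independent of the RNG.
.dcLocation <- function(spec) {
  cTarget <- spec@crossing
  sigma <- spec@vcNoiseSd
  pBelow <- function(mu) {
    z <- seq(-8, 8, length.out = 801)
    x <- pmin(pmax(mu + spec@dcSd * z, -100), 100)
    m <- spec@vcSlope * expectedVolumeChange(x) + spec@vcIntercept
    pv <- if (sigma > 0) pnorm((cTarget - m) / sigma)
          else as.numeric(m <= cTarget)
    w <- stats::dnorm(z)
    cont <- sum(w * pv) / sum(w)
    spec@pCompleteDisappearance +
      (1 - spec@pCompleteDisappearance) * cont
  }
  uniroot(function(mu) pBelow(mu) - 0.5, c(-90, 30), tol = 1e-6)$root
}

# Inverse-transform event times under a piecewise-constant baseline
# hazard scaled by exp(lp): solve H0(T) * exp(lp) = E, E ~ Exp(1).
.sampleEventTimes <- function(e, lp, rates, breaks) {
  target <- e / exp(lp)  # required baseline cumulative hazard
  bounds <- c(0, breaks, Inf)
  cumH <- c(0, cumsum(rates[seq_along(breaks)] * diff(c(0, breaks))))
  out <- numeric(length(target))
  for (i in seq_along(target)) {
    seg <- findInterval(target[i], cumH)
    out[i] <- bounds[seg] + (target[i] - cumH[seg]) / rates[seg]
  }
  out
}

#' Generate a synthetic survival cohort
#'
#' Draws covariates, diameter and volume measurements, responder-defining
#' changes, and right-censored survival times from a
#' proportional-hazards model, per the [cohortSpec()] construction.
#' Complete disappearance forces DC = VC = -100; VC is clipped at -100.
#'
#' @param spec a [CohortSpec-class].
#' @return A list with `cohort` (data.frame on the cohort CSV schema) and
#'   `truth` (planted crossing, true responder labels, true linear
#'   predictor, censoring fraction and hazard description).
#' @export
setMethod("generateCohort", "CohortSpec", function(spec) {
  withSeed(spec@seed, {
    n <- spec@n
    met <- rbinom(n, 1, spec@pMetastasis)
    pvtt <- rbinom(n, 1, spec@pPvtt)
    subs <- sample(0:3, n, replace = TRUE, prob = spec@pSubsequent)
    newLes <- rbinom(n, 1, spec@pNewLesion)
    cr <- rbinom(n, 1, spec@pCompleteDisappearance)
    cr[newLes == 1] <- 0L  # new lesions preclude complete response
    dBl <- exp(rnorm(n, spec@dBaselineMeanlog, spec@dBaselineSdlog))
    dc <- rnorm(n, .dcLocation(spec), spec@dcSd)
    dc <- pmin(pmax(dc, -100), 100)
    evc <- expectedVolumeChange(dc)
    vc <- spec@vcSlope * evc + spec@vcIntercept + rnorm(n, 0, spec@vcNoiseSd)
    vc <- pmax(vc, -100)
    dc[cr == 1] <- -100; vc[cr == 1] <- -100
    dUp <- dBl * (1 + dc / 100)
    vtvBl <- pi / 6 * dBl^3 * exp(rnorm(n, 0, 0.2))
    vtvUp <- vtvBl * (1 + vc / 100)
    responder <- as.integer(vc <= spec@crossing & newLes == 0)
    lp <- spec@betaMetastasis * met + spec@betaPvtt * pvtt +
      spec@betaSubsequent * subs +
      if (spec@hazardModel == "spline") spec@betaVc * (vc - spec@crossing)
      else spec@betaResponder * responder
    tEvent <- .sampleEventTimes(rexp(n), lp, spec@baselineRates,
                                spec@baselineBreaks)
    tCens <- pmin(rexp(n, spec@censorRate), spec@followupMax)
    time <- pmax(pmin(tEvent, tCens), 1e-3)
    event <- as.integer(tEvent <= tCens)
    cohort <- data.frame(
      id = seq_len(n),
      d_bl_cm = dBl, d_up_cm = dUp,
      vtv_bl_cm3 = vtvBl, vtv_up_cm3 = vtvUp,
      new_lesion = newLes, complete_disappearance = cr,
      metastasis = met, pvtt = pvtt, subsequent_treatment = subs,
      time_months = time, event = event)
    truth <- list(crossing = spec@crossing,
                  responder = responder,
                  vcPercent = vc, dcPercent = dc,
                  linearPredictor = lp,
                  censoredFraction = mean(1 - event),
                  hazardModel = spec@hazardModel)
    list(cohort = cohort, truth = truth)
  })
})

#' Generate paired diameter/volume measurements
#'
#' Baseline and follow-up diameter sums and viable volumes consistent
#' with the generator's diameter-change draw and the VC = a x EVC + b
#' relation, for exercising the EVC-VC regression and the agreement
#' statistics in isolation (no survival component).
#'
#' @param spec a [CohortSpec-class] (its measurement-model fields are
#'   used).
#' @param n number of pairs (>= 3); default `spec@n`.
#' @return data.frame with columns `d_bl`, `d_up`, `vtv_bl`, `vtv_up`.
#' @export
generatePairedMeasurements <- function(spec, n = NULL) {
  if (is.null(n)) n <- spec@n
  if (n < 3L) stop("need n >= 3 pairs")
  withSeed(spec@seed + 1L, {
    dBl <- exp(rnorm(n, spec@dBaselineMeanlog, spec@dBaselineSdlog))
    dc <- pmin(pmax(rnorm(n, .dcLocation(spec), spec@dcSd), -100), 100)
    evc <- expectedVolumeChange(dc)
    vc <- pmax(spec@vcSlope * evc + spec@vcIntercept +
                 rnorm(n, 0, spec@vcNoiseSd), -100)
    vtvBl <- pi / 6 * dBl^3 * exp(rnorm(n, 0, 0.2))
    data.frame(d_bl = dBl, d_up = dBl * (1 + dc / 100),
               vtv_bl = vtvBl, vtv_up = vtvBl * (1 + vc / 100))
  })
}
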