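# Data-driven volumetric response cutoff: a four-knot restricted cubic
# spline Cox model of the VC-hazard relation, and the VC value at which
# the hazard ratio of death (against a reference VC) equals 1.

#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline basis in the truncated-power form:
#' the identity plus k - 2 nonlinear terms constructed so the function is
#' linear beyond the boundary knots, with the conventional normalization
#' by the squared spread of the outer knots. For knots t1 < ... < tk the
#' j-th nonlinear term is
#' \deqn{[(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'       + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2.}
#'
#' @param x numeric values at which to evaluate the basis.
#' @param knots strictly increasing knot locations (>= 3).
#' @return Matrix with `length(knots) - 1` columns: the linear term then
#'   the nonlinear terms.
#' @export
rcsBasis <- function(x, knots) {
  if (length(knots) < 3L || is.unsorted(knots, strictly = TRUE))
    stop("'knots' must be >= 3 strictly increasing values")
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]
  norm <- (knots[k] - knots[1])^2
  cube <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (cube(x - tj) -
                      cube(x - tk1) * (tk - tj) / (tk - tk1) +
                      cube(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("lin", paste0("nl", seq_len(k - 2L)))
  out
}

#' Default knot locations for the VC spline
#'
#' Empirical quantiles 0.05, 0.35, 0.65, 0.95 of the observed VC values,
#' the conventional placement for a four-knot restricted cubic spline.
#'
#' @param vcValues observed percent volume changes (>= 20 distinct
#'   values).
#' @param probs quantile positions (default the four-knot convention).
#' @return Numeric knot locations.
#' @export
defaultKnots <- function(vcValues, probs = c(0.05, 0.35, 0.65, 0.95)) {
  vcValues <- vcValues[is.finite(vcValues)]
  if (length(unique(vcValues)) < 20L)
    stop("need >= 20 distinct VC values to place knots")
  kn <- unname(quantile(vcValues, probs))
  if (is.unsorted(kn, strictly = TRUE)) kn <- unique(kn)
  if (length(kn) < 3L)
    stop("VC distribution too degenerate for knot placement")
  kn
}

#' Fit the VC-hazard restricted cubic spline Cox model
#'
#' Cox proportional-hazards fit (Efron tie handling) of overall survival
#' on the restricted-cubic-spline basis of percent viable-volume change,
#' the spline terms being the only covariates. Patients with new lesions
#' are excluded (they are graded non-responders downstream but do not
#' inform the cutoff). The hazard-ratio reference is the median VC of the
#' records used, so HR(reference) = 1 by construction.
#'
#' @param records data.frame with columns `vc_percent`, `time_months`,
#'   `event`, and optionally `new_lesion` (rows with `new_lesion == 1`
#'   are dropped).
#' @param knots knot locations; default [defaultKnots()] of the retained
#'   VC values.
#' @param referenceValue VC value at which HR = 1; default the median VC.
#' @return A [SplineHazardFit-class].
#' @export
fitVcHazardSpline <- function(records, knots = NULL, referenceValue = NULL) {
  need <- c("vc_percent", "time_months", "event")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "))
  if ("new_lesion" %in% names(records))
    records <- records[records$new_lesion != 1, , drop = FALSE]
  if (any(records$time_months <= 0)) stop("survival times must be > 0")
  if (sum(records$event) < 1L) stop("no events: cannot fit a hazard model")
  vc <- records$vc_percent
  if (is.null(knots)) knots <- defaultKnots(vc)
  if (is.null(referenceValue)) referenceValue <- median(vc)
  X <- rcsBasis(vc, knots)
  fit <- survival::coxph(
    survival::Surv(records$time_months, records$event) ~ X,
    ties = "efron")
  if (any(!is.finite(coef(fit))))
    stop("spline Cox fit did not converge to finite coefficients")
  new("SplineHazardFit", knots = knots,
      coefficients = unname(coef(fit)),
      referenceValue = referenceValue,
      vcRange = range(vc), fit = fit, nUsed = nrow(records))
}

#' Build a spline hazard curve directly from coefficients
#'
#' Mainly for constructing known curves in simulations and tests; no
#' confidence intervals are available without an underlying fit.
#'
#' @param knots strictly increasing knot locations.
#' @param coefficients basis coefficients (linear term first, length
#'   `length(knots) - 1`).
#' @param referenceValue HR = 1 comparator on the VC scale.
#' @param vcRange range over which the curve is considered observed.
#' @return A [SplineHazardFit-class] with an empty `fit` slot.
#' @export
splineHazardFit <- function(knots, coefficients, referenceValue, vcRange) {
  new("SplineHazardFit", knots = as.numeric(knots),
      coefficients = as.numeric(coefficients),
      referenceValue = as.numeric(referenceValue),
      vcRange = as.numeric(vcRange), fit = NULL, nUsed = 0L)
}

.logHr <- function(fit, x) {
  b <- rcsBasis(x, fit@knots)
  bref <- rcsBasis(fit@referenceValue, fit@knots)
  drop((b - matrix(bref, nrow(b), ncol(b), byrow = TRUE)) %*%
         fit@coefficients)
}

#' Sample the fitted hazard-ratio curve
#'
#' Hazard ratio of death relative to the reference VC, with pointwise 95%
#' confidence intervals (delta method on the linear predictor contrast)
#' when an underlying Cox fit is available.
#'
#' @param fit a [SplineHazardFit-class].
#' @param vc grid of VC values; default a 0.5-point grid over the
#'   observed range.
#' @param conf logical, compute confidence intervals.
#' @return data.frame with columns `vc`, `hr`, and when available
#'   `lower`, `upper`.
#' @export
setMethod("hazardCurve", "SplineHazardFit", function(fit, vc = NULL,
                                                     conf = TRUE) {
  if (is.null(vc))
    vc <- seq(fit@vcRange[1], fit@vcRange[2], by = 0.5)
  lhr <- .logHr(fit, vc)
  out <- data.frame(vc = vc, hr = exp(lhr))
  if (conf && !is.null(fit@fit)) {
    b <- rcsBasis(vc, fit@knots)
    bref <- rcsBasis(fit@referenceValue, fit@knots)
    d <- b - matrix(bref, nrow(b), ncol(b), byrow = TRUE)
    se <- sqrt(pmax(0, rowSums((d %*% vcov(fit@fit)) * d)))
    out$lower <- exp(lhr - qnorm(0.975) * se)
    out$upper <- exp(lhr + qnorm(0.975) * se)
  }
  out
})

#' Locate the HR = 1 crossing of a fitted hazard curve
#'
#' Samples the log hazard-ratio curve on a fine grid over the observed VC
#' range, brackets every sign change and polishes each root with
#' [stats::uniroot()] (tolerance 1e-3 percentage points). The VC value at
#' which the hazard ratio of death equals 1 is adopted as the volumetric
#' response cutoff. When several crossings exist, the one on the
#' protective boundary — where the hazard rises steepest as the volume
#' reduction shrinks — is selected; all roots are reported.
#'
#' @param fit a [SplineHazardFit-class].
#' @param gridBy sampling step of the bracketing grid (default 0.5).
#' @param tol root tolerance in percentage points (default 1e-3).
#' @param ... unused.
#' @return A [CutoffResult-class].
#' @export
setMethod("findUnitHrCrossing", "SplineHazardFit",
  function(fit, gridBy = 0.5, tol = 1e-3, ...) {
    lo <- fit@vcRange[1]; hi <- fit@vcRange[2]
    grid <- seq(lo, hi, by = gridBy)
    if (grid[length(grid)] < hi) grid <- c(grid, hi)
    y <- .logHr(fit, grid)
    roots <- numeric()
    exact <- abs(y) < .Machine$double.eps * 100
    roots <- c(roots, grid[exact])
    sgn <- sign(y)
    for (i in seq_len(length(grid) - 1L)) {
      if (sgn[i] != 0 && sgn[i + 1] != 0 && sgn[i] != sgn[i + 1]) {
        r <- uniroot(function(x) .logHr(fit, x), c(grid[i], grid[i + 1]),
                     tol = tol)$root
        roots <- c(roots, r)
      }
    }
    roots <- sort(unique(round(roots / tol) * tol))
    if (!length(roots)) {
      curve <- hazardCurve(fit)
      cond <- structure(
        class = c("noCrossingError", "error", "condition"),
        list(message = paste("the fitted hazard-ratio curve does not cross 1",
                             "within the observed VC range"),
             call = sys.call(-1), curve = curve))
      stop(cond)
    }
    # protective boundary: hazard increasing in VC; prefer the steepest rise
    slope <- vapply(roots, function(r) {
      h <- max(gridBy / 10, tol)
      (.logHr(fit, min(hi, r + h)) - .logHr(fit, max(lo, r - h))) /
        (min(hi, r + h) - max(lo, r - h))
    }, numeric(1))
    rising <- which(slope > 0)
    pick <- if (length(rising)) rising[which.max(slope[rising])]
            else which.max(abs(slope))
    new("CutoffResult", cutoffPercent = roots[pick], roots = roots,
        curve = hazardCurve(fit), nUsed = fit@nUsed, fit = fit)
  })

#' Derive the volumetric response cutoff from a cohort
#'
#' End-to-end cutoff derivation: excludes patients with new lesions, fits
#' the four-knot restricted cubic spline Cox model of VC against the
#' hazard of death, and returns the VC value at which the hazard ratio
#' (relative to the cohort median VC) crosses 1.
#'
#' @inheritParams fitVcHazardSpline
#' @param gridBy,tol passed to [findUnitHrCrossing()].
#' @return A [CutoffResult-class].
#' @examples
#' coh <- generateCohort(cohortSpec(n = 400L, seed = 7L))$cohort
#' coh <- assessCohort(coh)
#' cutoffPercent(deriveCutoff(coh))
#' @export
deriveCutoff <- function(records, knots = NULL, referenceValue = NULL,
                         gridBy = 0.5, tol = 1e-3) {
  fit <- fitVcHazardSpline(records, knots = knots,
                           referenceValue = referenceValue)
  findUnitHrCrossing(fit, gridBy = gridBy, tol = tol)
}

#' Export a cutoff derivation as plain-text reports
#'
#' Writes a JSON report (knots, coefficients, reference, roots, chosen
#' cutoff, n used) and a CSV of hazard-curve samples for plotting.
#'
#' @param result a [CutoffResult-class].
#' @param jsonPath,curveCsvPath output paths (`NULL` to skip one).
#' @return Invisibly, the report list.
#' @export
writeCutoffReport <- function(result, jsonPath = NULL, curveCsvPath = NULL) {
  rep <- list(
    cutoff_percent = result@cutoffPercent,
    roots = result@roots,
    knots = result@fit@knots,
    coefficients = result@fit@coefficients,
    reference_value = result@fit@referenceValue,
    n_used = result@nUsed)
  if (!is.null(jsonPath))
    jsonlite::write_json(rep, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(curveCsvPath))
    write.csv(result@curve, curveCsvPath, row.names = FALSE)
  invisible(rep)
}
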