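# Diameter/volume change quantities, mRECIST and mqEASL classification,
# inter-criteria agreement, and the EVC-VC empirical relation.
#
# All change quantities are expressed in percent on [-100, Inf); fractions
# are never passed across the API, to avoid unit bugs.

#' Percent change from baseline
#'
#' `(followup - baseline) / baseline * 100`, applied identically to the
#' sum of viable-tumor diameters (DC) and to the viable tumor volume (VC).
#'
#' @param baseline positive baseline measurement.
#' @param followup non-negative follow-up measurement (same units).
#' @return Percent change (vectorized), always >= -100 for non-negative
#'   follow-up values.
#' @examples
#' percentChange(494.2, 292.5)  # -40.8% viable volume reduction
#' percentChange(11.5, 6.7)     # -41.7% diameter reduction
#' @export
percentChange <- function(baseline, followup) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("percent change is undefined for baseline <= 0")
  if (any(!is.finite(followup)) || any(followup < 0))
    stop("follow-up measurement must be non-negative")
  (followup - baseline) / baseline * 100
}

#' Expected volume change from a diameter change (cube law)
#'
#' For a sphere shrinking symmetrically, a relative diameter change of
#' `dc` percent implies a volume change of `((1 + dc/100)^3 - 1) * 100`
#' percent. A 30% diameter decrease maps to a 65.7% volume decrease,
#' which is the origin of the legacy 65% volumetric responder cutoff.
#'
#' @param dcPercent percent diameter change, >= -100 (vectorized).
#' @return Expected percent volume change (EVC).
#' @examples
#' expectedVolumeChange(-30)  # -65.7
#' @export
expectedVolumeChange <- function(dcPercent) {
  if (any(!is.finite(dcPercent)) || any(dcPercent < -100))
    stop("diameter change must be >= -100 percent")
  ((1 + dcPercent / 100)^3 - 1) * 100
}

#' Classify response under mRECIST
#'
#' One-dimensional response grading on the sum of the largest viable-tumor
#' diameters: complete response (CR) when all target enhancement has
#' disappeared, partial response (PR) at a >= 30% diameter decrease,
#' progressive disease (PD) at a >= 20% increase or on new intrahepatic
#' lesions, stable disease (SD) otherwise. New lesions take precedence
#' over CR; responders are CR and PR.
#'
#' @param dcPercent percent diameter change (vectorized).
#' @param newLesion logical, new intrahepatic lesion at follow-up.
#' @param completeDisappearance logical, no residual target enhancement.
#' @return Factor with levels CR, PR, SD, PD.
#' @export
classifyMRECIST <- function(dcPercent, newLesion = FALSE,
                            completeDisappearance = FALSE) {
  n <- max(length(dcPercent), length(newLesion), length(completeDisappearance))
  dcPercent <- rep_len(dcPercent, n)
  newLesion <- rep_len(as.logical(newLesion), n)
  completeDisappearance <- rep_len(as.logical(completeDisappearance), n)
  out <- rep("SD", n)
  out[dcPercent <= -30] <- "PR"
  out[dcPercent >= 20] <- "PD"
  out[completeDisappearance] <- "CR"
  out[newLesion] <- "PD"
  factor(out, levels = c("CR", "PR", "SD", "PD"))
}

#' Responder status under mRECIST
#' @param category factor/character of mRECIST categories.
#' @return Logical: `TRUE` for CR and PR.
#' @export
mrecistResponder <- function(category) as.character(category) %in% c("CR", "PR")

#' Classify responder status under mqEASL
#'
#' The volumetric responder rule: a patient is a responder when the viable
#' tumor volume decreased by at least the cutoff (default 57.0%,
#' inclusive) and no new lesion appeared; otherwise a non-responder.
#'
#' @param vcPercent percent viable-volume change (vectorized).
#' @param newLesion logical, new lesions at follow-up.
#' @param cutoffPercent responder boundary on the VC scale (negative);
#'   default -57.
#' @return Logical responder indicator.
#' @examples
#' classifyMqEASL(-40.8, FALSE)  # non-responder
#' classifyMqEASL(-57.0, FALSE)  # responder: boundary inclusive
#' @export
classifyMqEASL <- function(vcPercent, newLesion = FALSE,
                           cutoffPercent = -57.0) {
  if (any(!is.finite(vcPercent)) || any(vcPercent < -100))
    stop("volume change must be >= -100 percent")
  n <- max(length(vcPercent), length(newLesion))
  (rep_len(vcPercent, n) <= cutoffPercent) & !rep_len(as.logical(newLesion), n)
}

#' Annotate a cohort table with response quantities
#'
#' Appends `dc_percent`, `vc_percent`, `evc_percent`, `mrecist_category`,
#' `mrecist_responder` and `mqeasl_responder` to a cohort table on the
#' standard schema (columns `d_bl_cm`, `d_up_cm`, `vtv_bl_cm3`,
#' `vtv_up_cm3`, `new_lesion`, `complete_disappearance`, ...).
#'
#' @param cohort data.frame on the cohort schema.
#' @param cutoffPercent mqEASL responder cutoff (default -57).
#' @return The cohort with the response columns appended.
#' @export
assessCohort <- function(cohort, cutoffPercent = -57.0) {
  need <- c("d_bl_cm", "d_up_cm", "vtv_bl_cm3", "vtv_up_cm3",
            "new_lesion", "complete_disappearance")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  cohort$dc_percent <- percentChange(cohort$d_bl_cm, cohort$d_up_cm)
  cohort$vc_percent <- percentChange(cohort$vtv_bl_cm3, cohort$vtv_up_cm3)
  cohort$evc_percent <- expectedVolumeChange(cohort$dc_percent)
  cohort$mrecist_category <- as.character(classifyMRECIST(
    cohort$dc_percent, cohort$new_lesion == 1,
    cohort$complete_disappearance == 1))
  cohort$mrecist_responder <- as.integer(
    mrecistResponder(cohort$mrecist_category))
  cohort$mqeasl_responder <- as.integer(classifyMqEASL(
    cohort$vc_percent, cohort$new_lesion == 1, cutoffPercent))
  cohort
}

#' Agreement between two responder classifications
#'
#' Cross-tabulates paired responder labels (e.g. mRECIST vs mqEASL),
#' computes Cohen's kappa with its asymptotic 95% confidence interval, a
#' McNemar test on the discordant pairs (chi-square without continuity
#' correction when the discordant count is >= 25, exact binomial
#' otherwise), and the qualitative band: poor (< 0.4), moderate
#' (0.4-0.75), excellent (> 0.75).
#'
#' @param rater1,rater2 logical (or 0/1) responder labels of equal length.
#' @return A list with `table` (2x2 counts, rater1 in rows), `kappa`,
#'   `kappaCi95`, `mcnemarP`, `qualitative` and `degenerate` (TRUE when
#'   chance agreement is 1 and kappa is undefined).
#' @export
agreementStats <- function(rater1, rater2) {
  r1 <- as.logical(rater1); r2 <- as.logical(rater2)
  if (length(r1) != length(r2) || length(r1) < 1L)
    stop("need paired labels of equal positive length")
  f <- factor(c(FALSE, TRUE))
  tab <- table(factor(r1, levels = levels(f)), factor(r2, levels = levels(f)))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  rowm <- rowSums(tab) / n
  colm <- colSums(tab) / n
  pe <- sum(rowm * colm)
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(list(table = tab, kappa = NA_real_, kappaCi95 = c(NA_real_, NA_real_),
                mcnemarP = NA_real_, qualitative = NA_character_,
                degenerate = TRUE))
  }
  kappa <- (po - pe) / (1 - pe)
  # large-sample SE of kappa (Fleiss, Cohen & Everitt)
  p <- tab / n
  a <- 0
  for (i in 1:2) a <- a + p[i, i] * (1 - (rowm[i] + colm[i]) * (1 - kappa))^2
  b <- 0
  for (i in 1:2) for (j in 1:2) if (i != j)
    b <- b + p[i, j] * (colm[i] + rowm[j])^2
  b <- b * (1 - kappa)^2
  cc <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(0, a + b - cc) / (n * (1 - pe)^2))
  ci <- kappa + c(-1, 1) * qnorm(0.975) * se
  # McNemar on the discordant cells
  disc <- tab[1, 2] + tab[2, 1]
  mcp <- if (disc == 0) 1 else if (disc >= 25)
    mcnemar.test(tab, correct = FALSE)$p.value
  else binom.test(tab[1, 2], disc, 0.5)$p.value
  qual <- if (kappa < 0.4) "poor" else if (kappa <= 0.75) "moderate"
          else "excellent"
  list(table = tab, kappa = unname(kappa),
       kappaCi95 = unname(pmin(1, pmax(-1, ci))),
       mcnemarP = unname(mcp), qualitative = qual, degenerate = FALSE)
}

#' Fit the empirical EVC-VC linear relation
#'
#' Ordinary least-squares regression of the observed viable-volume change
#' (VC) on the cube-law expected volume change (EVC). A slope far from 1
#' and a large intercept indicate that the diameter-derived expectation
#' is a poor surrogate for the measured volumetric change.
#'
#' @param evcPercent,vcPercent paired percent changes (n >= 3).
#' @return A list with `slope`, `intercept` and the underlying `lm` fit.
#' @export
fitEvcVcLine <- function(evcPercent, vcPercent) {
  if (length(evcPercent) != length(vcPercent) || length(evcPercent) < 3L)
    stop("need >= 3 paired (EVC, VC) values")
  if (sd(evcPercent) < .Machine$double.eps^0.5)
    stop("degenerate design: EVC values are all equal")
  fit <- lm(vcPercent ~ evcPercent)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       fit = fit)
}
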