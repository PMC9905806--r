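# Survival comparison of the diameter-based and volume-based response
# markers: cohort splitting, Kaplan-Meier/log-rank, multivariate Cox
# models, Harrell's C, time-dependent AUROC and calibration curves.

#' Randomly split a cohort into training and validation sets
#'
#' Random partition without replacement at the given ratio (default 7:3);
#' the training size is `round(ratio * n)`. Reproducible given the seed.
#'
#' @param records cohort data.frame (n >= 10).
#' @param ratio training fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return A list with elements `training` and `validation`.
#' @export
splitCohort <- function(records, ratio = 0.7, seed = 1L) {
  n <- nrow(records)
  if (n < 10L) stop("need at least 10 records to split")
  if (ratio <= 0 || ratio >= 1) stop("'ratio' must lie in (0, 1)")
  nTrain <- round(ratio * n)
  idx <- withSeed(seed, sample.int(n, nTrain))
  list(training = records[sort(idx), , drop = FALSE],
       validation = records[setdiff(seq_len(n), idx), , drop = FALSE])
}

.survObj <- function(records)
  survival::Surv(records$time_months, records$event)

#' Kaplan-Meier median overall survival
#'
#' Product-limit median (first time at which the survival curve drops to
#' 0.5 or below) with the Brookmeyer-Crowley 95% confidence interval on
#' the log-log scale. When the curve never reaches 0.5 the median and the
#' open bounds are `NA`.
#'
#' @param records data.frame with `time_months` and `event` (>= 1 event).
#' @return A list with `median`, `lower`, `upper` (months) and the
#'   underlying `survfit`.
#' @export
kmMedian <- function(records) {
  if (sum(records$event) < 1L) stop("no events: median OS undefined")
  fit <- survival::survfit(.survObj(records) ~ 1, conf.type = "log-log")
  tab <- summary(fit)$table
  list(median = unname(tab["median"]),
       lower = unname(tab["0.95LCL"]),
       upper = unname(tab["0.95UCL"]),
       fit = fit)
}

#' Two-group log-rank test
#'
#' @param groupA,groupB data.frames with `time_months` and `event`.
#' @return A list with `chisq`, `p` and the `survdiff` object.
#' @export
logrankTest <- function(groupA, groupB) {
  if (nrow(groupA) < 1L || nrow(groupB) < 1L)
    stop("both groups must contain at least one subject")
  df <- rbind(
    data.frame(time_months = groupA$time_months, event = groupA$event,
               group = "A"),
    data.frame(time_months = groupB$time_months, event = groupB$event,
               group = "B"))
  sd <- survival::survdiff(.survObj(df) ~ group, data = df)
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  if (sd$chisq < .Machine$double.eps^0.5) p <- 1
  list(chisq = unname(sd$chisq), p = unname(p), survdiff = sd)
}

#' Compare responders and non-responders by Kaplan-Meier and log-rank
#'
#' @param records annotated cohort (see [assessCohort()]).
#' @param marker `"mrecist"` or `"mqeasl"`.
#' @return A list with per-group median OS (+ 95% CI, group sizes) and
#'   the log-rank p-value.
#' @export
kmByResponse <- function(records, marker = c("mqeasl", "mrecist")) {
  marker <- match.arg(marker)
  col <- paste0(marker, "_responder")
  if (!col %in% names(records)) stop("records lack column ", col)
  resp <- records[records[[col]] == 1, , drop = FALSE]
  nonresp <- records[records[[col]] == 0, , drop = FALSE]
  lr <- logrankTest(resp, nonresp)
  list(marker = marker,
       responder = c(n = nrow(resp), kmMedian(resp)[c("median", "lower", "upper")]),
       nonResponder = c(n = nrow(nonresp),
                        kmMedian(nonresp)[c("median", "lower", "upper")]),
       logrankP = lr$p)
}

.covariateCoding <- c(metastasis = "binary", pvtt = "binary",
                      subsequent_treatment = "ordinal",
                      mrecist_responder = "binary",
                      mqeasl_responder = "binary")

#' Construct a Cox model specification from printed coefficients
#'
#' @param coefficients named numeric vector; names drawn from the cohort
#'   schema (`metastasis`, `pvtt`, `subsequent_treatment`,
#'   `mrecist_responder`, `mqeasl_responder`).
#' @param responseMarker `"mrecist"`, `"mqeasl"` or `""`.
#' @return A [CoxModelSpec-class].
#' @examples
#' model1 <- coxModelSpec(c(metastasis = 1.68, pvtt = 1.43,
#'                          subsequent_treatment = -0.47,
#'                          mrecist_responder = -1.08), "mrecist")
#' @export
coxModelSpec <- function(coefficients, responseMarker = "") {
  coding <- unname(.covariateCoding[names(coefficients)])
  coding[is.na(coding)] <- "binary"
  new("CoxModelSpec",
      terms = data.frame(name = names(coefficients), coding = coding,
                         coefficient = unname(coefficients),
                         stringsAsFactors = FALSE),
      responseMarker = responseMarker, fit = NULL)
}

#' Fit a multivariate Cox model on the cohort schema
#'
#' Partial-likelihood estimation with Efron tie handling.
#' `subsequent_treatment` enters as a single ordinal 0-3 term and
#' responder markers as binary 0/1, matching the coding of the printed
#' prognostic models. Warns when there are fewer than 10 events per
#' covariate.
#'
#' @param records annotated cohort data.frame.
#' @param covariates character vector of covariate names.
#' @param responseMarker recorded marker label for the returned spec.
#' @return A [CoxModelSpec-class] with the `coxph` fit attached.
#' @export
fitCoxMultivariate <- function(records, covariates,
                               responseMarker = "") {
  miss <- setdiff(covariates, names(records))
  if (length(miss))
    stop("records are missing covariates: ", paste(miss, collapse = ", "))
  nev <- sum(records$event)
  if (nev < 10 * length(covariates))
    warning("fewer than 10 events per covariate (", nev, " events, ",
            length(covariates), " covariates); estimates may be unstable")
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = "efron")
  if (any(!is.finite(coef(fit))) || any(sqrt(diag(vcov(fit))) > 50))
    stop("Cox fit did not converge (possible separation)")
  coding <- unname(.covariateCoding[covariates])
  coding[is.na(coding)] <- "binary"
  new("CoxModelSpec",
      terms = data.frame(name = covariates, coding = coding,
                         coefficient = unname(coef(fit)),
                         stringsAsFactors = FALSE),
      responseMarker = responseMarker, fit = fit)
}

#' Linear predictor of a Cox model specification
#'
#' Dot product of the model coefficients with the patient's coded
#' covariates.
#'
#' @param spec a [CoxModelSpec-class].
#' @param patient a data.frame (one or more rows) or named list/vector
#'   supplying every covariate in the model.
#' @return Numeric linear predictor value(s).
#' @examples
#' model1 <- coxModelSpec(c(metastasis = 1.68, pvtt = 1.43,
#'                          subsequent_treatment = -0.47,
#'                          mrecist_responder = -1.08), "mrecist")
#' linearPredictor(model1, list(metastasis = 1, pvtt = 1,
#'                              subsequent_treatment = 0,
#'                              mrecist_responder = 0))  # 3.11
#' @export
setMethod("linearPredictor", "CoxModelSpec", function(spec, patient) {
  if (!is.data.frame(patient)) patient <- as.data.frame(as.list(patient))
  miss <- setdiff(spec@terms$name, names(patient))
  if (length(miss))
    stop("patient record is missing covariates: ",
         paste(miss, collapse = ", "))
  X <- as.matrix(patient[, spec@terms$name, drop = FALSE])
  if (any(!is.finite(X))) stop("covariate values must be finite")
  drop(X %*% spec@terms$coefficient)
})

#' Harrell's concordance index
#'
#' Fraction of usable pairs in which the patient with the higher linear
#' predictor has the shorter survival; ties in the predictor count 1/2.
#' Pairs are comparable when the earlier time is an event. Computed via
#' [survival::concordance()]; the standard error is the U-statistic
#' (infinitesimal jackknife) estimator.
#'
#' @param lp linear predictor (higher = higher risk).
#' @param times,events follow-up times and event indicators.
#' @return A list with `c` and `se`.
#' @export
harrellsC <- function(lp, times, events) {
  if (length(lp) != length(times) || length(lp) != length(events))
    stop("'lp', 'times' and 'events' must have equal length")
  cf <- survival::concordance(survival::Surv(times, events) ~ lp,
                              reverse = TRUE)
  if (cf$count[["concordant"]] + cf$count[["discordant"]] +
      cf$count[["tied.x"]] == 0)
    stop("no comparable pairs: concordance undefined")
  list(c = unname(cf$concordance), se = unname(sqrt(cf$var)))
}

# Kaplan-Meier estimate of the censoring survivor function G(t),
# evaluated with left limits for case weights.
.censoringKm <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  function(t, leftLimit = FALSE) {
    tt <- if (leftLimit) t - .Machine$double.eps^0.5 * max(1, abs(t)) else t
    s <- summary(fit, times = pmax(0, tt), extend = TRUE)$surv
    pmax(s, .Machine$double.eps)
  }
}

#' Time-dependent AUROC (cumulative cases / dynamic controls)
#'
#' Discrimination at a horizon: cases are subjects with an observed event
#' by the horizon, controls those still at risk beyond it. Weighted by
#' the inverse probability of censoring (Kaplan-Meier of the censoring
#' distribution); ties in the predictor count 1/2. Without censoring this
#' reduces to the direct empirical AUC between cases and controls. The
#' confidence interval is a seeded percentile bootstrap over patients.
#'
#' @param lp linear predictor (higher = higher risk).
#' @param times,events follow-up data.
#' @param horizon evaluation time (months).
#' @param nBoot bootstrap resamples for the CI (default 500); `0` skips
#'   the CI.
#' @param seed RNG seed for the bootstrap.
#' @return A list with `auc`, `lower`, `upper`, `horizon`.
#' @export
tdAuroc <- function(lp, times, events, horizon, nBoot = 500L, seed = 1L) {
  est <- function(lp, times, events) {
    case <- times <= horizon & events == 1
    ctrl <- times > horizon
    if (!any(case) || !any(ctrl)) return(NA_real_)
    G <- .censoringKm(times, events)
    wCase <- 1 / G(times[case], leftLimit = TRUE)
    wCtrl <- rep(1 / G(horizon), sum(ctrl))
    lc <- lp[case]; lu <- lp[ctrl]
    num <- 0
    for (i in seq_along(lc)) {
      num <- num + wCase[i] * sum(wCtrl * ((lc[i] > lu) + 0.5 * (lc[i] == lu)))
    }
    num / (sum(wCase) * sum(wCtrl))
  }
  auc <- est(lp, times, events)
  if (is.na(auc))
    stop("no events before (or no subjects at risk after) the horizon")
  lower <- upper <- NA_real_
  if (nBoot > 0) {
    n <- length(lp)
    boot <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      est(lp[idx], times[idx], events[idx])
    }, numeric(1)))
    qs <- quantile(boot, c(0.025, 0.975), na.rm = TRUE)
    lower <- unname(qs[1]); upper <- unname(qs[2])
  }
  list(auc = auc, lower = lower, upper = upper, horizon = horizon)
}

#' Predicted survival probabilities from a fitted Cox model
#'
#' Breslow baseline cumulative hazard from the training fit, combined
#' with each patient's linear predictor: S(t | x) = exp(-H0(t) e^lp).
#'
#' @param spec a [CoxModelSpec-class] with an attached fit.
#' @param records patients to predict for.
#' @param horizon time (months).
#' @return Numeric vector of predicted survival probabilities.
#' @export
predictedSurvival <- function(spec, records, horizon) {
  if (is.null(spec@fit))
    stop("a fitted model (with baseline hazard) is required")
  bh <- survival::basehaz(spec@fit, centered = FALSE)
  H0 <- if (any(bh$time <= horizon)) max(bh$hazard[bh$time <= horizon]) else 0
  lp <- linearPredictor(spec, records)
  exp(-H0 * exp(lp))
}

#' Calibration table of predicted vs observed survival
#'
#' Groups patients by predicted survival at the horizon (default
#' tertiles of predicted risk), and tabulates the mean predicted survival
#' against the Kaplan-Meier observed survival (with 95% CI) per group.
#' Groups with no subjects at risk at the horizon are flagged, not
#' dropped.
#'
#' @param spec a fitted [CoxModelSpec-class] (baseline from its training
#'   data).
#' @param records evaluation cohort.
#' @param horizon time (months).
#' @param nGroups number of risk groups (default 3).
#' @return data.frame with columns `group`, `n`, `predicted`, `observed`,
#'   `lower`, `upper`, `atRisk`, `flagged`.
#' @export
calibrationCurve <- function(spec, records, horizon, nGroups = 3L) {
  pred <- predictedSurvival(spec, records, horizon)
  qs <- quantile(pred, seq(0, 1, length.out = nGroups + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  grp <- cut(pred, unique(qs), labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    sub <- records[sel, , drop = FALSE]
    atRisk <- sum(sub$time_months >= horizon)
    fit <- survival::survfit(.survObj(sub) ~ 1, conf.type = "log-log")
    sm <- summary(fit, times = horizon, extend = TRUE)
    data.frame(group = g, n = sum(sel), predicted = mean(pred[sel]),
               observed = sm$surv, lower = sm$lower, upper = sm$upper,
               atRisk = atRisk, flagged = atRisk == 0)
  }))
  rownames(out) <- NULL
  out
}

#' Evaluate the diameter-based and volume-based prognostic models
#'
#' The head-to-head comparison: splits the cohort 7:3 into training and
#' validation sets, screens the pretreatment covariates (metastasis,
#' PVTT, subsequent treatment) by univariate Cox p-value, then fits two
#' multivariate Cox models on the training set — Model 1 carrying the
#' mRECIST responder marker, Model 2 the mqEASL responder marker — and
#' reports Harrell's C, time-dependent AUROC at the requested horizons,
#' and calibration tables on both cohorts.
#'
#' @param records annotated cohort (see [assessCohort()]).
#' @param splitSeed seed of the random 7:3 split.
#' @param ratio training fraction.
#' @param horizons AUROC/calibration horizons in months (default 6, 12,
#'   24).
#' @param screenP univariate entry threshold for pretreatment covariates
#'   (default 0.05).
#' @param nBoot bootstrap resamples for AUROC CIs.
#' @return A list with `models` (the two [CoxModelSpec-class] fits),
#'   `performance` (per model x cohort: C index with SE, AUROC per
#'   horizon, calibration tables) and the `split`.
#' @export
evaluateResponseModels <- function(records, splitSeed = 1L, ratio = 0.7,
                                   horizons = c(6, 12, 24), screenP = 0.05,
                                   nBoot = 200L) {
  split <- splitCohort(records, ratio = ratio, seed = splitSeed)
  train <- split$training
  base <- c("metastasis", "pvtt", "subsequent_treatment")
  keep <- base[vapply(base, function(cv) {
    f <- stats::as.formula(paste("survival::Surv(time_months, event) ~", cv))
    fit <- survival::coxph(f, data = train, ties = "efron")
    summary(fit)$coefficients[1, "Pr(>|z|)"] < screenP
  }, logical(1))]
  if (!length(keep)) keep <- base  # fall back to the full pretreatment set
  markers <- c(model1 = "mrecist_responder", model2 = "mqeasl_responder")
  models <- lapply(seq_along(markers), function(i) {
    fitCoxMultivariate(train, c(keep, markers[[i]]),
                       responseMarker = sub("_responder", "", markers[[i]]))
  })
  names(models) <- names(markers)
  perf <- lapply(models, function(m) {
    lapply(list(training = train, validation = split$validation),
           function(coh) {
      lp <- linearPredictor(m, coh)
      cidx <- harrellsC(lp, coh$time_months, coh$event)
      aucs <- lapply(horizons, function(h) {
        tryCatch(tdAuroc(lp, coh$time_months, coh$event, h,
                         nBoot = nBoot, seed = splitSeed + round(h)),
                 error = function(e) list(auc = NA_real_, lower = NA_real_,
                                          upper = NA_real_, horizon = h))
      })
      names(aucs) <- paste0("m", horizons)
      calib <- lapply(horizons, function(h)
        calibrationCurve(m, coh, h))
      names(calib) <- paste0("m", horizons)
      list(cIndex = cidx, auroc = aucs, calibration = calib)
    })
  })
  list(models = models, performance = perf, split = split)
}
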