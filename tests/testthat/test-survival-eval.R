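# Survival evaluation: split, Kaplan-Meier, log-rank, Cox models, linear
# predictors, concordance, time-dependent AUROC and calibration.

test_that("cohort split gives the documented sizes and a true partition", {
  coh <- data.frame(id = 1:129, time_months = rexp(129, 0.05),
                    event = rbinom(129, 1, 0.8))
  sp <- splitCohort(coh, ratio = 0.7, seed = 11L)
  expect_equal(nrow(sp$training), 90)
  expect_equal(nrow(sp$validation), 39)
  expect_setequal(c(sp$training$id, sp$validation$id), 1:129)
  expect_length(intersect(sp$training$id, sp$validation$id), 0)
  # determinism
  sp2 <- splitCohort(coh, ratio = 0.7, seed = 11L)
  expect_identical(sp$training$id, sp2$training$id)
  expect_error(splitCohort(coh[1:5, ]), "at least 10")
})

test_that("KM median matches hand product-limit computation", {
  # all events at t = 5
  allFive <- data.frame(time_months = rep(5, 8), event = 1L)
  expect_equal(kmMedian(allFive)$median, 5)
  # hand-computed table with heavy early censoring:
  # times 1+ 2 2 3+ 4 5: S(2)=0.6, S(4)=0.3 -> median 4
  toy <- data.frame(time_months = c(1, 2, 2, 3, 4, 5),
                    event = c(0, 1, 1, 0, 1, 1))
  km <- kmMedian(toy)
  expect_equal(km$median, 4)
  sm <- summary(km$fit, times = c(2, 4))
  expect_equal(sm$surv, c(0.6, 0.3))
  # exponential simulation: median near log(2)/rate
  set.seed(12)
  expDat <- data.frame(time_months = rexp(5000, log(2) / 20), event = 1L)
  expect_lt(abs(kmMedian(expDat)$median - 20), 1)
  # survival never reaching 0.5: undefined median, open upper bound
  high <- data.frame(time_months = c(1, 2, 3, 4, 5),
                     event = c(1, 0, 0, 0, 0))
  expect_true(is.na(kmMedian(high)$median))
  expect_error(kmMedian(data.frame(time_months = 1:3, event = 0L)),
               "no events")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(13)
  t <- sample(1:40, 60, replace = TRUE)
  fit <- kmMedian(data.frame(time_months = t, event = 1L))$fit
  sm <- summary(fit, times = sort(unique(t)))
  expect_equal(sm$surv, sapply(sort(unique(t)), function(u) mean(t > u)))
})

test_that("log-rank matches the hand O-E computation and null/power behavior", {
  # hand-worked small table
  gA <- data.frame(time_months = c(1, 3, 5), event = c(1, 1, 0))
  gB <- data.frame(time_months = c(2, 4, 6), event = c(1, 1, 1))
  # event times 1,2,3,4,6; observed A = 2
  # E_A = 3/6 + 2/5 + 2/4 + 1/3 + 0/1; V per-time p(1-p) hypergeom
  ea <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3 + 0 / 1
  va <- (3 * 3) / 36 + (2 * 3) / 25 + (2 * 2) / 16 + (1 * 2) / 9 + 0
  lr <- logrankTest(gA, gB)
  expect_equal(lr$chisq, (2 - ea)^2 / va, tolerance = 1e-10)
  expect_equal(lr$p, pchisq((2 - ea)^2 / va, 1, lower.tail = FALSE))
  # identical groups: statistic 0, p = 1
  same <- logrankTest(gA, gA)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  expect_error(logrankTest(gA, gA[0, ]), "at least one")
  # strong separation is detected essentially always
  hits <- vapply(1:10, function(s) {
    set.seed(200 + s)
    a <- data.frame(time_months = rexp(200, 0.05), event = 1L)
    b <- data.frame(time_months = rexp(200, 0.15), event = 1L)
    logrankTest(a, b)$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("linear predictors reproduce the printed prognostic models", {
  model1 <- coxModelSpec(c(metastasis = 1.68, pvtt = 1.43,
                           subsequent_treatment = -0.47,
                           mrecist_responder = -1.08), "mrecist")
  model2 <- coxModelSpec(c(metastasis = 1.88, pvtt = 0.92,
                           subsequent_treatment = -0.36,
                           mqeasl_responder = -1.41), "mqeasl")
  expect_equal(linearPredictor(model1,
    list(metastasis = 1, pvtt = 1, subsequent_treatment = 0,
         mrecist_responder = 0)), 3.11)
  expect_equal(linearPredictor(model2,
    list(metastasis = 0, pvtt = 0, subsequent_treatment = 0,
         mqeasl_responder = 0)), 0)
  expect_equal(linearPredictor(model2,
    list(metastasis = 0, pvtt = 0, subsequent_treatment = 3,
         mqeasl_responder = 1)), -2.49)
  expect_error(linearPredictor(model1, list(metastasis = 1)), "missing")
})

test_that("multivariate Cox matches a hand-maximized partial likelihood", {
  # single binary covariate, no ties: Newton-free grid oracle
  set.seed(14)
  n <- 24
  x <- rep(c(0, 1), each = n / 2)
  t <- rexp(n, 0.05 * exp(1 * x))
  rec <- data.frame(time_months = t, event = 1L, metastasis = x,
                    pvtt = 0, subsequent_treatment = 0)
  fit <- fitCoxMultivariate(rec, "metastasis")
  logPL <- function(b) {
    ord <- order(t)
    tt <- t[ord]; xx <- x[ord]
    sum(vapply(seq_len(n), function(i) {
      risk <- xx[seq(i, n)]
      b * xx[i] - log(sum(exp(b * risk)))
    }, numeric(1)))
  }
  oracle <- optimize(logPL, c(-4, 4), maximum = TRUE)$maximum
  expect_equal(modelTerms(fit)$coefficient[1], oracle, tolerance = 1e-4)
})

test_that("null covariates stay within their confidence intervals", {
  set.seed(15)
  n <- 400
  rec <- data.frame(time_months = rexp(n, 0.05), event = 1L,
                    metastasis = rbinom(n, 1, 0.3),
                    pvtt = rbinom(n, 1, 0.3),
                    subsequent_treatment = sample(0:3, n, TRUE))
  fit <- fitCoxMultivariate(rec, c("metastasis", "pvtt",
                                   "subsequent_treatment"))
  se <- sqrt(diag(vcov(fit@fit)))
  expect_true(all(abs(modelTerms(fit)$coefficient) < 2.6 * se))
})

test_that("Harrell's C equals brute-force pair enumeration", {
  bruteC <- function(lp, t, e) {
    num <- den <- 0
    n <- length(lp)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      # the pair is usable if the shorter time is an event
      a <- i; b <- j
      if (t[b] < t[a]) { a <- j; b <- i }
      if (t[a] == t[b]) {
        if (e[a] + e[b] == 0) next
        if (e[a] == 1 && e[b] == 1) next  # tied event times unusable
        if (e[a] == 0) { tmp <- a; a <- b; b <- tmp }
      }
      if (e[a] == 0) next
      den <- den + 1
      if (lp[a] > lp[b]) num <- num + 1
      else if (lp[a] == lp[b]) num <- num + 0.5
    }
    num / den
  }
  set.seed(16)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    lp <- round(rnorm(n), 1)  # rounding induces predictor ties
    t <- round(rexp(n, 0.1), 1)
    e <- rbinom(n, 1, 0.75)
    if (sum(e) < 2) e[1:2] <- 1L
    expect_equal(harrellsC(lp, t, e)$c, bruteC(lp, t, e))
  }
  # perfect anti-ranking, no censoring
  t <- 1:20
  expect_equal(harrellsC(-t, t, rep(1L, 20))$c, 1)
  # random predictor concentrates at 1/2
  set.seed(17)
  lp <- rnorm(2000); t <- rexp(2000, 0.05)
  expect_lt(abs(harrellsC(lp, t, rep(1L, 2000))$c - 0.5), 0.03)
})

test_that("Harrell's C is invariant under monotone transforms of the predictor", {
  set.seed(18)
  lp <- rnorm(100); t <- rexp(100, 0.1); e <- rbinom(100, 1, 0.8)
  c0 <- harrellsC(lp, t, e)$c
  expect_equal(harrellsC(3 * lp + 2, t, e)$c, c0)
  expect_equal(harrellsC(exp(lp), t, e)$c, c0)
})

test_that("binary-marker C and the log-rank direction agree", {
  set.seed(19)
  n <- 300
  marker <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.04 * exp(1.0 * marker))
  e <- rep(1L, n)
  cc <- harrellsC(marker, t, e)$c
  expect_gt(cc, 0.5)  # marker-positive group has worse survival
  mOS0 <- kmMedian(data.frame(time_months = t[marker == 0],
                              event = e[marker == 0]))$median
  mOS1 <- kmMedian(data.frame(time_months = t[marker == 1],
                              event = e[marker == 1]))$median
  expect_lt(mOS1, mOS0)
})

test_that("time-dependent AUROC matches the direct-count oracle without censoring", {
  set.seed(20)
  n <- 80
  lp <- round(rnorm(n), 1)
  t <- rexp(n, 0.08 * exp(0.8 * lp))
  e <- rep(1L, n)
  for (h in c(5, 10, 20)) {
    case <- t <= h
    ctrl <- t > h
    direct <- mean(outer(lp[case], lp[ctrl],
                         function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(tdAuroc(lp, t, e, h, nBoot = 0)$auc, direct)
  }
  # perfect risk ordering: AUC 1 at interior horizons
  t2 <- seq_len(n)
  expect_equal(tdAuroc(-t2, t2, rep(1L, n), 40, nBoot = 0)$auc, 1)
  # uninformative predictor near 1/2
  set.seed(21)
  lp <- rnorm(1000); t <- rexp(1000, 0.05)
  expect_lt(abs(tdAuroc(lp, t, rep(1L, 1000), 15, nBoot = 0)$auc - 0.5),
            0.05)
  expect_error(tdAuroc(lp, t + 100, rep(1L, 1000), 15, nBoot = 0),
               "horizon")
})

test_that("bootstrap AUROC intervals are seeded and ordered", {
  set.seed(22)
  n <- 150
  lp <- rnorm(n)
  t <- rexp(n, 0.06 * exp(0.7 * lp))
  e <- rbinom(n, 1, 0.85)
  a1 <- tdAuroc(lp, t, e, 12, nBoot = 60, seed = 5L)
  a2 <- tdAuroc(lp, t, e, 12, nBoot = 60, seed = 5L)
  expect_identical(a1, a2)
  expect_true(a1$lower <= a1$auc && a1$auc <= a1$upper)
})

test_that("calibration is self-consistent when the model is true", {
  g <- generateCohort(cohortSpec(n = 2000L, seed = 23L,
                                 hazardModel = "responder"))
  coh <- assessCohort(g$cohort)
  m <- fitCoxMultivariate(coh, c("metastasis", "pvtt",
                                 "subsequent_treatment",
                                 "mqeasl_responder"), "mqeasl")
  for (h in c(6, 12)) {
    tab <- calibrationCurve(m, coh, h)
    expect_true(all(abs(tab$predicted - tab$observed) <= 0.05))
    expect_false(any(tab$flagged))
  }
  # the mean predicted survival also matches the marginal KM
  marg <- summary(kmMedian(coh)$fit, times = 12, extend = TRUE)$surv
  expect_lt(abs(mean(predictedSurvival(m, coh, 12)) - marg), 0.05)
})

test_that("misspecified models still yield a monotone calibration table", {
  g <- generateCohort(cohortSpec(n = 1200L, seed = 24L))
  coh <- assessCohort(g$cohort)
  # omit the dominant response marker
  m <- fitCoxMultivariate(coh, c("metastasis", "pvtt"))
  tab <- calibrationCurve(m, coh, 12)
  # tied predictions (few distinct covariate patterns) may merge groups
  expect_gte(nrow(tab), 2)
  expect_true(all(diff(tab$predicted) > 0))
})

test_that("end-to-end evaluation compares the two markers on both cohorts", {
  coh <- assessCohort(generateCohort(cohortSpec(n = 350L, seed = 25L))$cohort)
  ev <- evaluateResponseModels(coh, splitSeed = 3L, nBoot = 30L)
  expect_named(ev$models, c("model1", "model2"))
  expect_equal(ev$models$model1@responseMarker, "mrecist")
  expect_equal(ev$models$model2@responseMarker, "mqeasl")
  for (m in names(ev$performance)) for (coh2 in names(ev$performance[[m]])) {
    p <- ev$performance[[m]][[coh2]]
    expect_true(p$cIndex$c >= 0 && p$cIndex$c <= 1)
    for (a in p$auroc)
      expect_true(is.na(a$auc) || (a$auc >= 0 && a$auc <= 1))
    for (tb in p$calibration)
      expect_true(all(tb$observed >= 0 & tb$observed <= 1, na.rm = TRUE))
  }
})
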