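# Pipeline entry points: file-in / file-out wrappers binding the modules
# end to end. The shipped command-line script (inst/cli/mqeasl.R) is a
# thin shell over these functions.

#' Quantify viable tumor volume from NIfTI inputs
#'
#' Reads the enhanced and unenhanced arterial-phase volumes, the
#' whole-tumor mask (Seg1) and the healthy-parenchyma reference points,
#' runs [quantifyViableTumor()], and writes the Seg2 mask plus a JSON
#' report (threshold, VTV in cm^3).
#'
#' @param enhancedPath,unenhancedPath,seg1Path NIfTI file paths.
#' @param refsPath CSV of 0-based reference voxel coordinates (columns
#'   x, y, z).
#' @param outJson report path; `NULL` to skip.
#' @param outSeg2 Seg2 NIfTI path; `NULL` to skip.
#' @param neighborhoodRadius reference-point sampling radius in voxels.
#' @return Invisibly, the [ViableVolumeResult-class].
#' @export
runQuantify <- function(enhancedPath, unenhancedPath, seg1Path, refsPath,
                        outJson = NULL, outSeg2 = NULL,
                        neighborhoodRadius = 1L) {
  enh <- readVolume(enhancedPath)
  unenh <- readVolume(unenhancedPath)
  seg1 <- readMask(seg1Path)
  refs <- readReferencePoints(refsPath, neighborhoodRadius)
  res <- quantifyViableTumor(enh, unenh, seg1, refs)
  if (!is.null(outSeg2)) writeMask(seg2(res), outSeg2)
  if (!is.null(outJson))
    jsonlite::write_json(
      list(threshold = enhancementThreshold(res), vtv_cm3 = vtv(res),
           seg2_voxels = sum(volumeData(seg2(res)))),
      outJson, auto_unbox = TRUE, digits = NA)
  invisible(res)
}

.readCohortCsv <- function(path) {
  cohort <- read.csv(path)
  need <- c("id", "d_bl_cm", "d_up_cm", "vtv_bl_cm3", "vtv_up_cm3",
            "new_lesion", "complete_disappearance")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort CSV is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!(cohort$d_bl_cm > 0) | !(cohort$vtv_bl_cm3 > 0) |
               !(cohort$d_up_cm >= 0) | !(cohort$vtv_up_cm3 >= 0) |
               !cohort$new_lesion %in% c(0, 1) |
               !cohort$complete_disappearance %in% c(0, 1))
  if (length(bad))
    stop("invalid cohort rows (ids): ",
         paste(cohort$id[bad], collapse = ", "))
  cohort
}

#' Annotate a cohort CSV with response classifications
#'
#' @param cohortPath input CSV on the cohort schema.
#' @param outPath annotated output CSV; `NULL` to skip writing.
#' @param cutoffPercent mqEASL responder cutoff (default -57).
#' @return Invisibly, the annotated data.frame.
#' @export
runAssess <- function(cohortPath, outPath = NULL, cutoffPercent = -57.0) {
  cohort <- assessCohort(.readCohortCsv(cohortPath), cutoffPercent)
  if (!is.null(outPath)) write.csv(cohort, outPath, row.names = FALSE)
  invisible(cohort)
}

#' Derive the volumetric response cutoff from a cohort CSV
#'
#' @param cohortPath input CSV (annotated, or raw — response columns are
#'   computed if absent).
#' @param outJson cutoff report path; `NULL` to skip.
#' @param outCurveCsv hazard-curve samples path; `NULL` to skip.
#' @param knots optional knot locations.
#' @return Invisibly, the [CutoffResult-class].
#' @export
runDeriveCutoff <- function(cohortPath, outJson = NULL, outCurveCsv = NULL,
                            knots = NULL) {
  cohort <- .readCohortCsv(cohortPath)
  if (!"vc_percent" %in% names(cohort)) cohort <- assessCohort(cohort)
  if (!all(c("time_months", "event") %in% names(cohort)))
    stop("cohort CSV lacks survival columns time_months/event")
  res <- deriveCutoff(cohort, knots = knots)
  writeCutoffReport(res, jsonPath = outJson, curveCsvPath = outCurveCsv)
  invisible(res)
}

#' Evaluate the two prognostic models from a cohort CSV
#'
#' Annotates the cohort if needed, runs [evaluateResponseModels()] and
#' writes a JSON performance report (per model and cohort: coefficients,
#' Harrell's C with SE, time-dependent AUROC with CIs, calibration
#' tables) plus optional KM comparison.
#'
#' @param cohortPath input CSV.
#' @param outJson report path; `NULL` to skip.
#' @param outCsvDir directory for plotting CSVs (KM curves by responder
#'   status, AUROC by horizon, calibration tables); `NULL` to skip.
#' @param splitSeed seed of the 7:3 split.
#' @param cutoffPercent mqEASL cutoff used for annotation.
#' @param horizons AUROC/calibration horizons (months).
#' @param nBoot bootstrap resamples for AUROC CIs.
#' @return Invisibly, the evaluation list.
#' @export
runEvaluate <- function(cohortPath, outJson = NULL, outCsvDir = NULL,
                        splitSeed = 1L,
                        cutoffPercent = -57.0, horizons = c(6, 12, 24),
                        nBoot = 200L) {
  cohort <- .readCohortCsv(cohortPath)
  if (!"mqeasl_responder" %in% names(cohort))
    cohort <- assessCohort(cohort, cutoffPercent)
  ev <- evaluateResponseModels(cohort, splitSeed = splitSeed,
                               horizons = horizons, nBoot = nBoot)
  if (!is.null(outJson)) {
    rep <- lapply(names(ev$models), function(mn) {
      m <- ev$models[[mn]]
      list(response_marker = m@responseMarker,
           coefficients = setNames(as.list(m@terms$coefficient),
                                   m@terms$name),
           performance = lapply(ev$performance[[mn]], function(p)
             list(c_index = p$cIndex$c, c_index_se = p$cIndex$se,
                  auroc = p$auroc,
                  calibration = lapply(p$calibration, function(tb)
                    as.list(tb)))))
    })
    names(rep) <- names(ev$models)
    jsonlite::write_json(rep, outJson, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(outCsvDir)) {
    dir.create(outCsvDir, showWarnings = FALSE, recursive = TRUE)
    # KM curves per marker and responder status, on the full cohort
    km <- do.call(rbind, lapply(c("mrecist", "mqeasl"), function(mk) {
      col <- paste0(mk, "_responder")
      do.call(rbind, lapply(0:1, function(r) {
        sub <- cohort[cohort[[col]] == r, , drop = FALSE]
        if (!nrow(sub) || sum(sub$event) < 1) return(NULL)
        fit <- kmMedian(sub)$fit
        data.frame(marker = mk, responder = r, time = fit$time,
                   surv = fit$surv, lower = fit$lower, upper = fit$upper)
      }))
    }))
    write.csv(km, file.path(outCsvDir, "km_curves.csv"), row.names = FALSE)
    auc <- do.call(rbind, lapply(names(ev$performance), function(mn)
      do.call(rbind, lapply(names(ev$performance[[mn]]), function(cn) {
        as <- ev$performance[[mn]][[cn]]$auroc
        data.frame(model = mn, cohort = cn,
                   horizon = vapply(as, `[[`, numeric(1), "horizon"),
                   auc = vapply(as, `[[`, numeric(1), "auc"),
                   lower = vapply(as, `[[`, numeric(1), "lower"),
                   upper = vapply(as, `[[`, numeric(1), "upper"))
      }))))
    write.csv(auc, file.path(outCsvDir, "auroc_by_time.csv"),
              row.names = FALSE)
    calib <- do.call(rbind, lapply(names(ev$performance), function(mn)
      do.call(rbind, lapply(names(ev$performance[[mn]]), function(cn) {
        cl <- ev$performance[[mn]][[cn]]$calibration
        do.call(rbind, lapply(names(cl), function(h)
          cbind(model = mn, cohort = cn, horizon = h, cl[[h]])))
      }))))
    write.csv(calib, file.path(outCsvDir, "calibration.csv"),
              row.names = FALSE)
  }
  invisible(ev)
}

#' Simulate phantom and cohort inputs to files
#'
#' Writes a synthetic cohort CSV with its truth sidecar JSON, and
#' optionally a NIfTI phantom set. Generation parameters can be supplied
#' as a YAML config (keys matching the [cohortSpec()] / [phantomSpec()]
#' arguments).
#'
#' @param outDir output directory (created if missing).
#' @param configPath optional YAML config with `cohort:` and `phantom:`
#'   sections.
#' @param seed RNG seed (overrides the config seed).
#' @param phantom logical, also write a phantom set.
#' @return Invisibly, paths of the files written.
#' @export
runSimulate <- function(outDir, configPath = NULL, seed = 1L,
                        phantom = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list()
  if (!is.null(configPath)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read config files")
    cfg <- yaml::read_yaml(configPath)
  }
  cohortArgs <- cfg$cohort %||% list()
  cohortArgs$seed <- seed
  gen <- generateCohort(do.call(cohortSpec, cohortArgs))
  cohortPath <- file.path(outDir, "cohort.csv")
  truthPath <- file.path(outDir, "cohort_truth.json")
  write.csv(gen$cohort, cohortPath, row.names = FALSE)
  jsonlite::write_json(gen$truth, truthPath, auto_unbox = TRUE, digits = NA)
  paths <- c(cohort = cohortPath, truth = truthPath)
  if (phantom) {
    phantomArgs <- cfg$phantom %||% list()
    phantomArgs$seed <- seed
    ph <- generatePhantom(do.call(phantomSpec, phantomArgs))
    pe <- file.path(outDir, "phantom_enhanced.nii.gz")
    pu <- file.path(outDir, "phantom_unenhanced.nii.gz")
    ps <- file.path(outDir, "phantom_seg1.nii.gz")
    pr <- file.path(outDir, "phantom_refs.csv")
    writeVolume(ph$enhanced, pe); writeVolume(ph$unenhanced, pu)
    writeMask(ph$seg1, ps)
    write.csv(data.frame(x = ph$refPoints@points[, 1] - 1L,
                         y = ph$refPoints@points[, 2] - 1L,
                         z = ph$refPoints@points[, 3] - 1L),
              pr, row.names = FALSE)
    jsonlite::write_json(list(true_vtv_cm3 = ph$trueVtvCm3),
                         file.path(outDir, "phantom_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, enhanced = pe, unenhanced = pu, seg1 = ps, refs = pr)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
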