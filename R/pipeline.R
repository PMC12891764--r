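# Per-subject orchestration and cohort aggregation. A subject record names
# the input files (T1-like stack, aqueduct morphological volume, two cine
# series, ROI/landmark JSON); runSubject() executes the three measurement
# pipelines and emits one cohort row; runCohort() applies the exclusion
# cascade (imaging failure, >10% cardiac-cycle mismatch, 3xIQR screening),
# then summaries, sex comparisons and correlation matrices, logging every
# exclusion with its reason.

#' Pipeline configuration
#'
#' All thresholds of the three pipelines in one record; no hidden
#' constants.
#'
#' @param resistance a \code{\link{resistanceParams}}
#' @param flow a \code{\link{flowParams}}
#' @param morphSpacingMm morphometry interpolation target in mm
#' @param outlierColumns,outlierK 3xIQR screening rule
#' @param mismatchLimitPct cardiac-cycle-mismatch QC limit in percent
#' @param seed RNG seed recorded with the run
#' @return list of class \code{runConfig}
#' @export
runConfig <- function(resistance = resistanceParams(), flow = flowParams(),
                      morphSpacingMm = 0.1,
                      outlierColumns = c("ratio_area", "ratio_sv",
                                         "resistance"),
                      outlierK = 3, mismatchLimitPct = 10, seed = 1L) {
  structure(list(resistance = resistance, flow = flow,
                 morphSpacingMm = morphSpacingMm,
                 outlierColumns = outlierColumns, outlierK = outlierK,
                 mismatchLimitPct = mismatchLimitPct,
                 seed = as.integer(seed)),
            class = "runConfig")
}

#' Generate and write a complete phantom subject
#'
#' Creates the four inputs of one synthetic subject (T1-like brain stack,
#' aqueduct tube volume, aqueduct- and cervical-level cine series) plus the
#' ROI/landmark JSON, writes them under \code{dir}, and returns the subject
#' record row. Per-subject anatomy and dynamics are drawn reproducibly from
#' the seed.
#'
#' @param dir output directory (created if needed)
#' @param id subject identifier
#' @param sex "M" or "F"
#' @param age age in years
#' @param seed subject seed
#' @param tubeSpec,brainSpec,cineAqSpec,cineCvSpec optional explicit
#'   phantom specs overriding the seed-derived defaults
#' @return one-row data.frame: the manifest entry (id, sex, age and file
#'   paths)
#' @export
makePhantomSubject <- function(dir, id, sex = "M", age = 25, seed = 1L,
                               tubeSpec = NULL, brainSpec = NULL,
                               cineAqSpec = NULL, cineCvSpec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  jit <- function(x, f = 0.1) x * (1 + runif(1, -f, f))
  if (is.null(brainSpec))
    brainSpec <- brainPhantomSpec(ventAxesMm = c(jit(10), jit(4)),
                                  plexusRadiusMm = 1.5, noiseSd = 2,
                                  seed = seed)
  if (is.null(tubeSpec)) {
    dMin <- jit(1.2); dMax <- jit(2.2)
    tubeSpec <- tubePhantomSpec(
      lengthMm = jit(15),
      diameterMm = function(s) dMin + (dMax - dMin) * (0.3 + 0.7 * s),
      voxelSpacingMm = 0.1, noiseSd = 2, seed = seed)
  }
  cycle <- jit(850)
  if (is.null(cineAqSpec))
    cineAqSpec <- cinePhantomSpec(cycleMs = cycle, lumenRadiusMm = jit(1.8),
                                  waveformAmpCms = jit(3), vencCms = 10,
                                  backgroundOffsetCms = runif(1, -0.3, 0.3),
                                  noiseSdCms = 0.2, voxelSpacingMm = 0.4,
                                  fovMm = 16, seed = seed + 1L)
  if (is.null(cineCvSpec))
    cineCvSpec <- cinePhantomSpec(cycleMs = jit(cycle, 0.02),
                                  lumenRadiusMm = jit(5),
                                  waveformAmpCms = jit(1.5), vencCms = 5,
                                  backgroundOffsetCms = runif(1, -0.3, 0.3),
                                  noiseSdCms = 0.2, voxelSpacingMm = 0.6,
                                  fovMm = 30, seed = seed + 2L)

  brain <- generateBrainSlice(brainSpec)
  tube <- generateTubeVolume(tubeSpec)
  t1Path <- file.path(dir, paste0(id, "_t1.nii.gz"))
  bffePath <- file.path(dir, paste0(id, "_bffe.nii.gz"))
  writeVolume(brain, t1Path)
  writeVolume(tube, bffePath)
  aqPrefix <- file.path(dir, paste0(id, "_cine_aq"))
  cvPrefix <- file.path(dir, paste0(id, "_cine_cv"))
  writeCineSeries(generateCineSeries(cineAqSpec), aqPrefix)
  writeCineSeries(generateCineSeries(cineCvSpec), cvPrefix)

  gtB <- groundTruth(brain); gtT <- groundTruth(tube)
  # the phantom lumen is centered in the field of view
  nPix <- function(sp) 2L * ceiling(sp$fovMm / 2 / sp$voxelSpacingMm) + 1L
  seedAq <- rep((nPix(cineAqSpec) - 1) / 2, 2)
  seedCv <- rep((nPix(cineCvSpec) - 1) / 2, 2)
  rois <- list(morph = gtB$rois, aqueduct = gtT$landmarks,
               flowSeeds = list(aq = seedAq, cv = seedCv))
  roiPath <- file.path(dir, paste0(id, "_rois.json"))
  writeRois(rois, roiPath)
  data.frame(id = id, sex = sex, age_years = age, t1_path = t1Path,
             bffe_path = bffePath, cine_aq_prefix = aqPrefix,
             cine_cv_prefix = cvPrefix, roi_path = roiPath,
             stringsAsFactors = FALSE)
}

#' Run the full measurement pipeline on one subject
#'
#' Executes morphometry, aqueduct resistance and flow quantification on the
#' files named in the record. Any stage error marks the row as failed with
#' the stage name; the remaining columns stay NA so a cohort run can
#' continue.
#'
#' @param record one-row manifest data.frame (see
#'   \code{\link{makePhantomSubject}})
#' @param config a \code{\link{runConfig}}
#' @return one-row data.frame with the cohort columns plus \code{status},
#'   \code{failed_stage}, \code{cycle_mismatch_pct}, \code{qc_flagged}
#' @export
runSubject <- function(record, config = runConfig()) {
  row <- data.frame(id = record$id, sex = record$sex,
                    age_years = record$age_years,
                    area_vent_mm2 = NA_real_, area_brain_mm2 = NA_real_,
                    ratio_area = NA_real_, resistance = NA_real_,
                    user_length_mm = NA_real_,
                    effective_length_mm = NA_real_, d_mean_mm = NA_real_,
                    d_min_mm = NA_real_, cycle_ms = NA_real_,
                    sv_aq_mm3 = NA_real_, sv_cv_mm3 = NA_real_,
                    ratio_sv = NA_real_, cycle_mismatch_pct = NA_real_,
                    qc_flagged = FALSE, status = "ok",
                    failed_stage = NA_character_,
                    stringsAsFactors = FALSE)
  fail <- function(stage) {
    row$status <<- "failed"
    row$failed_stage <<- stage
    row
  }
  rois <- tryCatch(readRois(record$roi_path),
                   error = function(e) NULL)
  if (is.null(rois)) return(fail("inputs"))

  morph <- tryCatch({
    vol <- readVolume(record$t1_path)
    selectMaxRatioSlice(vol,
                        list(ventricle = rois$morph$ventricle,
                             brain = rois$morph$brain),
                        targetSpacingMm = config$morphSpacingMm,
                        thresholdLine = rois$morph$thresholdLine)
  }, error = function(e) e)
  if (inherits(morph, "error")) return(fail("morphometry"))
  row$area_vent_mm2 <- morph@areaVentMm2
  row$area_brain_mm2 <- morph@areaBrainMm2
  row$ratio_area <- morph@ratioArea * 100

  aq <- tryCatch({
    vol <- readVolume(record$bffe_path)
    lm <- rois$aqueduct
    analyzeAqueduct(vol, list(startPx = lm$startPx, endPx = lm$endPx,
                              narrowLinePx = lm$narrowLinePx),
                    params = config$resistance)
  }, error = function(e) e)
  if (inherits(aq, "error")) return(fail("aqueduct"))
  s <- summarizeAqueduct(aq)
  row$resistance <- s$resistance_mPa_s_mm3
  row$user_length_mm <- s$user_length_mm
  row$effective_length_mm <- s$effective_length_mm
  row$d_mean_mm <- s$d_mean_mm
  row$d_min_mm <- s$d_min_mm

  flow <- tryCatch({
    aqS <- readCineSeries(record$cine_aq_prefix)
    cvS <- readCineSeries(record$cine_cv_prefix)
    fAq <- analyzeFlowSite(aqS, unlist(rois$flowSeeds$aq), config$flow)
    fCv <- analyzeFlowSite(cvS, unlist(rois$flowSeeds$cv), config$flow)
    list(r = ratioSV(fAq$sv, fCv$sv, aqS@cycleMs, cvS@cycleMs,
                     config$mismatchLimitPct),
         cycles = c(aqS@cycleMs, cvS@cycleMs))
  }, error = function(e) e)
  if (inherits(flow, "error")) return(fail("flow"))
  row$sv_aq_mm3 <- flow$r$svAqMm3
  row$sv_cv_mm3 <- flow$r$svCvMm3
  row$ratio_sv <- flow$r$ratioPct
  row$cycle_ms <- mean(flow$cycles)
  row$cycle_mismatch_pct <- flow$r$cycleMismatchPct
  row$qc_flagged <- flow$r$flagged
  row
}

#' Cohort-level report from a table of subject rows
#'
#' Applies the exclusion cascade in the fixed order imaging failure ->
#' cardiac-cycle-mismatch QC -> single-pass 3xIQR screening, then computes
#' per-parameter summaries (total and by sex), Wilcoxon sex comparisons
#' with effect sizes, and the Spearman correlation matrix. With fewer than
#' 4 surviving subjects only summaries are produced.
#'
#' @param table cohort data.frame (rows as from \code{\link{runSubject}} or
#'   \code{\link{generateCohortTable}})
#' @param config a \code{\link{runConfig}}
#' @return list with \code{kept}, \code{exclusions} (id/reason/detail),
#'   \code{summaries}, \code{sexTests}, \code{correlations}
#' @export
cohortReport <- function(table, config = runConfig()) {
  exclusions <- data.frame(id = character(), reason = character(),
                           detail = character(), stringsAsFactors = FALSE)
  note <- function(ids, reason, detail) {
    if (length(ids))
      exclusions <<- rbind(exclusions,
                           data.frame(id = as.character(ids),
                                      reason = reason, detail = detail,
                                      stringsAsFactors = FALSE))
  }
  tab <- table
  if ("status" %in% names(tab)) {
    bad <- tab$status != "ok"
    note(tab$id[bad], "imaging_failure",
         paste("stage:", tab$failed_stage[bad]))
    tab <- tab[!bad, , drop = FALSE]
  }
  if ("cycle_mismatch_pct" %in% names(tab)) {
    bad <- !is.na(tab$cycle_mismatch_pct) &
      abs(tab$cycle_mismatch_pct) > config$mismatchLimitPct
    note(tab$id[bad], "cycle_mismatch",
         sprintf("%.1f%%", tab$cycle_mismatch_pct[bad]))
    tab <- tab[!bad, , drop = FALSE]
  }
  scr <- excludeOutliers(tab, config$outlierColumns, config$outlierK)
  if (nrow(scr$excluded))
    note(scr$excluded$id, "iqr_outlier",
         sprintf("%s = %.4g outside [%.4g, %.4g]", scr$excluded$column,
                 scr$excluded$value, scr$excluded$lower,
                 scr$excluded$upper))
  tab <- scr$kept

  params <- intersect(c("area_vent_mm2", "area_brain_mm2", "ratio_area",
                        "user_length_mm", "effective_length_mm", "d_min_mm",
                        "d_mean_mm", "resistance", "cycle_ms", "sv_aq_mm3",
                        "sv_cv_mm3", "ratio_sv", "age_years"), names(tab))
  groups <- list(total = tab, male = tab[tab$sex == "M", , drop = FALSE],
                 female = tab[tab$sex == "F", , drop = FALSE])
  summaries <- lapply(groups, function(g) {
    if (nrow(g) < 2) return(NULL)
    out <- lapply(params, function(p) summarizeStats(g[[p]]))
    names(out) <- params
    out
  })

  sexTests <- NULL
  correlations <- NULL
  if (nrow(tab) >= 4) {
    m <- tab[tab$sex == "M", , drop = FALSE]
    f <- tab[tab$sex == "F", , drop = FALSE]
    if (nrow(m) >= 3 && nrow(f) >= 3) {
      sexTests <- lapply(params, function(p)
        wilcoxonRankSum(m[[p]], f[[p]]))
      names(sexTests) <- params
    }
    corCols <- intersect(c("resistance", "ratio_area", "ratio_sv",
                           "sv_aq_mm3", "sv_cv_mm3", "cycle_ms"),
                         names(tab))
    correlations <- correlationMatrix(tab, corCols)
  }
  list(kept = tab, exclusions = exclusions, summaries = summaries,
       sexTests = sexTests, correlations = correlations,
       config = unclass(config))
}

#' Run the pipeline over a manifest and aggregate the cohort
#'
#' @param manifest data.frame of subject records or path to a manifest CSV
#' @param config a \code{\link{runConfig}}
#' @param outputDir optional directory; when given, the cohort CSV, report
#'   JSON and exclusion log are written there
#' @return the \code{\link{cohortReport}} result with an extra
#'   \code{perSubject} element (all rows, including failed ones)
#' @export
runCohort <- function(manifest, config = runConfig(), outputDir = NULL) {
  if (is.character(manifest))
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i)
    runSubject(manifest[i, , drop = FALSE], config)))
  rep <- cohortReport(rows, config)
  rep$perSubject <- rows
  if (!is.null(outputDir)) writeCohortReport(rep, outputDir)
  rep
}

#' Write a cohort report to disk
#'
#' Writes \code{cohort.csv} (kept rows), \code{per_subject.csv} (all rows,
#' when present), \code{report.json} (summaries, tests, correlations) and
#' \code{exclusions.log} (one line per exclusion with its reason).
#'
#' @param report result of \code{\link{cohortReport}} or
#'   \code{\link{runCohort}}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writeCohortReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$kept, file.path(dir, "cohort.csv"), row.names = FALSE)
  if (!is.null(report$perSubject))
    write.csv(report$perSubject, file.path(dir, "per_subject.csv"),
              row.names = FALSE)
  jsonlite::write_json(
    list(summaries = report$summaries, sexTests = report$sexTests,
         correlations = lapply(report$correlations, function(m)
           if (is.matrix(m)) as.data.frame(m) else m),
         nAnalyzed = nrow(report$kept)),
    file.path(dir, "report.json"), digits = NA, auto_unbox = TRUE,
    dataframe = "columns")
  lines <- if (nrow(report$exclusions))
    sprintf("%s\t%s\t%s", report$exclusions$id, report$exclusions$reason,
            report$exclusions$detail)
  else "no exclusions"
  writeLines(lines, file.path(dir, "exclusions.log"))
  invisible(dir)
}
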