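#' Run the full synthetic-to-biomarker pipeline
#'
#' Orchestrates simulate -> segment -> score -> train -> predict ->
#' biomarker -> stats on a synthetic cohort, writing every intermediate
#' artifact, the resolved configuration and a metrics JSON into a run
#' directory so a run is reproducible from its saved config.  Stages never
#' mutate earlier outputs.
#'
#' @param config named list (or path to a JSON file) with optional entries
#'   `seed`, `phantom` (arguments to [phantomSpec()]), `outcome`
#'   (arguments to [outcomeSpec()]), `cnn` (arguments to [cnnConfig()]),
#'   `folds`, `cube_side_mm`, `cutoff`.
#' @param outDir run directory to create.
#' @return Invisibly, the metrics list written to `metrics.json`.
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  folds <- as.integer(config$folds %||% 10L)
  cutoff <- config$cutoff %||% NULL
  side_mm <- config$cube_side_mm %||% 64
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## simulate
  pspec <- stage("simulate",
                 do.call(phantomSpec, modifyList(list(seed = seed),
                                                 as.list(config$phantom))))
  cohort <- stage("simulate", genPhantomCohort(pspec))
  lesions <- cohort$lesions
  write.csv(lesions, file.path(outDir, "lesions_truth.csv"),
            row.names = FALSE)

  ## segment + conventional features
  segstage <- stage("segment", {
    lapply(seq_along(cohort$volumes), function(i) {
      vol <- cohort$volumes[[i]]
      d <- dim(petData(vol))
      params <- thresholdParams(c(2, d[1] - 1, 2, d[2] - 1, 2, d[3] - 1))
      mask <- segmentTumor(vol, params)
      feats <- petFeatures(vol, mask)
      list(mask = mask, feats = feats)
    })
  })
  feats <- do.call(rbind, lapply(segstage, function(s)
    as.data.frame(s$feats)))
  feats <- cbind(lesions[, c("patient_id", "lesion_id")], feats)
  write.csv(feats, file.path(outDir, "pet_features.csv"), row.names = FALSE)

  ## expression + immune scores (one sample per lesion)
  u <- setNames(lesions$u, lesions$lesion_id)
  expr <- stage("score", genExpression(u, seed = derive_seed(seed, 101L)))
  scores <- stage("score", immuneScores(expr))
  write.csv(scores, file.path(outDir, "immune_scores.csv"), row.names = FALSE)

  ## cubes + cross-validated training
  cubes <- stage("train", lapply(seq_along(cohort$volumes), function(i)
    extractCube(cohort$volumes[[i]], segstage[[i]]$mask, side_mm = side_mm,
                patientId = lesions$patient_id[i],
                lesionId = lesions$lesion_id[i])))
  targets <- scores$cytact[match(lesions$lesion_id, scores$sample_id)]
  cnn_cfg <- stage("train",
                   do.call(cnnConfig, modifyList(list(seed = seed),
                                                 as.list(config$cnn))))
  cv <- stage("train", trainCytActCNN(cubes, targets, cnn_cfg, folds = folds))
  saveCNNModels(cv, file.path(outDir, "model"))

  ## out-of-fold predictions feed the biomarker stage
  pred <- oofPredictions(cv)$predicted
  les_pred <- data.frame(lesions[, c("patient_id", "lesion_id", "u")],
                         predicted_cytact = pred)
  ospec <- stage("biomarker",
                 do.call(outcomeSpec,
                         modifyList(list(seed = derive_seed(seed, 202L)),
                                    as.list(config$outcome))))
  icb <- stage("biomarker", genICBCohort(les_pred, ospec))
  icb$lesions$predicted_cytact <- pred # CNN predictions, not the emulator
  targ <- stage("biomarker", filterTargetLesions(icb$lesions))
  bio <- stage("biomarker", aggregatePatients(targ))
  bio <- merge(bio, icb$patients, by = "patient_id")
  roc <- stage("stats", rocAnalysis(bio$min_cytact, bio$responder))
  bio <- dichotomizeCytAct(bio, cutoff %||% roc$optimal_cutoff)
  write.csv(bio, file.path(outDir, "biomarkers.csv"), row.names = FALSE)

  ## statistics
  sstats <- stage("stats", {
    sc <- spearmanRho(targ$predicted_cytact, targ$size_change_pct)
    surv <- survivalAnalysis(bio$pfs_months, bio$pfs_event, bio$group)
    multi <- bio[!is.na(bio$cytact_variance), ]
    het <- if (length(unique(multi$responder)) == 2L)
      rankSumTest(multi$cytact_variance[!multi$responder],
                  multi$cytact_variance[multi$responder])$p.value
    else NA_real_
    list(pooled_oof_rho = cvRho(cv),
         lesion_size_change_rho = sc$rho, lesion_size_change_p = sc$p.value,
         auc_min_cytact = roc$auc, youden_cutoff = roc$optimal_cutoff,
         pfs_logrank_p = surv$logrank_p, pfs_hr_high = surv$hazard_ratio,
         heterogeneity_wilcoxon_p = het,
         n_lesions = nrow(lesions), n_patients = length(unique(lesions$patient_id)))
  })
  cfg_out <- list(seed = seed, folds = folds, cube_side_mm = side_mm,
                  phantom = unclass(pspec), outcome = unclass(ospec),
                  cnn = unclass(cnn_cfg))
  jsonlite::write_json(cfg_out, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(sstats, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sstats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
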