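# Single-call desk-scale reproduction of the whole analysis: simulate ->
# preprocess -> segmenter train/apply -> five-fold classifier training and
# evaluation on BOTH dataset variants (enhanced, segmented) -> Grad-CAM
# attribution on the segmented variant. Every stage derives its seed from
# the global seed, and rerunning with the same configuration reproduces
# all numeric outputs bit-for-bit.

#' Desk-scale pipeline configuration
#'
#' Nested configuration for [runPipeline()]. The defaults complete in a
#' few minutes on one CPU while exercising every stage; `nPerClass`,
#' image sizes and epoch counts scale the run up. Any entry can be
#' overridden via arguments or a YAML file ([readPipelineConfig()]).
#'
#' @param seed global seed; all stage seeds derive from it.
#' @param nPerClass images per class for the study cohort.
#' @param nSegTrain (image, mask) pairs for segmenter training, generated
#'   separately from the study cohort (its stand-in for an external
#'   segmentation training set).
#' @param workSide preprocessing target side for the desk-scale run.
#' @param simulator,preprocess,segmenter,classifier argument lists merged
#'   over the respective module defaults ([simulatorConfig()],
#'   [preprocessConfig()], [segmenterConfig()], [classifierConfig()]).
#' @param classifierSegmented extra classifier overrides for the segmented
#'   variant (the full-scale protocol trains it longer).
#' @param folds cross-validation folds.
#' @param groupBySubject subject-grouped folds (recommended).
#' @param attributionRadius enrichment disk radius in pixels; NULL = 2x
#'   mean vessel diameter.
#' @return nested list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L, nPerClass = 8L, nSegTrain = 8L,
                           workSide = 64L,
                           simulator = list(imageSize = 96L),
                           preprocess = list(),
                           segmenter = list(epochs = 4L,
                                            patchesPerImage = 12L,
                                            patchSide = 32L),
                           classifier = list(inputSide = 48L,
                                             trainResizeSide = 56L,
                                             epochs = 4L),
                           classifierSegmented = list(),
                           folds = 5L, groupBySubject = TRUE,
                           attributionRadius = NULL) {
  cfg <- list(seed = as.integer(seed), nPerClass = as.integer(nPerClass),
              nSegTrain = as.integer(nSegTrain),
              workSide = as.integer(workSide), simulator = simulator,
              preprocess = preprocess, segmenter = segmenter,
              classifier = classifier,
              classifierSegmented = classifierSegmented,
              folds = as.integer(folds),
              groupBySubject = isTRUE(groupBySubject),
              attributionRadius = attributionRadius)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipelineConfig()] arguments; missing keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(y), known)
  if (length(bad)) stopConfig("unknown config keys: ",
                              paste(bad, collapse = ", "))
  do.call(pipelineConfig, y)
}

.mergeArgs <- function(fn, overrides) do.call(fn, overrides)

.configHash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full desk-scale analysis
#'
#' Executes simulate -> preprocess -> segmenter train/apply -> five-fold
#' classifier cross-validation on both the enhanced and the segmented
#' dataset variants -> Grad-CAM bifurcation-enrichment attribution on the
#' segmented variant (using the fold model with the highest test
#' precision, applied to its own untouched test fold). Writes
#' `metrics_enhanced.csv` and `metrics_segmented.csv` (one row per fold
#' plus the average row), `history_<variant>.csv` (per-epoch losses),
#' `attribution_segmented.csv` and `attribution_summary.csv`, and
#' `run_manifest.json` with the configuration hash and all stage seeds.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory.
#' @param verbose print stage progress.
#' @return list with the cohort manifest, per-variant cross-validation
#'   results, the attribution report, and the output paths, invisibly.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run"),
                        verbose = interactive()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  logLines <- character()
  stage <- function(name) {
    line <- sprintf("[%s] stage=%s elapsed=%.1fs", format(Sys.time()),
                    name, as.numeric(Sys.time() - t0, "secs"))
    logLines <<- c(logLines, line)
    say("%s", line)
  }

  simCfg <- .mergeArgs(simulatorConfig,
                       utils::modifyList(list(seed = config$seed),
                                         config$simulator))
  preCfg <- .mergeArgs(preprocessConfig,
                       utils::modifyList(list(targetSide = config$workSide),
                                         config$preprocess))
  segCfg <- .mergeArgs(segmenterConfig,
                       utils::modifyList(list(seed = deriveSeed(config$seed,
                                                                "segment")),
                                         config$segmenter))
  clsCfg <- .mergeArgs(classifierConfig,
                       utils::modifyList(list(seed = deriveSeed(config$seed,
                                                                "train")),
                                         config$classifier))
  clsCfgSeg <- .mergeArgs(classifierConfig, utils::modifyList(
    utils::modifyList(list(seed = deriveSeed(config$seed, "train")),
                      config$classifier),
    config$classifierSegmented))

  stage("simulate")
  cohort <- generateCohort(simCfg, config$nPerClass,
                           seed = deriveSeed(config$seed, "simulate"))
  labels <- cohort$manifest$label
  subjects <- cohort$manifest$subject_id

  stage("preprocess")
  pairs <- lapply(cohort$records, function(r)
    enhancePair(r$image, r$mask, preCfg))
  enhanced <- lapply(pairs, `[[`, "image")
  masksEnh <- lapply(pairs, `[[`, "mask")
  bifsEnh <- lapply(seq_along(pairs), function(i) {
    tr <- pairs[[i]]$transform
    bf <- cohort$records[[i]]$bifurcations
    data.frame(x = (bf$x - tr$x0) * tr$scale, y = (bf$y - tr$y0) * tr$scale)
  })

  stage("segment-train")
  segSim <- generateCohort(simCfg, config$nSegTrain,
                           seed = deriveSeed(config$seed, "segment"))
  segPairs <- lapply(segSim$records, function(r) {
    p <- enhancePair(r$image, r$mask, preCfg)
    list(image = p$image, mask = p$mask)
  })
  segModel <- trainSegmenter(segPairs, segCfg)

  stage("segment-apply")
  segmented <- makeSegmentedDataset(segModel, enhanced)

  results <- list()
  for (variant in c("enhanced", "segmented")) {
    stage(paste0("train-", variant))
    imgs <- if (variant == "enhanced") enhanced else segmented
    cfgV <- if (variant == "enhanced") clsCfg else clsCfgSeg
    cv <- crossValidate(imgs, labels,
                        subjects = if (config$groupBySubject) subjects,
                        config = cfgV, k = config$folds,
                        groupBySubject = config$groupBySubject,
                        seed = deriveSeed(config$seed, "train"))
    tab <- cvTable(cv$foldReports)
    write.csv(tab, file.path(outDir, paste0("metrics_", variant, ".csv")),
              row.names = FALSE)
    histt <- do.call(rbind, lapply(seq_along(cv$models), function(f)
      cbind(fold = f, cv$models[[f]]@history)))
    write.csv(histt, file.path(outDir, paste0("history_", variant, ".csv")),
              row.names = FALSE)
    results[[variant]] <- cv
  }

  stage("attribution")
  cvSeg <- results$segmented
  prec <- vapply(cvSeg$foldReports, methods::slot, 0, "precision")
  bestFold <- which.max(ifelse(is.na(prec), -1, prec))
  testIds <- cvSeg$plan@folds[[bestFold]]$test
  report <- cohortAttributionReport(
    cvSeg$models[[bestFold]], segmented[testIds], labels[testIds],
    masksEnh[testIds], bifsEnh[testIds],
    radius = config$attributionRadius,
    ids = cohort$manifest$id[testIds])
  write.csv(report$table, file.path(outDir, "attribution_segmented.csv"),
            row.names = FALSE)
  write.csv(report$summary, file.path(outDir, "attribution_summary.csv"),
            row.names = FALSE)

  manifest <- list(
    config_hash = .configHash(unclass(config)),
    global_seed = config$seed,
    stage_seeds = list(simulate = deriveSeed(config$seed, "simulate"),
                       segment = deriveSeed(config$seed, "segment"),
                       train = deriveSeed(config$seed, "train"),
                       folds = deriveSeed(config$seed, "folds")),
    n_records = nrow(cohort$manifest),
    variants = lapply(results, function(cv)
      list(folds = cv$plan@k,
           average = as.list(metricsTable(cv$average)))),
    attribution_fold = bestFold,
    log = logLines)
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage("done")
  invisible(list(manifest = cohort$manifest, results = results,
                 attribution = report, segModel = segModel,
                 outDir = outDir))
}
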