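#' Construct a pipeline configuration
#'
#' Bundles the synthetic cohort settings with analysis parameters: bands,
#' sliding-window geometry, multitaper settings, threshold grid, stage seeds
#' and the output directory.
#'
#' @param cohort a [CohortConfig-class]; default [cohortConfig()].
#' @param bands named list of [BandSpec-class]; default [canonicalBands()].
#' @param fsAnalysis analysis rate after downsampling (Hz, default 1000).
#' @param winLen,step sliding window length/step in samples (256 / 128).
#' @param nw,k multitaper time-bandwidth (3) and taper count (5).
#' @param gridSize threshold grid size (100).
#' @param decodeBand band whose features feed the decoders ("beta").
#' @param seeds named vector with elements simulation, community, decoding.
#' @param outputDir run output directory.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(cohort = cohortConfig(), bands = canonicalBands(),
                           fsAnalysis = 1000, winLen = 256, step = 128,
                           nw = 3, k = 5, gridSize = 100,
                           decodeBand = "beta",
                           seeds = c(simulation = 1, community = 1,
                                     decoding = 1),
                           outputDir = tempfile("nclnet_run_")) {
  stopifnot(all(c("simulation", "community", "decoding") %in% names(seeds)))
  new("PipelineConfig", cohort = cohort, bands = bands,
      fsAnalysis = fsAnalysis, winLen = winLen, step = step, nw = nw, k = k,
      gridSize = gridSize, decodeBand = decodeBand,
      seeds = seeds[c("simulation", "community", "decoding")],
      outputDir = outputDir)
}

#' Reduced configuration for quick end-to-end runs
#'
#' Generation directly at the analysis rate, 10 trials, beta band only —
#' the fast path for smoke tests and CLI dry runs.
#'
#' @param seed master seed.
#' @param outputDir run output directory.
#' @return a [PipelineConfig-class].
#' @export
fastPipelineConfig <- function(seed = 1, outputDir = tempfile("nclnet_fast_")) {
  beta <- canonicalBands()["beta"]
  pipelineConfig(
    cohort = cohortConfig(nSubjects = 2, nTrials = 10, fsRaw = 1000,
                          seed = seed,
                          bandCoupling = list(beta = c(0.3, 0.8)),
                          bands = beta),
    bands = beta,
    seeds = c(simulation = seed, community = seed, decoding = seed),
    outputDir = outputDir)
}

configToList <- function(config) {
  ch <- config@cohort
  list(
    cohort = list(nSubjects = ch@nSubjects, nTrials = ch@nTrials,
                  nChannels = ch@nChannels, fsRaw = ch@fsRaw,
                  epochPre = ch@epochPre, epochPost = ch@epochPost,
                  bandCoupling = ch@bandCoupling, lineAmp = ch@lineAmp,
                  noiseSd = ch@noiseSd, seed = ch@seed),
    bands = lapply(config@bands, function(b)
      list(name = b@name, fLo = b@fLo, fHi = b@fHi)),
    fsAnalysis = config@fsAnalysis, winLen = config@winLen,
    step = config@step, nw = config@nw, k = config@k,
    gridSize = config@gridSize, decodeBand = config@decodeBand,
    seeds = as.list(config@seeds), outputDir = config@outputDir)
}

listToConfig <- function(x) {
  bands <- lapply(x$bands, function(b) bandSpec(b$name, b$fLo, b$fHi))
  names(bands) <- vapply(bands, function(b) b@name, "")
  cohort <- cohortConfig(
    nSubjects = x$cohort$nSubjects, nTrials = x$cohort$nTrials,
    nChannels = x$cohort$nChannels, fsRaw = x$cohort$fsRaw,
    epochPre = x$cohort$epochPre, epochPost = x$cohort$epochPost,
    bandCoupling = lapply(x$cohort$bandCoupling, as.numeric),
    lineAmp = x$cohort$lineAmp, noiseSd = x$cohort$noiseSd,
    seed = x$cohort$seed, bands = bands)
  pipelineConfig(cohort = cohort, bands = bands, fsAnalysis = x$fsAnalysis,
                 winLen = x$winLen, step = x$step, nw = x$nw, k = x$k,
                 gridSize = x$gridSize, decodeBand = x$decodeBand,
                 seeds = unlist(x$seeds), outputDir = x$outputDir)
}

#' Read / write a pipeline configuration file
#'
#' JSON (always) or YAML (if the yaml package is installed), chosen by file
#' extension. A run's configuration copy is written beside its outputs so
#' every run is self-describing.
#'
#' @param path configuration file path (.json, .yaml or .yml).
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("configuration error: YAML config requires the yaml package",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  }
  listToConfig(x)
}

#' @param config a [PipelineConfig-class].
#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(configToList(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

logMsg <- function(...) message(sprintf(...))

# ---- pipeline stages; each reads missing inputs from the run directory ----

stagePaths <- function(dir) {
  list(recDir = file.path(dir, "recordings"),
       epochs = file.path(dir, "epochs.rds"),
       tensors = file.path(dir, "tensors.rds"),
       traces = file.path(dir, "coherence_traces.csv"),
       sweepDir = dir,
       thresholds = file.path(dir, "optimal_thresholds.json"),
       features = file.path(dir, "network_features.csv"),
       summaryLong = file.path(dir, "feature_summary_long.csv"),
       summaryWide = file.path(dir, "feature_summary_wide.csv"),
       comparisons = file.path(dir, "condition_comparisons.csv"),
       decodeJson = file.path(dir, "decode_results.json"),
       accMatrix = file.path(dir, "accuracy_matrix.csv"),
       rocPoints = file.path(dir, "roc_points.csv"),
       manifest = file.path(dir, "manifest.json"),
       config = file.path(dir, "config.json"))
}

stageSimulate <- function(config, paths) {
  cohort <- generateCohort(config@cohort)
  dir.create(paths$recDir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort) {
    writeRecording(rec, file.path(paths$recDir, rec@subjectId))
  }
  cohort
}

loadRecordings <- function(paths) {
  prefixes <- sub("\\.json$", "",
                  list.files(paths$recDir, pattern = "\\.json$",
                             full.names = TRUE))
  lapply(sort(prefixes), readRecording)
}

stagePreprocess <- function(config, paths, recordings = NULL) {
  if (is.null(recordings)) recordings <- loadRecordings(paths)
  epochs <- list()
  for (rec in recordings) {
    sig <- broadbandFilter(rec@signal, rec@fs)
    sig <- removeLineNoise(sig, rec@fs)
    sig <- downsampleSignal(sig, rec@fs, config@fsAnalysis)
    perBand <- bandDecompose(sig, config@fsAnalysis, config@bands)
    epochs[[rec@subjectId]] <- lapply(names(perBand), function(nm) {
      extractEpochs(rec, perBand[[nm]], config@fsAnalysis,
                    preS = config@cohort@epochPre,
                    postS = config@cohort@epochPost,
                    band = config@bands[[nm]])
    })
    names(epochs[[rec@subjectId]]) <- names(perBand)
  }
  saveRDS(epochs, paths$epochs)
  epochs
}

stageCoherence <- function(config, paths, epochs = NULL) {
  if (is.null(epochs)) epochs <- readRDS(paths$epochs)
  epochLen <- round((config@cohort@epochPre + config@cohort@epochPost) *
                    config@fsAnalysis)
  plan <- planWindows(epochLen, config@winLen, config@step,
                      eventSample = config@cohort@epochPre * config@fsAnalysis)
  tensors <- lapply(epochs, function(perBand) {
    lapply(perBand, coherenceTensor, plan = plan, nw = config@nw,
           k = config@k)
  })
  saveRDS(tensors, paths$tensors)
  mids <- (plan@starts + plan@winLen / 2 - plan@eventSample) /
    config@fsAnalysis
  rows <- list()
  for (sid in names(tensors)) {
    for (nm in names(tensors[[sid]])) {
      tr <- globalMeanCoherence(tensors[[sid]][[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, band = nm, window = seq_along(tr),
        midpoint_s = mids, mean_coherence = tr, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), paths$traces, row.names = FALSE)
  tensors
}

stageThreshold <- function(config, paths, tensors = NULL) {
  if (is.null(tensors)) tensors <- readRDS(paths$tensors)
  bandNames <- names(config@bands)
  taus <- list()
  for (nm in bandNames) {
    perSubject <- lapply(tensors, function(x) x[[nm]])
    sweep <- selectOptimalThreshold(perSubject, gridSize = config@gridSize,
                                    seed = config@seeds[["community"]])
    taus[[nm]] <- sweep@optimal
    utils::write.csv(
      data.frame(threshold = sweep@thresholds,
                 mean_surprise = sweep@meanSurprise,
                 mean_lcc_fraction = sweep@lccFraction),
      file.path(paths$sweepDir,
                sprintf("threshold_sweep_%s.csv", gsub(" ", "_", nm))),
      row.names = FALSE)
  }
  jsonlite::write_json(taus, paths$thresholds, auto_unbox = TRUE, digits = NA)
  taus
}

stageFeatures <- function(config, paths, tensors = NULL, taus = NULL) {
  if (is.null(tensors)) tensors <- readRDS(paths$tensors)
  if (is.null(taus)) taus <- jsonlite::read_json(paths$thresholds,
                                                 simplifyVector = TRUE)
  rows <- list()
  for (sid in names(tensors)) {
    for (nm in names(config@bands)) {
      rows[[length(rows) + 1L]] <-
        featuresPerWindow(tensors[[sid]][[nm]], tau = taus[[nm]],
                          seed = config@seeds[["community"]])
    }
  }
  features <- do.call(rbind, rows)
  utils::write.csv(features, paths$features, row.names = FALSE)
  summ <- summarizeFeatures(features)
  utils::write.csv(summ$long, paths$summaryLong, row.names = FALSE)
  utils::write.csv(summ$wide, paths$summaryWide, row.names = FALSE)
  features
}

stageStats <- function(config, paths, features = NULL) {
  if (is.null(features)) features <- utils::read.csv(paths$features)
  cmp <- compareConditions(features)
  utils::write.csv(cmp, paths$comparisons, row.names = FALSE)
  cmp
}

stageDecode <- function(config, paths, features = NULL) {
  if (is.null(features)) features <- utils::read.csv(paths$features)
  results <- runDecodingSuite(features, band = config@decodeBand,
                              seed = config@seeds[["decoding"]])
  jsonlite::write_json(
    lapply(results, function(r) list(
      feature_set = r@featureSet, decoder = r@decoder,
      fold_accuracies = r@foldAccuracies, mean_accuracy = r@meanAccuracy,
      auc = r@auc)),
    paths$decodeJson, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  accs <- sapply(results, function(r) r@meanAccuracy)
  parts <- strsplit(names(results), ".", fixed = TRUE)
  accDf <- data.frame(decoder = vapply(parts, `[`, "", 1),
                      feature_set = vapply(parts, `[`, "", 2),
                      mean_accuracy = unname(accs),
                      auc = unname(sapply(results, function(r) r@auc)))
  utils::write.csv(accDf, paths$accMatrix, row.names = FALSE)
  rocRows <- do.call(rbind, lapply(names(results), function(k) {
    data.frame(combination = k, fpr = results[[k]]@roc[, "fpr"],
               tpr = results[[k]]@roc[, "tpr"])
  }))
  utils::write.csv(rocRows, paths$rocPoints, row.names = FALSE)
  results
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> coherence -> threshold -> features -> stats ->
#' decode, writing every artifact (CSV tables, JSON summaries, serialized
#' intermediates) plus a manifest with checksums and stage timings under the
#' config's output directory. Stages can be run singly; any stage finds its
#' inputs among the persisted intermediates of earlier stages.
#'
#' @param config a [PipelineConfig-class].
#' @param stages character vector of stages to run, in order.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config,
                        stages = c("simulate", "preprocess", "coherence",
                                   "threshold", "features", "stats",
                                   "decode")) {
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  paths <- stagePaths(config@outputDir)
  writePipelineConfig(config, paths$config)
  timings <- list()
  state <- new.env(parent = emptyenv())
  runStage <- function(name, fun) {
    logMsg("[%s] starting", name)
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(fun(), error = function(e) {
      manifestWrite(config, paths, timings, incomplete = TRUE,
                    failedStage = name)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    logMsg("[%s] done in %.1f s", name, timings[[name]])
    val
  }
  for (stage in stages) {
    switch(stage,
      simulate = assign("recordings", runStage("simulate", function()
        stageSimulate(config, paths)), envir = state),
      preprocess = assign("epochs", runStage("preprocess", function()
        stagePreprocess(config, paths, state$recordings)), envir = state),
      coherence = assign("tensors", runStage("coherence", function()
        stageCoherence(config, paths, state$epochs)), envir = state),
      threshold = assign("taus", runStage("threshold", function()
        stageThreshold(config, paths, state$tensors)), envir = state),
      features = assign("features", runStage("features", function()
        stageFeatures(config, paths, state$tensors, state$taus)),
        envir = state),
      stats = assign("comparisons", runStage("stats", function()
        stageStats(config, paths, state$features)), envir = state),
      decode = assign("decoding", runStage("decode", function()
        stageDecode(config, paths, state$features)), envir = state),
      stop(sprintf("unknown pipeline stage '%s'", stage), call. = FALSE))
  }
  manifest <- manifestWrite(config, paths, timings, incomplete = FALSE)
  invisible(manifest)
}

manifestWrite <- function(config, paths, timings, incomplete,
                          failedStage = NULL) {
  files <- list.files(config@outputDir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  artifacts <- lapply(files, function(f) {
    list(path = sub(paste0("^", config@outputDir, "/?"), "", f),
         bytes = file.info(f)$size,
         md5 = unname(tools::md5sum(f)))
  })
  manifest <- list(incomplete = incomplete, artifacts = artifacts,
                   stage_seconds = timings)
  if (!is.null(failedStage)) manifest$failed_stage <- failedStage
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}
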