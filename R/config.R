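# Experiment configuration (YAML) and the end-to-end orchestration used by
# the command-line interface.

#' Read an experiment configuration
#'
#' YAML keys: `endpoints` (as in [readEndpointConfig()]), `model`
#' (`dense_single`, `dense_multi`, `gcn_single`, `gcn_multi`),
#' `include_helpers`, `split` (mapping with `strategy`, `k`, `cutoff`,
#' `strict`), `weighting` (`simple`/`balanced`), `seed`, `epochs`,
#' `batch_size`, `n_bits` and `output_dir`. Unknown endpoints referenced
#' by `small_task` raise an error.
#'
#' @param file path to a YAML file.
#' @return a validated list of class `experimentConfig`.
#' @export
readExperimentConfig <- function(file) {
  y <- yaml::read_yaml(file)
  ep <- if (is.null(y$endpoints)) defaultEndpoints() else {
    tmp <- tempfile(); on.exit(unlink(tmp))
    yaml::write_yaml(list(endpoints = y$endpoints), tmp)
    readEndpointConfig(tmp)
  }
  cfg <- list(
    endpoints = ep,
    model = if (is.null(y$model)) "gcn_multi" else y$model,
    includeHelpers = !isFALSE(y$include_helpers),
    split = utils::modifyList(
      list(strategy = "cluster", k = 10L, cutoff = NA, strict = FALSE),
      if (is.null(y$split)) list() else y$split),
    weighting = if (is.null(y$weighting)) "simple" else y$weighting,
    seed = if (is.null(y$seed)) 1L else as.integer(y$seed),
    epochs = y$epochs, batchSize = y$batch_size,
    nBits = if (is.null(y$n_bits)) 2048L else as.integer(y$n_bits),
    outputDir = if (is.null(y$output_dir)) "." else y$output_dir)
  if (!cfg$model %in% c("dense_single", "dense_multi", "gcn_single",
                        "gcn_multi"))
    stop("unknown model: ", cfg$model)
  class(cfg) <- "experimentConfig"
  cfg
}

.modelConfigFor <- function(cfg, nTasks) {
  if (startsWith(cfg$model, "gcn")) {
    mc <- graphConvConfig(nTasks = nTasks, weighting = cfg$weighting)
  } else {
    mc <- denseNetConfig(nTasks = nTasks, inputDim = cfg$nBits,
                         weighting = cfg$weighting,
                         inputNoiseP = if (endsWith(cfg$model, "multi"))
                           0.01 else 0.02)
  }
  if (!is.null(cfg$epochs)) mc$epochs <- as.integer(cfg$epochs)
  if (!is.null(cfg$batchSize)) mc$batchSize <- as.integer(cfg$batchSize)
  mc
}

#' Run a configured cross-validation experiment
#'
#' End-to-end workflow: read the assay table, build and preprocess the
#' assay matrix, derive the split, run [runCrossValidation()], and write
#' per-fold metrics, fold averages, learning curves and a run log (seed
#' and an md5 run hash of the configuration) into the output directory.
#'
#' @param cfg an `experimentConfig` from [readExperimentConfig()] (or a
#'   path to one).
#' @param recordsFile path to the delimited assay table.
#' @param verbose print progress.
#' @return the [runCrossValidation()] result, invisibly.
#' @export
runExperiment <- function(cfg, recordsFile, verbose = FALSE) {
  if (is.character(cfg)) cfg <- readExperimentConfig(cfg)
  records <- readAssayTable(recordsFile)
  first <- !duplicated(records$compound_id)
  std <- standardizeMolecules(records$smiles[first],
                              ids = records$compound_id[first])
  mols <- std$molecules
  am <- buildAssayMatrix(records, cfg$endpoints, mols = mols)
  fps <- fingerprintMatrix(mols[rownames(am)], nBits = cfg$nBits)
  plan <- switch(cfg$split$strategy,
    cluster = clusterSplit(fps, am, K = cfg$split$k, seed = cfg$seed),
    random = randomSplitMatched(
      clusterSplit(fps, am, K = cfg$split$k, seed = cfg$seed),
      am, seed = cfg$seed),
    time = timeSplit(am, cutoff = cfg$split$cutoff,
                     strict = isTRUE(cfg$split$strict), seed = cfg$seed),
    stop("unknown split strategy: ", cfg$split$strategy))
  mc <- .modelConfigFor(cfg, ncol(am))
  res <- runCrossValidation(am, mols, plan, model = cfg$model,
                            includeHelpers = cfg$includeHelpers,
                            config = mc, seed = cfg$seed,
                            verbose = verbose)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$report$perFold,
                   file.path(cfg$outputDir, "metrics_per_fold.csv"),
                   row.names = FALSE)
  utils::write.csv(res$report$average,
                   file.path(cfg$outputDir, "metrics_average.csv"),
                   row.names = FALSE)
  curves <- do.call(rbind, lapply(names(res$models), function(f)
    do.call(rbind, lapply(names(res$models[[f]]), function(ts)
      cbind(fold = f, tasks = ts, res$models[[f]][[ts]]@history)))))
  utils::write.csv(curves, file.path(cfg$outputDir, "learning_curves.csv"),
                   row.names = FALSE)
  ser <- unclass(cfg)
  ser$endpoints <- as.data.frame(cfg$endpoints)
  tmp <- tempfile(); yaml::write_yaml(ser, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  writeLines(c(paste("seed:", cfg$seed), paste("run_hash:", hash),
               paste("model:", cfg$model),
               paste("leakage_audit_passed:", res$leakageAudit)),
             file.path(cfg$outputDir, "run_log.txt"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pretty performance table
#'
#' Formats fold-averaged metrics as a tasks x metrics text table.
#'
#' @param report a [metricsReport()] result (or the `report` element of
#'   [runCrossValidation()]).
#' @return character vector of formatted lines (also printed).
#' @export
formatMetricsTable <- function(report) {
  a <- report$average
  lines <- c(sprintf("%-6s %8s %10s %10s %8s", "task", "R2", "Spearman",
                     "Pearson", "RMSE"),
             vapply(seq_len(nrow(a)), function(i)
               sprintf("%-6s %8.2f %10.2f %10.2f %8.2f", a$code[i],
                       a$r2[i], a$spearman[i], a$pearson[i], a$rmse[i]),
               character(1)))
  cat(lines, sep = "\n")
  invisible(lines)
}
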