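# Cross-validation driver, helper-task ablation and the leakage audit.

.newModelFor <- function(model, codes, config, seed) {
  switch(model,
    gcn_single = , gcn_multi =
      graphConvModel(codes, config = if (is.null(config))
        graphConvConfig() else config, seed = seed),
    dense_single = , dense_multi =
      denseNetModel(codes, config = if (is.null(config))
        denseNetConfig() else config, seed = seed),
    stop("unknown model type: ", model))
}

.subsetTasks <- function(am, codes) {
  am2 <- am[, codes]
  methods::new("AssayMatrix", am2)
}

#' Cross-validated training and evaluation
#'
#' Trains one model per cross-validation fold of a [SplitPlan-class]
#' (cluster or matched-random strategies; time plans yield a single
#' train/test round), evaluates on the held-out fold, and reports per-fold
#' and fold-averaged metrics with standard deviations. Helper tasks
#' contribute to joint training but are excluded from the headline average
#' table. Multitask variants train one model over all endpoints;
#' single-task variants train an independent model per non-helper
#' endpoint.
#'
#' Per-task standardization scalers are fitted inside [fitModel()] on the
#' training fold only; the returned `leakageAudit` confirms that no
#' evaluated compound was part of scaler fitting or any training batch.
#'
#' @param am an [AssayMatrix-class].
#' @param mols named list of standardized [Molecule-class] objects
#'   covering the compounds of `am`.
#' @param plan a [SplitPlan-class].
#' @param model one of `"gcn_multi"`, `"gcn_single"`, `"dense_multi"`,
#'   `"dense_single"`.
#' @param includeHelpers keep helper endpoints in the trained tasks.
#' @param config optional [graphConvConfig()] / [denseNetConfig()].
#' @param seed integer seed (fold models get derived seeds).
#' @param verbose print progress.
#' @return list with `report` (see [metricsReport()]; `average` excludes
#'   helper tasks), `models`, `leakageAudit` and the `plan`.
#' @export
runCrossValidation <- function(am, mols, plan,
                               model = c("gcn_multi", "gcn_single",
                                         "dense_multi", "dense_single"),
                               includeHelpers = TRUE, config = NULL,
                               seed = 1L, verbose = FALSE) {
  model <- match.arg(model)
  helper <- isHelper(am)
  codes <- if (includeHelpers) taskCodes(am) else
    taskCodes(am)[!helper]
  am <- .subsetTasks(am, codes)
  helper <- isHelper(am)
  single <- endsWith(model, "single")
  folds <- if (plan@strategy %in% c("cluster", "random"))
    sort(unique(plan@fold[plan@fold != -1L])) else 0L

  fold_metrics <- list()
  models <- list()
  audit_ok <- TRUE
  for (f in folds) {
    selres <- splitSelection(plan, am, fold = f)
    trainRows <- selres$trainRows
    evalCells <- selres$evalCells
    if (any(colSums(assayMask(am)[trainRows, , drop = FALSE]) == 0))
      stop("fold ", f, " leaves a task without training examples")
    trainKeys <- rownames(am)[trainRows]
    evalKeys <- rownames(am)[rowSums(evalCells) > 0]
    audit_ok <- audit_ok && length(intersect(trainKeys, evalKeys)) == 0
    task_sets <- if (single) as.list(codes[!helper]) else list(codes)
    pred <- matrix(NA_real_, nrow(am), ncol(am),
                   dimnames = dimnames(assayMask(am)))
    fold_models <- list()
    for (ts in task_sets) {
      amk <- .subsetTasks(am, ts)
      mod <- .newModelFor(model, ts, config, seed = seed + f)
      mod <- fitModel(mod, amk, train = trainRows, mols = mols,
                      seed = seed + 1000L * f, verbose = verbose)
      p <- predictTasks(mod, mols[evalKeys], scale = "model")
      pred[evalKeys, ts] <- p
      fold_models[[paste(ts, collapse = "+")]] <- mod
    }
    fold_metrics[[as.character(f)]] <-
      taskMetrics(pred, assayValues(am), evalCells)
    models[[as.character(f)]] <- fold_models
    if (verbose) message("fold ", f, " done")
  }
  report <- metricsReport(fold_metrics)
  report$average <- report$average[!helper[report$average$code], ,
                                   drop = FALSE]
  list(report = report, models = models, leakageAudit = audit_ok,
       plan = plan)
}

#' Helper-task ablation
#'
#' Runs the multitask model with and without the helper endpoints over
#' several seeds and reports the seed-wise held-out performance difference
#' on a small endpoint of interest. The direction of the difference is
#' computed and logged, not asserted: it quantifies how much the helper
#' tasks support the small task on this particular data set.
#'
#' @param am an [AssayMatrix-class] containing helper tasks.
#' @param mols named list of standardized molecules.
#' @param plan a [SplitPlan-class]; evaluation uses the external test set
#'   (`fold = -1`).
#' @param smallTask endpoint code to report (default `"LOP"`).
#' @param seeds integer vector of seeds to average over.
#' @param model `"gcn_multi"` or `"dense_multi"`.
#' @param config optional model config.
#' @return data.frame with one row per seed (`r2_with`, `r2_without`,
#'   `delta`) plus attribute `summary` (mean delta).
#' @export
helperTaskAblation <- function(am, mols, plan, smallTask = "LOP",
                               seeds = 1:10,
                               model = c("gcn_multi", "dense_multi"),
                               config = NULL) {
  model <- match.arg(model)
  selres <- splitSelection(plan, am, fold = -1L)
  trainRows <- selres$trainRows
  evalCells <- selres$evalCells
  evalKeys <- rownames(am)[evalCells[, smallTask]]
  obs <- assayValues(am)[evalKeys, smallTask]
  one <- function(seed, withHelpers) {
    codes <- if (withHelpers) taskCodes(am) else
      taskCodes(am)[!isHelper(am)]
    amk <- .subsetTasks(am, codes)
    mod <- .newModelFor(model, codes, config, seed = seed)
    mod <- fitModel(mod, amk, train = trainRows, mols = mols, seed = seed)
    p <- predictTasks(mod, mols[evalKeys], scale = "model")[, smallTask]
    r2(p, obs)
  }
  rows <- lapply(seeds, function(s) {
    data.frame(seed = s, r2_with = one(s, TRUE),
               r2_without = one(s, FALSE))
  })
  out <- do.call(rbind, rows)
  out$delta <- out$r2_with - out$r2_without
  message(sprintf(
    "helper-task ablation on %s: mean delta r2 = %+.3f over %d seed(s)",
    smallTask, mean(out$delta), length(seeds)))
  attr(out, "summary") <- c(mean_delta = mean(out$delta))
  out
}
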