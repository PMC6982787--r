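# Shared training loop: minibatch Adam over shuffled compounds with the
# masked multitask loss on standardized targets.

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Standardized target matrix + mask restricted to given rows; target NA -> 0
# so it never contributes (the mask guarantees zero gradient there).
.targetsFor <- function(am, rows) {
  z <- SummarizedExperiment::assay(am, "z")[rows, , drop = FALSE]
  mask <- assayMask(am)[rows, , drop = FALSE]
  z[!mask] <- 0
  list(z = z, mask = mask)
}

.trainLoop <- function(params, config, nTrain, step_fun, lr_fun, seed,
                       verbose = FALSE) {
  state <- .adamInit(params)
  history <- list()
  nb <- max(1L, ceiling(nTrain / config$batchSize))
  step <- 0L
  best_epoch_loss <- Inf
  lr_scale <- 1
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(nTrain)
    epoch_loss <- 0; used <- 0L
    for (bi in seq_len(nb)) {
      idx <- perm[((bi - 1L) * config$batchSize + 1L):
                  min(bi * config$batchSize, nTrain)]
      lr <- lr_fun(step, lr_scale)
      res <- step_fun(params, idx)
      if (is.null(res)) next  # batch with no labeled cell
      if (!is.finite(res$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      upd <- .adamStep(params, res$grads, state, lr)
      params <- upd$params; state <- upd$state
      step <- step + 1L
      epoch_loss <- epoch_loss + res$loss * length(idx)
      used <- used + length(idx)
    }
    epoch_loss <- epoch_loss / max(used, 1L)
    history[[epoch]] <- data.frame(epoch = epoch, step = step,
                                   loss = epoch_loss,
                                   lr = lr_fun(step, lr_scale))
    if (!is.null(attr(lr_fun, "plateau")) && epoch > 1) {
      if (epoch_loss > 0.999 * best_epoch_loss)
        lr_scale <- max(lr_scale * 0.5, 1e-3)
    }
    best_epoch_loss <- min(best_epoch_loss, epoch_loss)
    if (verbose) message(sprintf("epoch %3d  loss %.5f", epoch, epoch_loss))
  }
  list(params = params, history = do.call(rbind, history))
}

.resolveTrain <- function(am, train) {
  if (is.null(train)) rep(TRUE, nrow(am))
  else if (is.logical(train)) train
  else rownames(am) %in% train
}

#' @describeIn fitModel train the graph convolutional model. `mols` is a
#'   named list of [Molecule-class] covering the training compounds (or
#'   `graphs`, a named list of pre-featurized [MolecularGraph-class]).
setMethod("fitModel", "GraphConvModel",
  function(object, am, train = NULL, mols = NULL, graphs = NULL,
           seed = 1L, verbose = FALSE) {
    sel <- .resolveTrain(am, train)
    am <- standardizeTasks(am, train = sel)
    keys <- rownames(am)[sel]
    if (is.null(graphs)) {
      if (is.null(mols)) stop("supply mols or graphs")
      graphs <- lapply(mols[keys], molToGraph)
    } else graphs <- graphs[keys]
    tg <- .targetsFor(am, keys)
    sizes <- colSums(assayMask(am)[sel, , drop = FALSE])
    config <- object@config
    lr_fun <- function(step, scale)
      config$learningRate *
        config$lrDecayFactor^(step %/% config$lrDecayEvery)
    step_fun <- function(params, idx) {
      mask <- tg$mask[idx, , drop = FALSE]
      if (!any(mask)) return(NULL)
      pack <- .packGraphs(graphs[idx])
      fwd <- .gcnForward(params, config, pack)
      lg <- .maskedLossGrad(fwd$yhat, tg$z[idx, , drop = FALSE], mask,
                            weighting = config$weighting,
                            taskSizes = sizes, perBatch = config$perBatch)
      list(loss = lg$loss,
           grads = .gcnBackward(params, config, pack, fwd$cache, lg$grad))
    }
    fit <- .withSeed(seed,
      .trainLoop(object@params, config, length(keys), step_fun, lr_fun,
                 seed, verbose))
    object@params <- fit$params
    object@history <- fit$history
    st <- scalers(am)
    st$transform <- SummarizedExperiment::colData(am)$transform[
      match(st$code, colnames(am))]
    object@scalers <- list(table = st)
    object
  })

#' @describeIn fitModel train the fully connected model. `fps` is a count
#'   fingerprint matrix with rownames = compound keys (or `mols`, from
#'   which fingerprints are computed at the configured width).
setMethod("fitModel", "DenseNetModel",
  function(object, am, train = NULL, mols = NULL, fps = NULL,
           seed = 1L, verbose = FALSE) {
    sel <- .resolveTrain(am, train)
    am <- standardizeTasks(am, train = sel)
    keys <- rownames(am)[sel]
    config <- object@config
    if (is.null(fps)) {
      if (is.null(mols)) stop("supply mols or fps")
      fps <- fingerprintMatrix(mols[keys], nBits = config$inputDim)
    } else fps <- fps[keys, , drop = FALSE]
    if (ncol(fps) != config$inputDim)
      stop("fingerprint width does not match config$inputDim")
    tg <- .targetsFor(am, keys)
    sizes <- colSums(assayMask(am)[sel, , drop = FALSE])
    lr_fun <- structure(function(step, scale)
      config$learningRate * scale, plateau = TRUE)
    step_fun <- function(params, idx) {
      mask <- tg$mask[idx, , drop = FALSE]
      if (!any(mask)) return(NULL)
      X <- inputNoise(fps[idx, , drop = FALSE], p = config$inputNoiseP,
                      sd = config$noiseSD)
      dm <- .denseDropMasks(config, length(idx))
      fwd <- .denseForward(params, X, config, dropMasks = dm)
      lg <- .maskedLossGrad(fwd$yhat, tg$z[idx, , drop = FALSE], mask,
                            weighting = config$weighting,
                            taskSizes = sizes, perBatch = config$perBatch)
      grads <- .denseBackward(params, config, fwd$cache, lg$grad,
                              dropMasks = dm)
      if (config$weightDecay > 0)
        for (nm in names(grads))
          if (startsWith(nm, "W"))
            grads[[nm]] <- grads[[nm]] + config$weightDecay * params[[nm]]
      list(loss = lg$loss, grads = grads)
    }
    fit <- .withSeed(seed,
      .trainLoop(object@params, config, length(keys), step_fun, lr_fun,
                 seed, verbose))
    object@params <- fit$params
    object@history <- fit$history
    st <- scalers(am)
    st$transform <- SummarizedExperiment::colData(am)$transform[
      match(st$code, colnames(am))]
    object@scalers <- list(table = st)
    object
  })

.unscalePredictions <- function(object, Y, scale, mw) {
  colnames(Y) <- object@taskCodes
  if (scale == "standardized") return(Y)
  st <- object@scalers$table
  if (is.null(st)) stop("model has no fitted scalers; train it first")
  st <- st[match(object@taskCodes, st$code), ]
  Y <- sweep(sweep(Y, 2, st$sd, "*"), 2, st$mean, "+")
  if (scale == "model") return(Y)
  tr <- st$transform
  if (is.null(tr)) stop("assay-scale predictions need transform info")
  for (j in seq_len(ncol(Y)))
    Y[, j] <- invertModelScale(Y[, j], tr[j], scaler = NULL,
                               molWeight = mw)
  Y
}

#' @describeIn predictTasks predictions of the graph convolutional model
#'   for a list of [Molecule-class] or [MolecularGraph-class] objects.
setMethod("predictTasks", "GraphConvModel",
  function(object, newdata, scale = c("standardized", "model", "assay"),
           mw = NULL, batchSize = 256L) {
    scale <- match.arg(scale)
    if (is(newdata, "Molecule") || is(newdata, "MolecularGraph"))
      newdata <- list(newdata)
    graphs <- lapply(newdata, function(x)
      if (is(x, "MolecularGraph")) x else molToGraph(x))
    n <- length(graphs)
    out <- matrix(NA_real_, n, object@config$nTasks)
    for (start in seq(1L, n, by = batchSize)) {
      idx <- start:min(start + batchSize - 1L, n)
      pack <- .packGraphs(graphs[idx])
      out[idx, ] <- .gcnForward(object@params, object@config, pack)$yhat
    }
    rn <- names(newdata)
    rownames(out) <- rn
    .unscalePredictions(object, out, scale, mw)
  })

#' @describeIn predictTasks predictions of the fully connected model for a
#'   fingerprint count matrix or a list of [Molecule-class] objects. The
#'   input-noise probability is forced to zero and dropout is disabled, so
#'   inference is deterministic.
setMethod("predictTasks", "DenseNetModel",
  function(object, newdata, scale = c("standardized", "model", "assay"),
           mw = NULL) {
    scale <- match.arg(scale)
    config <- object@config
    fps <- if (is.matrix(newdata)) newdata else
      fingerprintMatrix(newdata, nBits = config$inputDim)
    X <- inputNoise(fps, p = 0, sd = config$noiseSD)
    Y <- .denseForward(object@params, X, config, dropMasks = NULL)$yhat
    rownames(Y) <- rownames(fps)
    .unscalePredictions(object, Y, scale, mw)
  })

setMethod("show", "ADMETModel", function(object) {
  cat(class(object), "for", length(object@taskCodes), "task(s):",
      paste(object@taskCodes, collapse = ", "), "\n")
  trained <- nrow(object@history) > 0
  cat(" ", if (trained) sprintf("trained, final loss %.5f",
                                utils::tail(object@history$loss, 1))
      else "untrained", "\n")
})

#' @rdname taskCodes
setMethod("taskCodes", "ADMETModel", function(x) x@taskCodes)

#' @rdname scalers
setMethod("scalers", "ADMETModel", function(x) x@scalers$table)

#' Save or load a model checkpoint
#'
#' Checkpoints are plain-text YAML archives holding the configuration, task
#' codes, per-task scalers and all weight matrices, so they survive
#' source-only distribution.
#'
#' @param object a fitted [ADMETModel-class].
#' @param file path to the checkpoint file.
#' @return `loadCheckpoint` returns the restored model.
#' @export
saveCheckpoint <- function(object, file) {
  stopifnot(is(object, "ADMETModel"))
  payload <- list(
    class = class(object),
    config = unclass(object@config),
    taskCodes = object@taskCodes,
    scalers = if (!is.null(object@scalers$table))
      as.list(object@scalers$table) else NULL,
    params = lapply(object@params, function(p)
      list(dim = dim(p), values = as.numeric(p))))
  yaml::write_yaml(payload, file, precision = 17)
  invisible(file)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(file) {
  y <- yaml::read_yaml(file)
  config <- y$config
  class(config) <- if (y$class == "GraphConvModel") "graphConvConfig"
                   else "denseNetConfig"
  params <- lapply(y$params, function(p) {
    v <- as.numeric(p$values)
    if (!is.null(p$dim) && length(p$dim) == 2)
      matrix(v, p$dim[[1]], p$dim[[2]]) else v
  })
  obj <- new(y$class, config = config, params = params,
             taskCodes = as.character(y$taskCodes),
             scalers = if (!is.null(y$scalers))
               list(table = as.data.frame(y$scalers,
                                          stringsAsFactors = FALSE))
             else list(),
             history = data.frame())
  obj
}

#' Write predictions as CSV in assay units
#'
#' @param pred prediction matrix from [predictTasks()] (rownames =
#'   compound ids).
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writePredictions <- function(pred, file) {
  df <- data.frame(compound_id = rep(rownames(pred), ncol(pred)),
                   endpoint = rep(colnames(pred), each = nrow(pred)),
                   prediction = as.vector(pred))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
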