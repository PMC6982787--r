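# Fully connected fingerprint networks: pyramidal rectifier stack with
# decreasing dropout, He-initialized weights, output bias at -1, and the
# input-noise scheme that "drops in" plausible fingerprint counts before a
# tanh squashing of the inputs.

#' Configuration of the fully connected network
#'
#' Defaults follow the pyramidal architecture used for fingerprint
#' regression: hidden layers 2000/1000/500/100 with dropout
#' 0.5/0.5/0.25/0, rectifier activations, He weight initialization, hidden
#' biases 0 and output bias -1. Input counts are perturbed (probability
#' `inputNoiseP` per element, replacement = `|round(N(0, noiseSD))|`) and
#' squashed by tanh; at inference the noise probability is forced to zero.
#' The learning-rate schedule halves the rate when the epoch training loss
#' stops improving; weight decay and batch size are tunable defaults.
#'
#' @param nTasks number of output units.
#' @param inputDim fingerprint width (1024 or 2048).
#' @param hiddenDims,dropout parallel vectors of layer sizes and dropout
#'   rates.
#' @param inputNoiseP per-element replacement probability (0.02 works well
#'   for single-task, 0.01 for multitask models).
#' @param noiseSD standard deviation of the pre-rounding normal noise
#'   source.
#' @param outputBiasInit initial output bias.
#' @param learningRate,weightDecay,batchSize,epochs optimizer settings
#'   (Adam).
#' @param weighting,perBatch multitask loss weighting (see
#'   [maskedMultitaskMSE()]).
#' @return a validated config list of class `denseNetConfig`.
#' @export
denseNetConfig <- function(nTasks = 1L, inputDim = 2048L,
                           hiddenDims = c(2000L, 1000L, 500L, 100L),
                           dropout = c(0.5, 0.5, 0.25, 0),
                           inputNoiseP = 0.02, noiseSD = 3,
                           outputBiasInit = -1, learningRate = 1e-3,
                           weightDecay = 1e-5, batchSize = 128L,
                           epochs = 40L,
                           weighting = c("simple", "balanced"),
                           perBatch = FALSE) {
  stopifnot(length(hiddenDims) == length(dropout),
            all(dropout >= 0 & dropout < 1),
            inputNoiseP >= 0, inputNoiseP <= 1, nTasks >= 1)
  structure(list(nTasks = as.integer(nTasks), inputDim = as.integer(inputDim),
                 hiddenDims = as.integer(hiddenDims), dropout = dropout,
                 inputNoiseP = inputNoiseP, noiseSD = noiseSD,
                 outputBiasInit = outputBiasInit,
                 learningRate = learningRate, weightDecay = weightDecay,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 weighting = match.arg(weighting), perBatch = perBatch),
            class = "denseNetConfig")
}

#' Sample fingerprint-count replacement noise
#'
#' The input-noise source: draws from a zero-mean normal distribution with
#' standard deviation `sd`, then rounds and takes the absolute value to
#' yield plausible non-negative integer counts.
#'
#' @param n number of draws.
#' @param sd standard deviation of the underlying normal (default 3).
#' @param preRounding if `TRUE`, return the raw normal samples before
#'   rounding/absolute value (useful for checking the noise source itself).
#' @return numeric vector of length `n`.
#' @export
sampleNoiseCounts <- function(n, sd = 3, preRounding = FALSE) {
  z <- stats::rnorm(n, mean = 0, sd = sd)
  if (preRounding) z else abs(round(z))
}

#' Apply input noise and tanh squashing to fingerprint counts
#'
#' Each element is replaced, independently with probability `p`, by a
#' random non-negative integer count drawn as `|round(N(0, sd))|`; tanh is
#' applied afterwards to smooth the inputs. With `p = 0` (the inference
#' setting) the result is exactly `tanh(counts)`.
#'
#' @param fp numeric vector or matrix of non-negative counts.
#' @param p per-element replacement probability in `[0, 1]`.
#' @param sd noise standard deviation (default 3).
#' @return numeric object of the same shape as `fp`.
#' @examples
#' inputNoise(c(0, 1, 4), p = 0)  # tanh of the counts
#' @export
inputNoise <- function(fp, p, sd = 3) {
  if (p < 0 || p > 1) stop("noise probability must be in [0, 1]")
  if (any(fp < 0)) stop("fingerprint counts must be non-negative")
  x <- fp
  if (p > 0) {
    n <- length(x)
    repl <- stats::runif(n) < p
    x[repl] <- sampleNoiseCounts(sum(repl), sd = sd)
  }
  tanh(x)
}

# He-initialized parameter set for the dense net.
.initDense <- function(config) {
  dims <- c(config$inputDim, config$hiddenDims, config$nTasks)
  L <- length(dims) - 1L
  params <- list()
  for (l in seq_len(L)) {
    params[[paste0("W", l)]] <- matrix(
      stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
      dims[l], dims[l + 1])
    params[[paste0("b", l)]] <- rep(
      if (l == L) config$outputBiasInit else 0, dims[l + 1])
  }
  params
}

# Forward pass. X is the already noised+tanh input (batch x inputDim).
# dropMasks: list of per-layer retained-unit masks scaled by 1/keep
# (inverted dropout), or NULL at inference.
.denseForward <- function(params, X, config, dropMasks = NULL) {
  L <- length(config$hiddenDims)
  H <- X
  cache <- list(H = vector("list", L + 1L))
  cache$H[[1]] <- H
  for (l in seq_len(L)) {
    Z <- H %*% params[[paste0("W", l)]]
    Z <- sweep(Z, 2, params[[paste0("b", l)]], "+")
    H <- Z * (Z > 0)
    if (!is.null(dropMasks) && config$dropout[l] > 0)
      H <- H * dropMasks[[l]]
    cache$H[[l + 1]] <- H
  }
  Y <- sweep(H %*% params[[paste0("W", L + 1)]], 2,
             params[[paste0("b", L + 1)]], "+")
  cache$Y <- Y
  list(yhat = Y, cache = cache)
}

.denseBackward <- function(params, config, cache, dY, dropMasks = NULL) {
  L <- length(config$hiddenDims)
  grads <- list()
  dH <- dY
  for (l in rev(seq_len(L + 1L))) {
    Hin <- cache$H[[l]]
    grads[[paste0("W", l)]] <- crossprod(Hin, dH)
    grads[[paste0("b", l)]] <- colSums(dH)
    if (l > 1) {
      dH <- dH %*% t(params[[paste0("W", l)]])
      # backprop through dropout then ReLU of layer l-1
      if (!is.null(dropMasks) && config$dropout[l - 1] > 0)
        dH <- dH * dropMasks[[l - 1]]
      dH <- dH * (cache$H[[l]] > 0)
    }
  }
  grads
}

.denseDropMasks <- function(config, batchSize) {
  lapply(seq_along(config$hiddenDims), function(l) {
    p <- config$dropout[l]
    if (p == 0) return(NULL)
    keep <- 1 - p
    matrix((stats::runif(batchSize * config$hiddenDims[l]) < keep) / keep,
           batchSize, config$hiddenDims[l])
  })
}

#' Construct an untrained fully connected model
#'
#' @param taskCodes character vector of endpoint codes to model.
#' @param config a [denseNetConfig()] (its `nTasks` is overridden by
#'   `length(taskCodes)`).
#' @param seed integer seed for the He initialization.
#' @return a [DenseNetModel-class].
#' @export
denseNetModel <- function(taskCodes, config = denseNetConfig(),
                          seed = 1L) {
  config$nTasks <- length(taskCodes)
  params <- .withSeed(seed, .initDense(config))
  new("DenseNetModel", config = config, params = params,
      taskCodes = taskCodes, scalers = list(),
      history = data.frame())
}
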