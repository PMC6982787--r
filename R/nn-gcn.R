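# Duvenaud-style graph convolutional regression networks. Node features are
# propagated along bonds by affine transformations of the atom itself and
# the sum of its neighbors; after two convolutions and a per-atom dense
# layer, mean and max readouts over atoms are concatenated and squashed by
# tanh into a fixed-length molecule embedding feeding linear task heads.

#' Configuration of the graph convolutional network
#'
#' Defaults follow the architecture recommended for ADMET regression: two
#' graph convolution steps of 128 units with rectifier activations, a
#' per-atom dense layer of 256 units, mean/max readout to a 512-dimensional
#' molecule embedding, learning rate 0.001, batch size 128, 40 epochs, and
#' exponential learning-rate decay every 1000 steps (factor
#' `lrDecayFactor`, default 0.95). The same architecture and
#' hyperparameters serve single- and multitask models.
#'
#' `degreeWeights = TRUE` switches the shared neighbor matrix to
#' degree-specific neighbor matrices (one per heavy-atom degree bucket), for
#' fidelity to the original neural-fingerprint formulation; the default is
#' a single shared weight pair per layer. `graphPool` and `batchNorm`
#' (present in some implementations) are accepted as configuration keys but
#' are not implemented and must remain `FALSE` -- they are never silently
#' active.
#'
#' @param nTasks number of output units.
#' @param convDims widths of the two convolution steps.
#' @param denseDim per-atom dense width (readout width is `2 * denseDim`).
#' @param learningRate,batchSize,epochs optimizer settings (Adam).
#' @param lrDecayEvery,lrDecayFactor step interval and factor of the
#'   exponential learning-rate decay.
#' @param degreeWeights,maxDegree degree-specific neighbor weights and the
#'   degree bucket cap.
#' @param graphPool,batchNorm unimplemented compatibility flags.
#' @param weighting,perBatch multitask loss weighting (see
#'   [maskedMultitaskMSE()]).
#' @return a validated config list of class `graphConvConfig`.
#' @export
graphConvConfig <- function(nTasks = 1L, convDims = c(128L, 128L),
                            denseDim = 256L, learningRate = 1e-3,
                            batchSize = 128L, epochs = 40L,
                            lrDecayEvery = 1000L, lrDecayFactor = 0.95,
                            degreeWeights = FALSE, maxDegree = 6L,
                            graphPool = FALSE, batchNorm = FALSE,
                            weighting = c("simple", "balanced"),
                            perBatch = FALSE) {
  stopifnot(length(convDims) == 2, nTasks >= 1)
  if (isTRUE(graphPool) || isTRUE(batchNorm))
    stop("graphPool/batchNorm layers are not implemented; leave them FALSE")
  structure(list(nTasks = as.integer(nTasks),
                 convDims = as.integer(convDims),
                 denseDim = as.integer(denseDim),
                 readoutDim = 2L * as.integer(denseDim),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 lrDecayEvery = as.integer(lrDecayEvery),
                 lrDecayFactor = lrDecayFactor,
                 degreeWeights = degreeWeights,
                 maxDegree = as.integer(maxDegree),
                 graphPool = FALSE, batchNorm = FALSE,
                 weighting = match.arg(weighting), perBatch = perBatch),
            class = "graphConvConfig")
}

#' One graph convolution step
#'
#' `h'_v = ReLU(W_self h_v + W_nb sum_{u in N(v)} h_u + b)`. The neighbor
#' sum makes the operation independent of atom numbering; an isolated node
#' reduces to `ReLU(W_self h + b)`.
#'
#' @param H node feature matrix (atoms x width).
#' @param A symmetric adjacency matrix (zero diagonal).
#' @param Wself,Wnb,b affine parameters; input rows of both weight
#'   matrices must match `ncol(H)`.
#' @return new node feature matrix (atoms x `ncol(Wself)`).
#' @export
graphConvLayer <- function(H, A, Wself, Wnb, b) {
  if (ncol(H) != nrow(Wself) || ncol(H) != nrow(Wnb))
    stop("node feature width does not match layer input width")
  Z <- H %*% Wself + as.matrix(A %*% H) %*% Wnb
  Z <- sweep(Z, 2, b, "+")
  Z * (Z > 0)
}

#' Mean/max readout to a molecule embedding
#'
#' Averages the learned atom features and takes their per-feature maximum,
#' concatenates both and applies tanh, yielding an embedding of length
#' `2 * ncol(H)` with every entry strictly inside (-1, 1). Invariant to
#' atom order; for a single-atom molecule the two halves coincide.
#'
#' @param H learned node features (atoms x width), at least one atom.
#' @return numeric vector of length `2 * ncol(H)`.
#' @export
readout <- function(H) {
  if (!is.matrix(H) || nrow(H) < 1) stop("readout needs at least one atom")
  tanh(c(colMeans(H), apply(H, 2, max)))
}

# --- batch packing -------------------------------------------------------

# Stack a list of MolecularGraph into one block-diagonal system.
.packGraphs <- function(graphs) {
  ns <- vapply(graphs, function(g) nrow(g@nodeFeatures), integer(1))
  offs <- cumsum(c(0L, ns[-length(ns)]))
  H0 <- do.call(rbind, lapply(graphs, function(g) g@nodeFeatures))
  trip <- lapply(seq_along(graphs), function(k) {
    Tm <- methods::as(methods::as(graphs[[k]]@adjacency, "generalMatrix"),
                      "TsparseMatrix")
    cbind(Tm@i + 1L, Tm@j + 1L) + offs[k]
  })
  ij <- do.call(rbind, trip)
  N <- sum(ns)
  A <- if (length(ij) && nrow(ij))
    Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1, dims = c(N, N))
  else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(N, N))
  molIndex <- rep(seq_along(graphs), ns)
  list(H0 = H0, A = A, molIndex = molIndex, n = ns,
       rows = split(seq_len(N), molIndex), B = length(graphs),
       degrees = unlist(lapply(graphs, function(g) g@degrees)))
}

.heMat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

.initGCN <- function(config) {
  d <- c(75L, config$convDims, config$denseDim)
  params <- list()
  for (l in 1:2) {
    params[[paste0("Wself", l)]] <- .heMat(d[l], d[l + 1])
    if (config$degreeWeights) {
      for (k in 0:config$maxDegree)
        params[[paste0("Wnb", l, "_", k)]] <- .heMat(d[l], d[l + 1])
    } else {
      params[[paste0("Wnb", l)]] <- .heMat(d[l], d[l + 1])
    }
    params[[paste0("bconv", l)]] <- rep(0, d[l + 1])
  }
  params$Wdense <- .heMat(d[3], d[4])
  params$bdense <- rep(0, d[4])
  params$Wout <- .heMat(2L * config$denseDim, config$nTasks)
  params$bout <- rep(0, config$nTasks)
  params
}

# neighbor aggregation with optional degree-specific weights
.convStep <- function(params, config, l, H, pack) {
  S <- as.matrix(pack$A %*% H)
  Z <- H %*% params[[paste0("Wself", l)]]
  if (config$degreeWeights) {
    dg <- pmin(pack$degrees, config$maxDegree)
    for (k in unique(dg)) {
      sel <- dg == k
      Z[sel, ] <- Z[sel, , drop = FALSE] +
        S[sel, , drop = FALSE] %*% params[[paste0("Wnb", l, "_", k)]]
    }
  } else {
    Z <- Z + S %*% params[[paste0("Wnb", l)]]
  }
  Z <- sweep(Z, 2, params[[paste0("bconv", l)]], "+")
  list(Z = Z, H = Z * (Z > 0), S = S)
}

.gcnForward <- function(params, config, pack) {
  c1 <- .convStep(params, config, 1L, pack$H0, pack)
  c2 <- .convStep(params, config, 2L, c1$H, pack)
  Z3 <- sweep(c2$H %*% params$Wdense, 2, params$bdense, "+")
  H3 <- Z3 * (Z3 > 0)
  B <- pack$B; d <- config$denseDim
  M <- rowsum(H3, pack$molIndex) / pack$n
  X <- matrix(0, B, d)
  amax <- matrix(0L, B, d)
  for (k in seq_len(B)) {
    Hm <- H3[pack$rows[[k]], , drop = FALSE]
    am <- max.col(t(Hm), ties.method = "first")
    amax[k, ] <- pack$rows[[k]][am]
    X[k, ] <- Hm[cbind(am, seq_len(d))]
  }
  E <- tanh(cbind(M, X))
  Y <- sweep(E %*% params$Wout, 2, params$bout, "+")
  list(yhat = Y,
       cache = list(c1 = c1, c2 = c2, H3 = H3, E = E, amax = amax))
}

.gcnBackward <- function(params, config, pack, cache, dY) {
  d <- config$denseDim
  grads <- list(Wout = crossprod(cache$E, dY), bout = colSums(dY))
  dE <- dY %*% t(params$Wout)
  dPre <- dE * (1 - cache$E^2)
  dM <- dPre[, seq_len(d), drop = FALSE]
  dX <- dPre[, d + seq_len(d), drop = FALSE]
  dH3 <- (dM / pack$n)[pack$molIndex, , drop = FALSE]
  idx <- cbind(as.vector(cache$amax), rep(seq_len(d), each = pack$B))
  dH3[idx] <- dH3[idx] + as.vector(dX)
  dZ3 <- dH3 * (cache$H3 > 0)
  grads$Wdense <- crossprod(cache$c2$H, dZ3)
  grads$bdense <- colSums(dZ3)
  dH2 <- dZ3 %*% t(params$Wdense)

  backConv <- function(l, Hin, conv, dH) {
    dZ <- dH * (conv$H > 0)
    grads[[paste0("Wself", l)]] <<- crossprod(Hin, dZ)
    grads[[paste0("bconv", l)]] <<- colSums(dZ)
    if (config$degreeWeights) {
      dg <- pmin(pack$degrees, config$maxDegree)
      dS <- matrix(0, nrow(dZ), ncol(Hin))
      for (k in unique(dg)) {
        sel <- dg == k
        grads[[paste0("Wnb", l, "_", k)]] <<-
          crossprod(conv$S[sel, , drop = FALSE], dZ[sel, , drop = FALSE])
        dS[sel, ] <- dZ[sel, , drop = FALSE] %*%
          t(params[[paste0("Wnb", l, "_", k)]])
      }
      for (k in 0:config$maxDegree)
        if (!k %in% unique(dg))
          grads[[paste0("Wnb", l, "_", k)]] <<-
            matrix(0, ncol(Hin), ncol(dZ))
      dZ %*% t(params[[paste0("Wself", l)]]) +
        as.matrix(pack$A %*% dS)
    } else {
      grads[[paste0("Wnb", l)]] <<- crossprod(conv$S, dZ)
      dZ %*% t(params[[paste0("Wself", l)]]) +
        as.matrix(pack$A %*% (dZ %*% t(params[[paste0("Wnb", l)]])))
    }
  }
  dH1 <- backConv(2L, cache$c1$H, cache$c2, dH2)
  invisible(backConv(1L, pack$H0, cache$c1, dH1))
  grads
}

#' Construct an untrained graph convolutional model
#'
#' @param taskCodes character vector of endpoint codes to model.
#' @param config a [graphConvConfig()] (its `nTasks` is overridden by
#'   `length(taskCodes)`).
#' @param seed integer seed for the He initialization.
#' @return a [GraphConvModel-class].
#' @export
graphConvModel <- function(taskCodes, config = graphConvConfig(),
                           seed = 1L) {
  config$nTasks <- length(taskCodes)
  params <- .withSeed(seed, .initGCN(config))
  new("GraphConvModel", config = config, params = params,
      taskCodes = taskCodes, scalers = list(), history = data.frame())
}
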