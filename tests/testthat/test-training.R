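test_that("the fully connected net solves a linear fingerprint problem", {
  # generator with known signal-to-noise: y linear in tanh(counts) plus
  # small noise, so ridge regression (independent oracle) nearly saturates
  set.seed(20)
  n <- 700; d <- 64
  X <- matrix(rpois(n * d, 0.5), n, d)
  w <- rnorm(d, sd = 0.5) * (runif(d) < 0.4)
  y <- as.vector(tanh(X) %*% w) + rnorm(n, 0, 0.05)
  tr <- seq_len(600); te <- 601:n
  am <- singleTaskMatrix(y)
  rownames(X) <- rownames(am)
  ridge <- glmnet::cv.glmnet(tanh(X[tr, ]), y[tr], alpha = 0)
  oracle <- r2(as.vector(predict(ridge, tanh(X[te, ]))), y[te])
  expect_gte(oracle, 0.95)
  cfg <- denseNetConfig(nTasks = 1, inputDim = 64L,
                        hiddenDims = c(128L, 32L), dropout = c(0, 0),
                        inputNoiseP = 0, epochs = 40L, batchSize = 32L)
  mod <- fitModel(denseNetModel("T1", cfg, seed = 4), am,
                  train = rownames(am)[tr], fps = X, seed = 8)
  pred <- predictTasks(mod, X[te, , drop = FALSE], scale = "model")
  val_r2 <- r2(pred[, 1], y[te])
  expect_gt(val_r2, 0.9)
  expect_lte(val_r2, oracle + 0.02)
})

test_that("epoch-one loss equals the hand-computed masked loss", {
  set.seed(25)
  n <- 40; d <- 32
  X <- matrix(rpois(n * d, 1), n, d)
  y <- rnorm(n)
  am <- singleTaskMatrix(y)
  rownames(X) <- rownames(am)
  # single full batch, no noise, no dropout: the first recorded epoch loss
  # is the loss of the untouched initial parameters
  cfg <- denseNetConfig(nTasks = 1, inputDim = 32L,
                        hiddenDims = c(16L, 8L), dropout = c(0, 0),
                        inputNoiseP = 0, epochs = 1L, batchSize = 64L)
  mod0 <- denseNetModel("T1", cfg, seed = 6)
  mod <- fitModel(mod0, am, fps = X, seed = 7)
  ams <- standardizeTasks(am)
  z <- SummarizedExperiment::assay(ams, "z")
  fwd <- admetnet:::.denseForward(mod0@params, tanh(X), cfg)
  by_hand <- maskedMultitaskMSE(fwd$yhat, z, assayMask(am))
  expect_equal(mod@history$loss[1], by_hand, tolerance = 1e-12)
})

test_that("training is reproducible bit for bit under fixed seeds", {
  set.seed(26)
  n <- 60; d <- 32
  X <- matrix(rpois(n * d, 1), n, d)
  y <- rnorm(n)
  am <- singleTaskMatrix(y)
  rownames(X) <- rownames(am)
  cfg <- denseNetConfig(nTasks = 1, inputDim = 32L,
                        hiddenDims = c(16L, 8L), dropout = c(0.25, 0),
                        inputNoiseP = 0.02, epochs = 3L, batchSize = 16L)
  m1 <- fitModel(denseNetModel("T1", cfg, seed = 3), am, fps = X, seed = 9)
  m2 <- fitModel(denseNetModel("T1", cfg, seed = 3), am, fps = X, seed = 9)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@history, m2@history)
})

test_that("an empty helper task does not break joint training", {
  fx <- fixtureStudy()
  am <- fx$am
  mask <- SummarizedExperiment::assay(am, "mask")
  v <- SummarizedExperiment::assay(am, "values")
  mask[, "LOX"] <- FALSE           # helper task with no example at all
  v[, "LOX"] <- NA_real_
  SummarizedExperiment::assay(am, "mask") <- mask
  SummarizedExperiment::assay(am, "values") <- v
  cfg <- graphConvConfig(nTasks = ncol(am), convDims = c(8L, 8L),
                         denseDim = 8L, epochs = 1L, batchSize = 64L)
  # the empty helper never appears in any minibatch, so it is excluded
  # from N by the masking rule and joint training proceeds
  mod <- fitModel(graphConvModel(taskCodes(am), cfg, seed = 1), am,
                  mols = fx$study$mols, seed = 2)
  expect_true(all(is.finite(mod@history$loss)))
  # ... but an empty modeled (non-helper) task is an error
  am_bad <- am
  mask2 <- SummarizedExperiment::assay(am_bad, "mask")
  v2 <- SummarizedExperiment::assay(am_bad, "values")
  mask2[, "LOD"] <- FALSE; v2[, "LOD"] <- NA_real_
  SummarizedExperiment::assay(am_bad, "mask") <- mask2
  SummarizedExperiment::assay(am_bad, "values") <- v2
  expect_error(standardizeTasks(am_bad), "LOD")
})

test_that("divergence is reported as an error, not silent NaN", {
  set.seed(27)
  n <- 30; d <- 16
  X <- matrix(rpois(n * d, 1), n, d)
  y <- rnorm(n)
  am <- singleTaskMatrix(y)
  rownames(X) <- rownames(am)
  cfg <- denseNetConfig(nTasks = 1, inputDim = 16L, hiddenDims = c(8L, 4L),
                        dropout = c(0, 0), inputNoiseP = 0,
                        epochs = 3L, batchSize = 16L)
  mod <- denseNetModel("T1", cfg, seed = 1)
  mod@params$W1[1, 1] <- NaN  # a poisoned weight makes the loss non-finite
  expect_error(fitModel(mod, am, fps = X, seed = 2), "diverged")
})

test_that("checkpoints round trip through plain text", {
  set.seed(28)
  mols <- randomMolecules(6, seed = 71)
  cfg <- graphConvConfig(nTasks = 1, convDims = c(8L, 8L), denseDim = 8L,
                         epochs = 1L, batchSize = 8L)
  y <- rnorm(6)
  am <- singleTaskMatrix(y)
  names(mols) <- rownames(am)
  mod <- fitModel(graphConvModel("T1", cfg, seed = 5), am, mols = mols,
                  seed = 6)
  f <- withr::local_tempfile(fileext = ".yaml")
  saveCheckpoint(mod, f)
  back <- loadCheckpoint(f)
  p1 <- predictTasks(mod, mols, scale = "assay")
  p2 <- predictTasks(back, mols, scale = "assay")
  expect_equal(p2, p1, tolerance = 1e-12)
})
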