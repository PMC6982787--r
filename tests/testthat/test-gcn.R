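test_that("graph convolution layer follows its affine-propagation rule", {
  set.seed(1)
  # isolated node: neighbor sum is empty
  H <- matrix(rnorm(4), 1, 4)
  A <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                            x = numeric(0), dims = c(1, 1))
  Ws <- matrix(rnorm(12), 4, 3); Wn <- matrix(rnorm(12), 4, 3)
  b <- rnorm(3)
  out <- graphConvLayer(H, A, Ws, Wn, b)
  expect_equal(out, pmax(H %*% Ws + rep(1, 1) %o% b, 0))
  # 2-node path with identity weights: each output = ReLU(h_v + h_u)
  H2 <- matrix(c(1, -2, 3, 4), 2, 2)
  A2 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1)
  I2 <- diag(2)
  out2 <- graphConvLayer(H2, A2, I2, I2, c(0, 0))
  expect_equal(out2, pmax(H2 + H2[2:1, ], 0))
  # width mismatch is a configuration error
  expect_error(graphConvLayer(H2, A2, matrix(0, 3, 2), I2, c(0, 0)),
               "width")
})

test_that("readout concatenates mean and max under tanh", {
  set.seed(2)
  H <- matrix(rnorm(5 * 8), 5, 8)
  r <- readout(H)
  expect_length(r, 16)
  expect_true(all(r > -1 & r < 1))
  expect_equal(r, tanh(c(colMeans(H), apply(H, 2, max))))
  # single atom: the two halves coincide
  r1 <- readout(H[1, , drop = FALSE])
  expect_equal(r1[1:8], r1[9:16])
  # identical rows reduce to the single-atom case
  expect_equal(readout(H[c(1, 1, 1), ]), r1)
  expect_error(readout(H[0, , drop = FALSE]), "at least one atom")
})

test_that("embedding dimension chain is 75 -> 128 -> 128 -> 256 -> 512", {
  mod <- graphConvModel("T1")
  p <- mod@params
  expect_equal(dim(p$Wself1), c(75L, 128L))
  expect_equal(dim(p$Wnb1), c(75L, 128L))
  expect_equal(dim(p$Wself2), c(128L, 128L))
  expect_equal(dim(p$Wdense), c(128L, 256L))
  expect_equal(dim(p$Wout), c(512L, 1L))
  expect_equal(mod@config$readoutDim, 2L * mod@config$denseDim)
})

test_that("zero weights force the prediction to the output bias", {
  mols <- randomMolecules(4, seed = 51)
  mod <- graphConvModel(c("A", "B"), graphConvConfig(nTasks = 2))
  mod@params <- lapply(mod@params, function(p) p * 0)
  mod@params$bout <- c(0.7, -0.2)
  pred <- predictTasks(mod, mols, scale = "standardized")
  expect_equal(dim(pred), c(4L, 2L))
  for (i in 1:4) expect_equal(unname(pred[i, ]), c(0.7, -0.2))
})

test_that("predictions are invariant to atom renumbering", {
  mols <- randomMolecules(10, seed = 52)
  mod <- graphConvModel("T1", graphConvConfig(convDims = c(32L, 32L),
                                              denseDim = 16L), seed = 3)
  set.seed(9)
  for (m in mols) {
    m2 <- permuteMolecule(m, sample(nAtoms(m)))
    p1 <- predictTasks(mod, m, scale = "standardized")
    p2 <- predictTasks(mod, m2, scale = "standardized")
    expect_lt(abs(p1 - p2), 1e-5)
  }
})

test_that("backpropagation matches finite-difference gradients", {
  mols <- randomMolecules(3, seed = 53)
  graphs <- lapply(mols, molToGraph)
  cfg <- graphConvConfig(nTasks = 2, convDims = c(8L, 8L), denseDim = 6L)
  for (degw in c(FALSE, TRUE)) {
    cfg$degreeWeights <- degw
    params <- admetnet:::.withSeed(5, admetnet:::.initGCN(cfg))
    pack <- admetnet:::.packGraphs(graphs)
    set.seed(6)
    tgt <- matrix(rnorm(6), 3, 2)
    mask <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE), 3, 2)
    lossOf <- function(p) {
      f <- admetnet:::.gcnForward(p, cfg, pack)
      admetnet:::.maskedLossGrad(f$yhat, tgt, mask,
                                 want_grad = FALSE)$loss
    }
    fwd <- admetnet:::.gcnForward(params, cfg, pack)
    lg <- admetnet:::.maskedLossGrad(fwd$yhat, tgt, mask)
    gr <- admetnet:::.gcnBackward(params, cfg, pack, fwd$cache, lg$grad)
    for (nm in names(params)) {
      p <- params[[nm]]
      for (i in sample(length(p), min(4, length(p)))) {
        eps <- 1e-6
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (lossOf(p1) - lossOf(p2)) / (2 * eps)
        denom <- max(1e-6, abs(num) + abs(gr[[nm]][i]))
        expect_lt(abs(num - gr[[nm]][i]) / denom, 1e-4)
      }
    }
  }
})

test_that("the network can overfit a small batch", {
  mols <- randomMolecules(32, seed = 54)
  set.seed(11)
  y <- vapply(mols, function(m) molDescriptors(m)["nC"], 0) / 10 +
    rnorm(32, 0, 0.05)
  am <- singleTaskMatrix(scale(y)[, 1])
  names(mols) <- rownames(am)
  cfg <- graphConvConfig(nTasks = 1, convDims = c(32L, 32L),
                         denseDim = 32L, epochs = 200L, batchSize = 32L,
                         learningRate = 3e-3)
  mod <- fitModel(graphConvModel("T1", cfg, seed = 2), am, mols = mols,
                  seed = 3)
  h <- mod@history
  expect_lt(h$loss[nrow(h)], 0.1 * h$loss[1])
})

test_that("unimplemented compatibility layers refuse to switch on", {
  expect_error(graphConvConfig(graphPool = TRUE), "not implemented")
  expect_error(graphConvConfig(batchNorm = TRUE), "not implemented")
})
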