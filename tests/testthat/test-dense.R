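test_that("input noise reduces to tanh at p = 0 and replaces counts at p = 1", {
  fp <- c(0, 1, 2, 5, 0, 3)
  expect_equal(inputNoise(fp, p = 0), tanh(fp))
  set.seed(4)
  noisy <- inputNoise(rep(99, 500), p = 1)
  # every element replaced by tanh of a non-negative integer
  expect_true(all(noisy %in% tanh(0:50)))
  expect_error(inputNoise(fp, p = 1.5), "probability")
  expect_error(inputNoise(c(-1, 2), p = 0), "non-negative")
})

test_that("the noise source is |round(N(0, 3))| with the stated spread", {
  set.seed(8)
  pre <- sampleNoiseCounts(1e5, preRounding = TRUE)
  expect_equal(mean(pre), 0, tolerance = 3 * 3 / sqrt(1e5))
  expect_equal(sd(pre), 3, tolerance = 0.05)
  set.seed(8)
  post <- sampleNoiseCounts(1e5)
  expect_identical(post, abs(round(pre)))
  # Monte-Carlo oracle for E|round(N(0,3))| via the normal CDF:
  # P(|round(Z)| = k) mass at integers k
  ks <- 0:40
  pk <- pnorm((ks + 0.5) / 3) - pnorm((ks - 0.5) / 3)
  expected_mean <- sum(ks * 2 * pk[ks + 1] * (ks > 0)) +
    0 * (2 * pnorm(0.5 / 3) - 1)
  se <- sd(post) / sqrt(length(post))
  expect_lt(abs(mean(post) - expected_mean), 3 * se)
})

test_that("a fresh network maps zero input to the output bias of -1", {
  cfg <- denseNetConfig(nTasks = 3, inputDim = 64L,
                        hiddenDims = c(32L, 16L), dropout = c(0.5, 0))
  mod <- denseNetModel(c("A", "B", "C"), cfg, seed = 1)
  x <- matrix(0, 1, 64)
  pred <- predictTasks(mod, x, scale = "standardized")
  expect_equal(unname(pred[1, ]), c(-1, -1, -1))
  expect_equal(dim(pred), c(1L, 3L))
})

test_that("inference is deterministic (noise off, dropout off)", {
  cfg <- denseNetConfig(nTasks = 2, inputDim = 32L,
                        hiddenDims = c(16L, 8L), dropout = c(0.5, 0.25))
  mod <- denseNetModel(c("A", "B"), cfg, seed = 2)
  x <- matrix(rpois(5 * 32, 1), 5, 32)
  p1 <- predictTasks(mod, x, scale = "standardized")
  p2 <- predictTasks(mod, x, scale = "standardized")
  expect_identical(p1, p2)
})

test_that("He initialization roughly preserves activation variance", {
  cfg <- denseNetConfig(nTasks = 1, inputDim = 256L,
                        hiddenDims = c(256L, 128L, 64L, 32L),
                        dropout = c(0, 0, 0, 0))
  params <- admetnet:::.withSeed(3, admetnet:::.initDense(cfg))
  set.seed(5)
  X <- matrix(rnorm(200 * 256), 200, 256)
  # He scaling compensates the halving of variance by the rectifier, so
  # post-ReLU activations keep roughly the input variance
  H1 <- pmax(X %*% params$W1, 0)
  ratio <- var(as.vector(H1)) / var(as.vector(X))
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
  expect_true(all(params$b1 == 0))
  expect_true(all(params$b5 == -1))
})

test_that("default architecture is the 2000/1000/500/100 pyramid", {
  cfg <- denseNetConfig(nTasks = 2)
  expect_equal(cfg$hiddenDims, c(2000L, 1000L, 500L, 100L))
  expect_equal(cfg$dropout, c(0.5, 0.5, 0.25, 0))
  expect_error(denseNetConfig(hiddenDims = c(10L, 20L), dropout = 0.5))
})
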