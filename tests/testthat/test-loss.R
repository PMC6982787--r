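test_that("masked loss reproduces its defining examples", {
  # one task, full mask: plain MSE
  p <- matrix(c(1, 2, 4), 3, 1); o <- matrix(c(1, 1, 1), 3, 1)
  m <- matrix(TRUE, 3, 1)
  expect_equal(maskedMultitaskMSE(p, o, m), mean((p - o)^2))
  # two present tasks, simple weighting, L1 = 4, L2 = 0 -> 2
  p2 <- matrix(c(2, 0), 1); o2 <- matrix(0, 1, 2); m2 <- matrix(TRUE, 1, 2)
  expect_equal(maskedMultitaskMSE(p2, o2, m2), 2)
  # balanced weighting, sizes (1000, 100): weights (1/11, 10/11)
  expect_equal(maskedMultitaskMSE(p2, matrix(c(0, 1), 1), m2,
                                  weighting = "balanced",
                                  taskSizes = c(1000, 100)),
               14 / 11)  # L1 = 4, L2 = 1: (1/11)*4 + (10/11)*1
  p3 <- matrix(c(1, 1), 1); o3 <- matrix(c(0, 1), 1)
  expect_equal(maskedMultitaskMSE(p3, o3, m2, weighting = "balanced",
                                  taskSizes = c(1000, 100)),
               1 / 11)  # L1 = 1, L2 = 0
  p4 <- matrix(c(1, 1), 1); o4 <- matrix(c(0, 0), 1)
  expect_equal(maskedMultitaskMSE(p4, o4, m2, weighting = "balanced",
                                  taskSizes = c(1000, 100)), 1)
  expect_error(maskedMultitaskMSE(p2, o2, matrix(FALSE, 1, 2)),
               "empty mask")
})

test_that("masked loss equals the brute-force double loop", {
  set.seed(13)
  for (rep in 1:200) {
    b <- sample(2:8, 1); T <- sample(1:5, 1)
    pred <- matrix(rnorm(b * T), b, T)
    tgt <- matrix(rnorm(b * T), b, T)
    mask <- matrix(runif(b * T) < 0.6, b, T)
    if (!any(mask)) mask[1, 1] <- TRUE
    sizes <- sample(10:1000, T, replace = TRUE)
    expect_equal(maskedMultitaskMSE(pred, tgt, mask),
                 bruteMaskedLoss(pred, tgt, mask), tolerance = 1e-10)
    expect_equal(maskedMultitaskMSE(pred, tgt, mask,
                                    weighting = "balanced",
                                    taskSizes = sizes),
                 bruteMaskedLoss(pred, tgt, mask, "balanced", sizes),
                 tolerance = 1e-10)
  }
})

test_that("simple and balanced weighting coincide for equal task sizes", {
  set.seed(14)
  pred <- matrix(rnorm(12), 4, 3); tgt <- matrix(rnorm(12), 4, 3)
  mask <- matrix(TRUE, 4, 3)
  expect_equal(maskedMultitaskMSE(pred, tgt, mask),
               maskedMultitaskMSE(pred, tgt, mask, "balanced",
                                  taskSizes = c(50, 50, 50)))
})

test_that("gradients vanish exactly at unmasked cells", {
  set.seed(15)
  pred <- matrix(rnorm(20), 5, 4); tgt <- matrix(rnorm(20), 5, 4)
  mask <- matrix(runif(20) < 0.5, 5, 4)
  mask[, 4] <- FALSE  # a task entirely absent from the batch
  mask[1, 1] <- TRUE
  lg <- admetnet:::.maskedLossGrad(pred, tgt, mask)
  expect_true(all(lg$grad[!mask] == 0))
  expect_equal(lg$weights[4], 0)  # absent task excluded from N
  # per-minibatch balanced variant uses batch counts
  lb <- admetnet:::.maskedLossGrad(pred, tgt, mask,
                                   weighting = "balanced", perBatch = TRUE)
  present <- colSums(mask) > 0
  expect_equal(sum(lb$weights), 1)
  expect_true(all(lb$weights[!present] == 0))
})
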