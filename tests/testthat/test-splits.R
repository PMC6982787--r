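test_that("k-means split recovers well-separated structure", {
  # two synthetic blobs in fingerprint space, inter-blob distance >>
  # intra-blob spread; oracle = the generating labels themselves
  set.seed(23)
  n <- 60
  labels <- rep(1:2, each = n / 2)
  fps <- matrix(rpois(n * 32, 1), n, 32) +
    40 * (labels == 2)  # shift the second blob far away
  rownames(fps) <- paste0("c", seq_len(n))
  y <- rnorm(n)
  am <- singleTaskMatrix(y)
  rownames(fps) <- rownames(am)
  plan <- clusterSplit(fps, am, K = 2L, seed = 5, testFold = 2L)
  memb <- ifelse(plan@fold == -1L, 2L, 1L)
  # recovered partition matches the generator labels (up to relabeling)
  agreement <- max(mean(memb == labels), mean(memb == 3L - labels))
  expect_equal(agreement, 1)
})

test_that("cluster folds partition compounds and cover every task", {
  fx <- fixtureStudy()
  plan <- clusterSplit(fx$fps, fx$am, K = 4L, seed = 3)
  fold <- plan@fold
  expect_setequal(names(fold), rownames(fx$am))
  expect_false(any(is.na(fold)))
  mask <- assayMask(fx$am)
  for (f in unique(fold))
    expect_true(all(colSums(mask[fold == f, , drop = FALSE]) > 0))
  # deterministic under a fixed seed
  plan2 <- clusterSplit(fx$fps, fx$am, K = 4L, seed = 3)
  expect_identical(plan@fold, plan2@fold)
  plan3 <- clusterSplit(fx$fps, fx$am, K = 4L, seed = 4)
  expect_false(identical(plan@fold, plan3@fold))
})

test_that("a task with fewer than 2 compounds is an explicit error", {
  fx <- fixtureStudy()
  am <- fx$am
  mask <- SummarizedExperiment::assay(am, "mask")
  mask[, "LOX"] <- FALSE
  mask[1, "LOX"] <- TRUE
  SummarizedExperiment::assay(am, "mask") <- mask
  expect_error(clusterSplit(fx$fps, am, K = 4L, seed = 1),
               "fewer than 2")
})

test_that("matched random split keeps fold sizes and coverage", {
  fx <- fixtureStudy()
  plan <- clusterSplit(fx$fps, fx$am, K = 4L, seed = 3)
  rnd <- randomSplitMatched(plan, fx$am, seed = 8)
  expect_identical(sort(as.integer(table(plan@fold))),
                   sort(as.integer(table(rnd@fold))))
  mask <- assayMask(fx$am)
  for (f in unique(rnd@fold))
    expect_true(all(colSums(mask[rnd@fold == f, , drop = FALSE]) > 0))
  rnd2 <- randomSplitMatched(plan, fx$am, seed = 9)
  expect_false(identical(rnd@fold, rnd2@fold))
  expect_identical(sort(as.integer(table(rnd2@fold))),
                   sort(as.integer(table(plan@fold))))
})

test_that("time splits separate by date, strictly when asked", {
  fx <- fixtureStudy()
  cutoff <- as.Date("2014-06-30")
  tw <- timeSplit(fx$am, cutoff, strict = FALSE, seed = 2)
  ct <- tw@cellTest
  dates <- assayDates(fx$am)
  mask <- assayMask(fx$am)
  dated <- mask & !is.na(dates)
  expect_true(all(ct[dated & dates > as.numeric(cutoff)]))
  expect_true(all(!ct[dated & dates <= as.numeric(cutoff)]))
  # taskwise: some compound is train in one task and test in another
  mixed <- rowSums(ct, na.rm = TRUE) > 0 &
    rowSums(!ct & !is.na(ct)) > 0
  expect_gt(sum(mixed), 0)
  # strict: train and test compound sets are disjoint across all tasks
  st <- timeSplit(fx$am, cutoff, strict = TRUE, seed = 2)
  cs <- st@cellTest
  trainC <- rownames(cs)[rowSums(!cs & !is.na(cs)) > 0]
  testC <- rownames(cs)[rowSums(cs & !is.na(cs)) > 0]
  expect_length(intersect(trainC, testC), 0)
  # degenerate cutoffs error
  expect_error(timeSplit(fx$am, as.Date("2030-01-01")), "empty test")
  expect_error(timeSplit(fx$am, as.Date("1990-01-01")), "empty training")
})

test_that("dateless tasks fall back to random assignment in time splits", {
  fx <- fixtureStudy()
  am <- fx$am
  dates <- SummarizedExperiment::assay(am, "dates")
  dates[, "LOA"] <- NA_real_
  SummarizedExperiment::assay(am, "dates") <- dates
  tw <- timeSplit(am, as.Date("2014-06-30"), seed = 4)
  loa <- tw@cellTest[, "LOA"]
  m <- assayMask(am)[, "LOA"]
  expect_true(all(!is.na(loa[m])))
  expect_gt(sum(loa[m]), 0)       # some random test cells
  expect_gt(sum(!loa[m]), 0)
})

test_that("split plans serialize and reload identically", {
  fx <- fixtureStudy()
  plan <- clusterSplit(fx$fps, fx$am, K = 4L, seed = 3)
  f <- withr::local_tempfile()
  writeSplitPlan(plan, f)
  back <- readSplitPlan(f)
  expect_identical(back@fold, plan@fold)
  expect_identical(back@strategy, plan@strategy)
  ts <- timeSplit(fx$am, as.Date("2014-06-30"), strict = TRUE, seed = 2)
  f2 <- withr::local_tempfile()
  writeSplitPlan(ts, f2)
  back2 <- readSplitPlan(f2, fx$am)
  expect_identical(back2@cellTest, ts@cellTest)
})
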