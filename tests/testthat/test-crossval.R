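# Small-fixture orchestration tests: tiny networks and few epochs keep the
# bookkeeping checks fast; predictive quality is covered elsewhere.

smallGcnConfig <- function(nTasks = 1L)
  graphConvConfig(nTasks = nTasks, convDims = c(12L, 12L), denseDim = 12L,
                  epochs = 3L, batchSize = 64L)

test_that("cross-validation emits per-fold rows plus fold averages", {
  fx <- fixtureStudy()
  plan <- clusterSplit(fx$fps, fx$am, K = 4L, seed = 3)
  res <- runCrossValidation(fx$am, fx$study$mols, plan,
                            model = "gcn_multi",
                            config = smallGcnConfig(ncol(fx$am)),
                            seed = 11)
  nfolds <- length(unique(plan@fold[plan@fold != -1L]))
  per <- res$report$perFold
  expect_equal(nrow(per), nfolds * ncol(fx$am))
  expect_setequal(unique(per$fold), as.character(seq_len(nfolds)))
  # helper tasks never reach the headline average
  helpers <- names(which(isHelper(fx$am)))
  expect_false(any(res$report$average$code %in% helpers))
  expect_true(all(per$code %in% taskCodes(fx$am)))
  expect_true(res$leakageAudit)
})

test_that("reruns with the same seeds reproduce metrics bit-identically", {
  fx <- fixtureStudy()
  plan <- clusterSplit(fx$fps, fx$am, K = 4L, seed = 3)
  cfg <- smallGcnConfig(ncol(fx$am))
  r1 <- runCrossValidation(fx$am, fx$study$mols, plan, model = "gcn_multi",
                           config = cfg, seed = 5)
  r2_ <- runCrossValidation(fx$am, fx$study$mols, plan, model = "gcn_multi",
                            config = cfg, seed = 5)
  expect_identical(r1$report, r2_$report)
})

test_that("single-task mode trains one model per non-helper endpoint", {
  fx <- fixtureStudy()
  # restrict to two endpoints to keep this light
  am <- methods::new("AssayMatrix", fx$am[, c("LOD", "LMP")])
  plan <- clusterSplit(fx$fps, am, K = 3L, seed = 6)
  res <- runCrossValidation(am, fx$study$mols, plan, model = "gcn_single",
                            config = smallGcnConfig(1L), seed = 2)
  expect_setequal(names(res$models[["1"]]), c("LOD", "LMP"))
  expect_true(res$leakageAudit)
})

test_that("helper ablation reports the with/without comparison", {
  fx <- fixtureStudy()
  plan <- clusterSplit(fx$fps, fx$am, K = 3L, seed = 4)
  tab <- helperTaskAblation(fx$am, fx$study$mols, plan,
                            smallTask = "LOP", seeds = 1:2,
                            model = "gcn_multi",
                            config = smallGcnConfig())
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("r2_with", "r2_without", "delta") %in% colnames(tab)))
  expect_true(all(is.finite(tab$delta)))
  expect_named(attr(tab, "summary"), "mean_delta")
})

test_that("a configured experiment runs end to end from files", {
  dir <- withr::local_tempdir()
  writeFixtures(dir, syntheticConfig(nCompounds = 100L), seed = 9)
  cfg_file <- file.path(dir, "experiment.yaml")
  yaml::write_yaml(list(model = "gcn_multi", seed = 3, epochs = 2,
                        batch_size = 32, n_bits = 1024,
                        split = list(strategy = "cluster", k = 3),
                        output_dir = file.path(dir, "out")),
                   cfg_file)
  res <- runExperiment(cfg_file, file.path(dir, "records.tsv"))
  expect_true(file.exists(file.path(dir, "out", "metrics_average.csv")))
  expect_true(file.exists(file.path(dir, "out", "metrics_per_fold.csv")))
  expect_true(file.exists(file.path(dir, "out", "learning_curves.csv")))
  log <- readLines(file.path(dir, "out", "run_log.txt"))
  expect_true(any(grepl("seed: 3", log)))
  expect_true(any(grepl("leakage_audit_passed: TRUE", log)))
})
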