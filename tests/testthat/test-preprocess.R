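test_that("qualifier adjustment halves '<' and doubles '>' measurements", {
  expect_equal(applyQualifier(10, "lt"), 5)
  expect_equal(applyQualifier(10, "gt"), 20)
  expect_equal(applyQualifier(7.3, "eq"), 7.3)
  expect_equal(applyQualifier(c(10, 10, 7.3), c("<", ">", "=")),
               c(5, 20, 7.3))
  expect_error(applyQualifier(Inf, "eq"), "finite")
  expect_error(applyQualifier(1, "about"), "qualifier")
})

test_that("replicates average after per-record qualifier adjustment", {
  expect_equal(aggregateReplicates(5), 5)
  expect_equal(aggregateReplicates(c(1, 3)), 2)
  expect_equal(aggregateReplicates(c(10, 6), c("lt", "eq")), 5.5)
  expect_error(aggregateReplicates(numeric(0)), "no measurements")
  # property: pipeline order (adjust each record, then mean) equals the
  # brute-force per-record oracle on random replicate sets
  set.seed(42)
  for (i in 1:50) {
    k <- sample(1:5, 1)
    v <- runif(k, 0.1, 100)
    q <- sample(c("eq", "lt", "gt"), k, replace = TRUE)
    oracle <- mean(vapply(seq_len(k), function(j)
      switch(q[j], eq = v[j], lt = v[j] / 2, gt = 2 * v[j]), 0))
    expect_equal(aggregateReplicates(v, q), oracle, tolerance = 1e-12)
  }
})

test_that("model-scale transforms match their definitions", {
  expect_equal(toModelScale(180, "log10_molar", molWeight = 180), -3)
  expect_equal(toModelScale(100, "log10"), 2)
  expect_equal(toModelScale(120, "none"), 120)
  expect_error(toModelScale(-1, "log10"), "positive")
  expect_error(toModelScale(10, "log10_molar", molWeight = -5), "weight")
})

test_that("invertModelScale is the exact inverse of the forward pipeline", {
  set.seed(7)
  for (tr in c("none", "log10", "log10_molar")) {
    x <- runif(20, 0.5, 500)
    mw <- runif(20, 50, 400)
    fwd <- vapply(seq_along(x), function(i)
      toModelScale(x[i], tr, mw[i]), 0)
    back <- invertModelScale(fwd, tr, molWeight = mw)
    expect_equal(back, x, tolerance = 1e-9)
  }
  # standardized 0 maps back to the task mean on the transformed scale
  expect_equal(invertModelScale(0, "none", scaler = c(3.2, 1.7)), 3.2)
  expect_equal(invertModelScale(-3, "log10_molar", molWeight = 180), 180)
})

test_that("buildAssayMatrix does the bookkeeping", {
  recs <- data.frame(
    compound_id = c("a", "a", "b", "c"),
    smiles = c("CCO", "CCO", "c1ccccc1O", "CC(=O)O"),
    endpoint = c("E1", "E2", "E1", "E2"),
    value = c(10, 4, 8, 6),
    qualifier = c("eq", "eq", "lt", "eq"),
    stringsAsFactors = FALSE)
  eps <- endpointSet(c("E1", "E2"), c("none", "none"))
  am <- buildAssayMatrix(recs, eps)
  expect_equal(dim(am), c(3L, 2L))
  expect_equal(sum(assayMask(am)), 4)
  expect_equal(assayValues(am)["b", "E1"], 4)  # "<8" -> 4
  # replicate cell holds the mean of adjusted values
  recs2 <- rbind(recs,
                 data.frame(compound_id = "a", smiles = "CCO",
                            endpoint = "E1", value = 20, qualifier = "eq"))
  am2 <- buildAssayMatrix(recs2, eps)
  expect_equal(assayValues(am2)["a", "E1"], 15)
  expect_equal(taskSizes(am2), c(E1 = 2, E2 = 2))
})

test_that("compound identity is the standardized structure, not the id", {
  recs <- data.frame(
    compound_id = c("x1", "x2", "y"),
    smiles = c("OCC", "CCO.Cl", "c1ccccc1"),  # x1, x2 same structure
    endpoint = "E1", value = c(2, 4, 6), qualifier = "eq",
    stringsAsFactors = FALSE)
  am <- buildAssayMatrix(recs, endpointSet("E1"))
  expect_equal(nrow(am), 2L)
  expect_equal(assayValues(am)["x1", "E1"], 3)  # merged replicates
})

test_that("records invalid under a log transform are dropped and counted", {
  recs <- data.frame(
    compound_id = c("a", "b", "bad"),
    smiles = c("CCO", "CCN", "CCC"),
    endpoint = "S", value = c(100, -5, 50), qualifier = "eq",
    stringsAsFactors = FALSE)
  recs$smiles[3] <- "X("  # unparseable on top
  am <- buildAssayMatrix(recs, endpointSet("S", "log10_molar"))
  expect_equal(nrow(am), 2L)
  expect_equal(sum(assayMask(am)), 1)
  dr <- S4Vectors::metadata(am)$dropped
  expect_equal(unname(dr["structure"]), 1L)
  expect_equal(unname(dr["nonpositive"]), 1L)
})

test_that("per-task standardization hits zero mean/unit sd and inverts", {
  fx <- fixtureStudy()
  am <- standardizeTasks(fx$am)
  z <- SummarizedExperiment::assay(am, "z")
  m <- assayMask(am)
  for (j in seq_len(ncol(am))) {
    zj <- z[m[, j], j]
    expect_lt(abs(mean(zj)), 1e-6)
    expect_lt(abs(sd(zj) - 1), 1e-6)
  }
  sc <- scalers(am)
  back <- sweep(sweep(z, 2, sc$sd, "*"), 2, sc$mean, "+")
  expect_lt(max(abs(back[m] - assayValues(am)[m])), 1e-9)
  # train-only fitting leaves held-out rows out of the scaler
  tr <- rownames(am)[seq_len(100)]
  am3 <- standardizeTasks(fx$am, train = tr)
  sc3 <- scalers(am3)
  j <- 1L
  vals <- assayValues(am3)[intersect(tr, rownames(am3)[m[, j]]), j]
  expect_equal(sc3$mean[j], mean(vals), tolerance = 1e-12)
})

test_that("assay tables round trip through delimited text", {
  fx <- fixtureStudy()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAssayTable(fx$study$records, f)
  back <- readAssayTable(f)
  expect_equal(nrow(back), nrow(fx$study$records))
  expect_equal(back$value, fx$study$records$value, tolerance = 1e-9)
  expect_equal(back$qualifier, fx$study$records$qualifier)
})
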