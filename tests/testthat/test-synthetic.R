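test_that("generated molecules all parse and are reproducible", {
  smi <- generateMolecules(120, seed = 61)
  expect_identical(smi, generateMolecules(120, seed = 61))
  expect_false(identical(smi, generateMolecules(120, seed = 62)))
  res <- standardizeMolecules(smi)
  expect_equal(nrow(res$failures), 0)
  expect_length(res$molecules, 120)
})

test_that("descriptor distributions span multiple bins", {
  mols <- randomMolecules(200, seed = 63)
  d <- molDescriptorTable(mols)
  # molecular weight, donors/acceptors and rotatable bonds all spread out
  expect_gt(length(unique(cut(d$mw, breaks = seq(0, 800, by = 100)))), 3)
  expect_gt(length(unique(d$hbd)), 3)
  expect_gt(length(unique(d$hba)), 4)
  expect_gt(length(unique(d$rotB)), 4)
  expect_gt(max(d$nAtoms), 25)
  expect_lt(min(d$nAtoms), 8)
})

test_that("latent endpoint structure has the intended correlation signs", {
  fx <- fixtureStudy()
  tr <- fx$study$truth
  expect_lt(cor(tr$logKow, tr$logS), 0)     # logD anticorrelated with sol.
  expect_gt(cor(tr$LOO, tr$LOQ), 0.5)       # solubility assays correlate
  expect_gt(cor(tr$LOD, tr$LOA), 0.5)       # the two logD endpoints
  expect_lt(abs(cor(tr$LMP, tr$logKow)), 0.5)  # melting point only weakly
})

test_that("ground truth generated without GSE noise sits on the surface", {
  mols <- randomMolecules(60, seed = 64)
  cfg <- syntheticConfig(nCompounds = 60L, gseNoise = 0)
  ep <- generateEndpoints(mols, cfg, seed = 3)
  tr <- ep$truth
  res <- gseConsistency(tr$LMP, tr$logKow, tr$logS)
  expect_equal(unname(res["predicted"]), 1, tolerance = 1e-12)
})

test_that("masked-cell counts equal the configured task sizes", {
  fx <- fixtureStudy()
  n <- length(fx$study$mols)
  expected <- vapply(
    taskCodes(fx$am),
    function(code) max(2L, round(fx$cfg$taskFractions[code] * n)),
    numeric(1))
  expect_equal(unname(taskSizes(fx$am)), unname(expected))
})

test_that("qualifier censoring approximately recovers the true value", {
  fx <- fixtureStudy()
  recs <- fx$study$records
  cens <- recs[recs$qualifier != "eq", ]
  expect_gt(nrow(cens), 0)
  adj <- applyQualifier(cens$value, cens$qualifier)
  # censoring replaced v by ("<", 2v) or (">", v/2): adjustment undoes it
  # up to replicate-level scatter
  expect_true(all(adj > 0))
  lt <- cens$qualifier == "lt"
  expect_equal(adj[lt], cens$value[lt] / 2)
})

test_that("infeasible generator settings are rejected", {
  expect_error(syntheticConfig(gseNoise = -1), "infeasible")
  expect_error(syntheticConfig(taskFractions = c(LOD = 0)), "fractions")
})

test_that("fixture writer emits a consumable miniature study", {
  dir <- withr::local_tempdir()
  writeFixtures(dir, syntheticConfig(nCompounds = 40L), seed = 5)
  recs <- readAssayTable(file.path(dir, "records.tsv"))
  eps <- readEndpointConfig(file.path(dir, "endpoints.yaml"))
  expect_equal(length(eps), 10L)
  am <- buildAssayMatrix(recs, eps)
  expect_gt(nrow(am), 20)
  expect_equal(ncol(am), 10L)
})
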