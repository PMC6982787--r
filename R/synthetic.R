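# Synthetic study generator: valence-valid molecules from a fragment
# grammar, and a sparse correlated multi-endpoint assay table whose ground
# truths are linear in cheap graph descriptors (so a closed-form oracle
# exists) with a built-in general-solubility-equation relation among
# solubility, melting point and partition coefficient.

.TERMINAL_SUBS <- c(
  "C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N", "NC", "F", "Cl", "Br",
  "C#N", "C(=O)O", "C(=O)OC", "C(=O)N", "C(=O)C", "S(=O)(=O)C",
  "C(F)(F)F", "CO", "CCO", "CN", "CCN")

# ring templates: D = ring-closure digit, A = growth slot, B = decoration
.RING_MONO <- c("cDccc(A)ccD", "cDccnc(A)cD", "cDcc(A)scD", "cDcc(A)ocD",
                "cDcc(A)[nH]cD", "CDCCC(A)CCD", "CDCC(A)OCCD")
.RING_DI <- c("cDcc(B)cc(A)cD", "cDc(B)cnc(A)cD")
.LINKERS <- c("A", "CA", "CCA", "OA", "OCA", "C(=O)NA", "C(=O)A", "NA",
              "SA", "CNA", "COA")

.CHAIN_MOLS <- c("CCO", "CCCO", "CCN", "CCC(=O)O", "CCCC", "CC(C)CO",
                 "CCOC(=O)C", "NCCO", "OCCO", "CCCCN", "CC(=O)NC")

.growFragment <- function(depth, state) {
  if (depth <= 0 || stats::runif(1) < 0.3 || state$ring >= 8)
    return(sample(.TERMINAL_SUBS, 1))
  state$ring <- state$ring + 1L
  d <- as.character((state$ring - 1L) %% 9L + 1L)
  tmpl <- if (stats::runif(1) < 0.45) sample(.RING_DI, 1) else
    sample(.RING_MONO, 1)
  ring <- gsub("D", d, tmpl, fixed = TRUE)
  ring <- sub("B", sample(.TERMINAL_SUBS, 1), ring, fixed = TRUE)
  inner <- .growFragment(depth - 1L, state)
  linker <- sample(.LINKERS, 1)
  sub("A", sub("A", inner, linker, fixed = TRUE), ring, fixed = TRUE)
}

#' Generate valence-valid synthetic molecules
#'
#' Assembles drug-like SMILES from a fragment grammar: aryl/heteroaryl and
#' saturated ring cores decorated with polar and lipophilic substituents
#' and linked by short chains, ethers, amines or amides, plus a minority of
#' small acyclic molecules. Heavy-atom counts span roughly 4-40 with the
#' bulk between 10 and 30. Deterministic for a given seed.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @return character vector of `n` SMILES.
#' @examples
#' generateMolecules(3, seed = 7)
#' @export
generateMolecules <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  .withSeed(seed, {
    vapply(seq_len(n), function(i) {
      if (stats::runif(1) < 0.08)
        return(sample(.CHAIN_MOLS, 1))
      state <- new.env()
      state$ring <- 1L
      d <- "1"
      depth <- sample(0:4, 1, prob = c(0.05, 0.25, 0.35, 0.25, 0.10))
      tmpl <- if (stats::runif(1) < 0.6) sample(.RING_DI, 1) else
        sample(.RING_MONO, 1)
      ring <- gsub("D", d, tmpl, fixed = TRUE)
      ring <- sub("B", sample(.TERMINAL_SUBS, 1), ring, fixed = TRUE)
      sub("A", .growFragment(depth, state), ring, fixed = TRUE)
    }, character(1))
  })
}

#' Configuration of the synthetic study
#'
#' Defaults emulate the shape of an in-house physico-chemical data
#' collection: ten endpoints with very unequal task sizes (the
#' powder-solubility-like task is smallest), solubility endpoints mutually
#' correlated, logD anticorrelated with solubility, melting point only
#' weakly coupled, replicate measurements, censored records with `<`/`>`
#' qualifiers, and measurement dates. Latent ground truths are linear in
#' graph descriptors: `logKow* = kow0 + kowC * nC - kowPolar * nPolar +
#' eps`, `LMP* = mp0 + mpRings * nRings + mpDonors * hbd + eps`, and
#' `logS*` follows the general solubility equation applied to `LMP*` and
#' `logKow*` plus independent noise (`gseNoise = 0` generates data exactly
#' on the GSE surface).
#'
#' @param nCompounds number of molecules to generate.
#' @param taskFractions named fractions of compounds labeled per endpoint.
#' @param kow0,kowC,kowPolar,kowNoise partition-coefficient model.
#' @param mp0,mpRings,mpDonors,mpNoise melting-point model (degrees C).
#' @param gseNoise independent noise on `logS*` around the GSE surface.
#' @param assayNoise named per-endpoint measurement noise (model scale).
#' @param replicateRate fraction of cells measured twice.
#' @param qualifierRate fraction of records censored: a value `v` becomes
#'   `("<", 2 v)` or `(">", v / 2)`, so the qualifier rule approximately
#'   recovers `v`.
#' @param dateRange measurement date range.
#' @return a config list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(
    nCompounds = 2000L,
    taskFractions = c(LOD = 0.45, LOA = 0.70, LOM = 0.35, LOH = 0.35,
                      LMP = 0.50, LOO = 0.35, LOP = 0.10, LON = 0.45,
                      LOX = 0.08, LOQ = 0.30),
    kow0 = -0.5, kowC = 0.28, kowPolar = 0.85, kowNoise = 0.30,
    mp0 = 60, mpRings = 35, mpDonors = 22, mpNoise = 25,
    gseNoise = 0.40,
    assayNoise = c(LOD = 0.15, LOA = 0.25, LOM = 0.25, LOH = 0.30,
                   LMP = 10, LOO = 0.20, LOP = 0.30, LON = 0.30,
                   LOX = 0.50, LOQ = 0.35),
    replicateRate = 0.15, qualifierRate = 0.05,
    dateRange = as.Date(c("2008-01-01", "2016-06-30"))) {
  cfg <- list(nCompounds = as.integer(nCompounds),
              taskFractions = taskFractions,
              kow0 = kow0, kowC = kowC, kowPolar = kowPolar,
              kowNoise = kowNoise, mp0 = mp0, mpRings = mpRings,
              mpDonors = mpDonors, mpNoise = mpNoise, gseNoise = gseNoise,
              assayNoise = assayNoise, replicateRate = replicateRate,
              qualifierRate = qualifierRate, dateRange = as.Date(dateRange))
  if (any(taskFractions <= 0 | taskFractions > 1))
    stop("task fractions must lie in (0, 1]")
  if (any(c(kowNoise, mpNoise, gseNoise, assayNoise) < 0) ||
      any(c(cfg$kowC, cfg$kowPolar, cfg$mpRings) < 0))
    stop("infeasible correlation targets: noise and slope signs must ",
         "preserve the solubility/logD anticorrelation structure")
  class(cfg) <- "syntheticConfig"
  cfg
}

#' Generate the correlated assay records for a set of molecules
#'
#' Draws latent `logKow*`, `LMP*` and `logS*` per compound (see
#' [syntheticConfig()]), derives the ten endpoint truths (logD endpoints
#' from `logKow*`, membrane affinity and albumin binding as noisy affine
#' functions of `logKow*`, melting point from `LMP*`, all five solubility
#' endpoints as re-noised copies of `logS*`), converts them to assay units
#' (mg/L for solubility, linear scale for the log10 endpoints), sparsifies
#' to the configured task sizes, duplicates a fraction of cells as
#' replicates, censors a fraction with `<`/`>` qualifiers and assigns
#' measurement dates.
#'
#' @param mols named list of standardized [Molecule-class] objects.
#' @param cfg a [syntheticConfig()].
#' @param seed integer seed.
#' @return list with `records` (assay table data.frame), `truth`
#'   (per-compound latent values and per-endpoint model-scale truths) and
#'   `descriptors` (the latent descriptor table).
#' @export
generateEndpoints <- function(mols, cfg = syntheticConfig(), seed = 1L) {
  stopifnot(length(mols) >= 3)
  desc <- molDescriptorTable(mols)
  n <- nrow(desc)
  .withSeed(seed, {
    logKow <- cfg$kow0 + cfg$kowC * desc$nC - cfg$kowPolar * desc$nPolar +
      stats::rnorm(n, 0, cfg$kowNoise)
    LMP <- cfg$mp0 + cfg$mpRings * desc$nRings + cfg$mpDonors * desc$hbd +
      stats::rnorm(n, 0, cfg$mpNoise)
    logS <- gseLogS(LMP, logKow) + stats::rnorm(n, 0, cfg$gseNoise)
    an <- cfg$assayNoise
    truth_model <- cbind(
      LOD = logKow + stats::rnorm(n, 0, an["LOD"]),
      LOA = logKow - 1.2 + stats::rnorm(n, 0, an["LOA"]),
      LOM = 1.0 + 0.70 * logKow + stats::rnorm(n, 0, an["LOM"]),
      LOH = 1.2 + 0.55 * logKow + stats::rnorm(n, 0, an["LOH"]),
      LMP = LMP + stats::rnorm(n, 0, an["LMP"]),
      LOO = logS + stats::rnorm(n, 0, an["LOO"]),
      LOP = logS + stats::rnorm(n, 0, an["LOP"]),
      LON = logS + stats::rnorm(n, 0, an["LON"]),
      LOX = logS + stats::rnorm(n, 0, an["LOX"]),
      LOQ = logS + stats::rnorm(n, 0, an["LOQ"]))
    rownames(truth_model) <- desc$id
    mw <- desc$mw
    # model scale -> assay units
    toAssay <- function(code, v, mwv)
      switch(code,
             LOD = , LOA = , LMP = v,
             LOM = , LOH = 10^v,
             10^v * 1000 * mwv)  # solubility endpoints, mg/L
    codes <- colnames(truth_model)
    recs <- list()
    for (code in codes) {
      k <- max(2L, round(cfg$taskFractions[code] * n))
      sel <- sample.int(n, min(k, n))
      raw <- toAssay(code, truth_model[sel, code], mw[sel])
      nrep <- 1L + (stats::runif(length(sel)) < cfg$replicateRate)
      idx <- rep(seq_along(sel), nrep)
      v <- raw[idx]
      # replicate-level measurement scatter (multiplicative for positive
      # assay scales, additive for melting point / logD)
      if (code %in% c("LOD", "LOA", "LMP")) {
        v <- v + stats::rnorm(length(v), 0,
                              if (code == "LMP") 2 else 0.05)
      } else {
        v <- v * exp(stats::rnorm(length(v), 0, 0.05))
      }
      qual <- rep("eq", length(v))
      cens <- stats::runif(length(v)) < cfg$qualifierRate &
        v > 0  # halving/doubling keeps positive values positive
      lt <- cens & stats::runif(length(v)) < 0.5
      gt <- cens & !lt
      qual[lt] <- "lt"; v[lt] <- 2 * v[lt]
      qual[gt] <- "gt"; v[gt] <- v[gt] / 2
      dates <- as.Date(cfg$dateRange[1]) +
        floor(stats::runif(length(v)) *
                as.numeric(diff(cfg$dateRange) + 1))
      recs[[code]] <- data.frame(
        compound_id = desc$id[sel][idx],
        smiles = vapply(mols[desc$id[sel][idx]],
                        function(m) m@smiles, ""),
        endpoint = code, value = v, qualifier = qual,
        date = dates, stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
    list(records = records,
         truth = data.frame(id = desc$id, logKow = logKow, LMP = LMP,
                            logS = logS, truth_model,
                            stringsAsFactors = FALSE),
         descriptors = desc)
  })
}

#' Generate a complete miniature study
#'
#' Convenience wrapper: generate molecules, standardize them, deduplicate
#' at the canonical-structure level, and produce the correlated assay
#' records. Task sizes of the resulting [AssayMatrix-class] equal the
#' configured per-endpoint counts exactly because sparsification happens
#' after deduplication.
#'
#' @param cfg a [syntheticConfig()].
#' @param seed integer seed driving both molecule and endpoint generation.
#' @return list with `mols` (named list of unique standardized molecules),
#'   `records`, `truth`, `descriptors` and `endpoints`
#'   (the [defaultEndpoints()]).
#' @export
syntheticStudy <- function(cfg = syntheticConfig(), seed = 1L) {
  smiles <- generateMolecules(cfg$nCompounds, seed = seed)
  std <- standardizeMolecules(smiles)
  mols <- std$molecules
  can <- vapply(mols, function(m) m@smiles, "")
  mols <- mols[!duplicated(can)]
  ep <- generateEndpoints(mols, cfg, seed = seed + 1L)
  list(mols = mols, records = ep$records, truth = ep$truth,
       descriptors = ep$descriptors, endpoints = defaultEndpoints())
}

#' Upper-bound oracle on the latent descriptors
#'
#' Ordinary least squares on the true latent descriptors (`nC`, `nPolar`,
#' `nRings`, `hbd`, `nAtoms`) fitted on the training compounds and
#' evaluated on the held-out compounds. Because every synthetic ground
#' truth is linear in these descriptors plus independent noise, this
#' bounds from above the R-squared any structure-based model can reach.
#'
#' @param study a [syntheticStudy()] result.
#' @param am the [AssayMatrix-class] built from `study$records`.
#' @param code endpoint to evaluate.
#' @param trainKeys,testKeys compound keys of the two partitions.
#' @return named numeric: oracle `r2` on the test compounds.
#' @export
oracleDescriptorR2 <- function(study, am, code, trainKeys, testKeys) {
  d <- study$descriptors
  rownames(d) <- d$id
  v <- assayValues(am)[, code]
  m <- assayMask(am)[, code]
  tr <- intersect(trainKeys, rownames(am)[m])
  te <- intersect(testKeys, rownames(am)[m])
  df <- data.frame(y = v[tr], d[tr, c("nC", "nPolar", "nRings", "hbd",
                                      "nAtoms")])
  fit <- stats::lm(y ~ ., data = df)
  pred <- stats::predict(fit, newdata = d[te, ])
  c(r2 = r2(pred, v[te]))
}

#' Write a miniature study to disk
#'
#' Emits the delimited-text assay table consumed by [readAssayTable()], a
#' SMILES file and the endpoint configuration YAML.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [syntheticConfig()].
#' @param seed integer seed.
#' @return the directory, invisibly.
#' @export
writeFixtures <- function(dir, cfg = syntheticConfig(nCompounds = 200L),
                          seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- syntheticStudy(cfg, seed = seed)
  writeAssayTable(study$records, file.path(dir, "records.tsv"))
  writeLines(paste(vapply(study$mols, function(m) m@smiles, ""),
                   names(study$mols)),
             file.path(dir, "molecules.smi"))
  writeEndpointConfig(study$endpoints, file.path(dir, "endpoints.yaml"))
  invisible(dir)
}
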