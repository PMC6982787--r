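# Shared fixtures, built once per test run (memoized across files).

.fixtures <- new.env(parent = emptyenv())

# a handful of named reference molecules
fixtureMols <- function() {
  if (is.null(.fixtures$mols)) {
    smi <- c(ethanol = "CCO", benzene = "c1ccccc1", phenol = "c1ccccc1O",
             toluene = "Cc1ccccc1", paracetamol = "CC(=O)Nc1ccc(O)cc1",
             methane = "C", alanine = "C[C@H](N)C(=O)O",
             acetate = "CC(=O)[O-]")
    .fixtures$mols <- standardizeMolecules(smi, ids = names(smi))$molecules
  }
  .fixtures$mols
}

# small end-to-end synthetic study (~180 unique compounds, 10 endpoints)
fixtureStudy <- function() {
  if (is.null(.fixtures$study)) {
    cfg <- syntheticConfig(nCompounds = 220L)
    st <- syntheticStudy(cfg, seed = 101)
    am <- buildAssayMatrix(st$records, st$endpoints, mols = st$mols)
    fps <- fingerprintMatrix(st$mols[rownames(am)], nBits = 1024L)
    .fixtures$study <- list(study = st, am = am, fps = fps, cfg = cfg)
  }
  .fixtures$study
}

# large study for the split/recovery acceptance checks (~2000 unique)
fixtureBigStudy <- function() {
  if (is.null(.fixtures$big)) {
    cfg <- syntheticConfig(nCompounds = 2600L)
    st <- syntheticStudy(cfg, seed = 77)
    am <- buildAssayMatrix(st$records, st$endpoints, mols = st$mols)
    fps <- fingerprintMatrix(st$mols[rownames(am)], nBits = 1024L)
    plan <- clusterSplit(fps, am, K = 10L, seed = 7)
    .fixtures$big <- list(study = st, am = am, fps = fps, plan = plan)
  }
  .fixtures$big
}

randomMolecules <- function(n, seed) {
  standardizeMolecules(generateMolecules(n, seed = seed))$molecules
}

# renumber the atoms of a molecule by a permutation
permuteMolecule <- function(m, perm) {
  inv <- order(perm)
  m2 <- m
  m2@element <- m@element[perm]
  m2@charge <- m@charge[perm]
  m2@aromatic <- m@aromatic[perm]
  m2@hybridization <- m@hybridization[perm]
  m2@nH <- m@nH[perm]
  b <- m@bonds
  if (nrow(b) > 0) {
    b[, 1] <- inv[m@bonds[, 1]]
    b[, 2] <- inv[m@bonds[, 2]]
  }
  m2@bonds <- b
  m2
}

# single-task AssayMatrix around a plain response vector (for training
# tests that do not need the chemistry layer)
singleTaskMatrix <- function(y, code = "T1") {
  v <- matrix(y, length(y), 1,
              dimnames = list(paste0("c", seq_along(y)), code))
  mask <- matrix(TRUE, length(y), 1, dimnames = dimnames(v))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = v, mask = mask),
    colData = S4Vectors::DataFrame(code = code, transform = "none",
                                   helper = FALSE, row.names = code))
  methods::new("AssayMatrix", se)
}

# brute-force reference implementations (independent oracles)
bruteMaskedLoss <- function(pred, target, mask, weighting = "simple",
                            sizes = NULL) {
  Ls <- c(); ws <- c()
  for (t in seq_len(ncol(pred))) {
    cells <- which(mask[, t])
    if (!length(cells)) next
    s <- 0
    for (i in cells) s <- s + (pred[i, t] - target[i, t])^2
    Ls <- c(Ls, s / length(cells))
    ws <- c(ws, if (weighting == "simple") 1 else 1 / sizes[t])
  }
  ws <- ws / sum(ws)
  sum(ws * Ls)
}

bruteR2 <- function(pred, obs) {
  ssr <- 0; sst <- 0; mo <- sum(obs) / length(obs)
  for (i in seq_along(obs)) {
    ssr <- ssr + (obs[i] - pred[i])^2
    sst <- sst + (obs[i] - mo)^2
  }
  1 - ssr / sst
}

brutePearson <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

bruteSpearman <- function(x, y) brutePearson(rank(x), rank(y))

bruteRmse <- function(pred, obs) {
  s <- 0
  for (i in seq_along(obs)) s <- s + (pred[i] - obs[i])^2
  sqrt(s / length(obs))
}
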