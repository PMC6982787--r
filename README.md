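# admetnet

Multitask graph convolutional and fingerprint neural networks for
physico-chemical ADMET endpoints, in R.

## The problem

Early drug discovery relies on a handful of physico-chemical assays —
logD at neutral and acidic pH, aqueous solubility measured in several
assay formats, melting point, membrane affinity, human serum albumin
binding — that are measured at medium throughput and modeled constantly
(QSAR). These endpoints are biologically related and experimentally
correlated: the solubility assays correlate with one another, logD is
anticorrelated with solubility, and melting point couples only weakly to
everything else. `admetnet` implements a joint (multitask) deep-learning
treatment of such a panel, for computational chemists who want to rank
compounds before synthesis:

- **Assay preprocessing** into a sparse compounds × tasks matrix
  (`AssayMatrix`, a `SummarizedExperiment`): inequality qualifiers
  (`<` halves, `>` doubles the reported value, per measurement), replicate
  averaging on the raw scale, unit/log transforms (solubility mg/L →
  log10 mol/L), structure-level deduplication, and per-task
  standardization to zero mean and unit variance fitted on training data
  only.
- **Molecular representations**: standardized structures (largest
  fragment, cleared stereo, neutralized charges) are featurized both as
  folded circular count fingerprints (ECFC6: identifiers for radii 0–3
  per atom, counted and folded modulo 1024/2048) and as molecular graphs
  with 75 binary atomic input features.
- **Models**: a pyramidal fully connected network
  (2000/1000/500/100, decreasing dropout, He initialization, output bias
  −1, and an input-noise scheme that replaces counts by |round(N(0, 3))|
  with probability *p* before a tanh squashing), and a Duvenaud-style
  graph convolutional network — two convolutions of width 128,

  h′_v = ReLU(W_self h_v + W_nb Σ_{u∈N(v)} h_u + b),

  a per-atom dense layer of 256 units, and a mean ⊕ max readout with tanh
  giving a 512-dimensional molecule embedding with one linear head per
  task.
- **Masked multitask loss**: L = Σ_t w_t · mean((ŷ − y)² over labeled
  cells of task t), with equal weights 1/N over the tasks present in the
  minibatch ("simple") or weights ∝ 1/task-size ("balanced"); missing
  labels contribute exactly zero gradient.
- **Validation the way prospective users experience it**:
  leave-cluster-out cross-validation (k-means, K = 10, on count
  fingerprints, with clusters merged until every fold covers every task),
  matched random splits of identical fold sizes, and taskwise or strict
  time splits.
- **The general solubility equation audit**: the Yalkowsky relation
  logS_w = −0.01 (LMP − 25) − log K_ow + 0.5 links solubility, melting
  point and partition coefficient; `gseConsistency()` checks whether a
  trained model's predictions respect it without ever being trained on it.
- **Synthetic studies**: a generator of valence-valid molecules and
  correlated sparse assay tables (with replicates, censored records,
  dates, helper tasks, and a built-in GSE relation) so that the entire
  pipeline is testable without proprietary assay data.

## Worked example

```r
library(admetnet)

study <- syntheticStudy(syntheticConfig(nCompounds = 600L), seed = 1)
am <- buildAssayMatrix(study$records, study$endpoints, mols = study$mols)
am
#> AssayMatrix: 546 compounds x 10 tasks
#>   labeled cells: 2001 ( 36.6 % dense )
#>   task sizes: LOD=248 LOA=386 LOM=193 LOH=193 LMP=276 LOO=193 LOP=55 LON=248 LOX=44 LOQ=165

fps <- fingerprintMatrix(study$mols[rownames(am)], nBits = 2048L)
plan <- clusterSplit(fps, am, K = 5L, seed = 1)
res <- runCrossValidation(am, study$mols, plan, model = "gcn_multi",
                          config = graphConvConfig(epochs = 20L), seed = 1)
formatMetricsTable(res$report)
#> task         R2   Spearman    Pearson     RMSE
#> LMP       -2.59       0.36       0.39    62.06
#> LOA        0.16       0.74       0.75     1.33
#> LOD        0.35       0.79       0.81     1.22
#> LOH        0.13       0.68       0.71     0.75
#> LOM        0.19       0.61       0.66     0.90
#> LOO       -0.80       0.72       0.73     1.79
#> LOP       -2.58       0.35       0.31     2.39
```

Each row is one endpoint (helper tasks are trained jointly but never
reported); the columns are the leave-cluster-out fold averages of the
coefficient of determination (1 − SS_res/SS_tot, negative when the model
is worse than predicting the mean), Spearman's rho, Pearson's r and the
RMSE on the transformed assay scale (°C for LMP, log units elsewhere).
At this deliberately small training size the ranking metrics are already
informative while R² on hard, high-variance endpoints is still negative —
cluster splits test extrapolation into unseen chemical space, which is
the hardest setting. At 2000 compounds and the full 40 training epochs
the same multitask model reaches held-out R² ≈ 0.6–0.8 on the logD-like
endpoints (this is what the acceptance suite verifies).

The GSE consistency audit on the held-out cluster of the same study:

```r
sel <- splitSelection(plan, am, fold = -1L)
mod <- fitModel(graphConvModel(taskCodes(am)), am, train = sel$trainRows,
                mols = study$mols, seed = 1)
test <- rownames(am)[!sel$trainRows]
pred <- predictTasks(mod, study$mols[test], scale = "model")
round(gseConsistency(pred[, "LMP"], pred[, "LOD"], pred[, "LOO"]), 3)
#> predicted logd_only
#>     0.894     0.799
```

The solubility derived from the model's *own* melting-point and logD
predictions via the GSE correlates with its predicted solubility more
strongly (0.894) than the plain −logD ablation (0.799): the model has
internalized the thermodynamic relation without being trained on it.

A thin command-line interface mirrors the workflow
(`inst/exec/admetnet`): `fixtures`, `preprocess`, `split`, `train`,
`predict`, `crossvalidate`, `gse-audit`.

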