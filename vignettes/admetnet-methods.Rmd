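---
title: "Methods: multitask networks for physico-chemical ADMET panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multitask networks for physico-chemical ADMET panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` do not themselves
compute.

## The modeling problem

A physico-chemical ADMET panel is a set of related regression tasks over
the same chemical space: logD at two pHs, several aqueous-solubility
assays, melting point, membrane affinity, serum albumin binding. Any one
compound is measured in only a few of them, so the joint training matrix
is sparse (a third dense or less). The premise of multitask modeling is
that the endpoints share structure — solubility assays correlate, logD
anticorrelates with solubility — so a shared representation regularizes
the small tasks and transfers chemical-space coverage from the large
ones. Three endpoints are *helper tasks*: they participate in the joint
loss purely to support related endpoints, and their own accuracy is never
reported in headline averages.

## Preprocessing

Raw records are one measurement each: compound, SMILES, endpoint code,
value, optional `<`/`>` qualifier, optional date.

* **Qualifier rule.** A censored measurement `< v` is replaced by `v/2`,
  `> v` by `2 v`. The adjustment is a property of the individual
  measurement, so it is applied per record *before* replicate averaging;
  the two orders differ whenever a cell mixes qualifiers, and a property
  test asserts agreement with a per-record brute-force oracle.
* **Replicate averaging** takes the arithmetic mean on the raw assay
  scale, then transforms. Averaging before the log keeps the estimator
  unbiased on the scale the assay actually reports; the alternative
  (mean of logs) is a geometric mean and was deliberately not chosen.
* **Transforms.** Melting point (°C) and the two logD endpoints pass
  through unchanged; membrane affinity and albumin binding take log10;
  solubilities are converted from mg/L to mol/L with the molecular weight
  of the standardized structure and then log10-transformed. Records whose
  qualifier-adjusted value is non-positive under a log transform are
  dropped and counted, not clamped — the log is undefined and no floor is
  defensible.
* **Structure standardization** (OpenBabel via ChemmineR/ChemmineOB):
  stereo descriptors are cleared, the largest covalent fragment kept, and
  charges neutralized by protonating anionic acids and deprotonating
  cationic bases. Adjacent opposite charges (nitro, N-oxides) are left
  intact, as are quaternary nitrogens. Compound identity for
  deduplication is the canonical SMILES of the standardized structure,
  not the vendor identifier, so salts and stereo-duplicates collapse into
  one row. Tautomer canonicalization is exposed as a configuration flag
  but is currently a no-op: the underlying toolkit provides no
  canonical-tautomer routine, and silently substituting a different
  algorithm seemed worse than documenting the gap.
* **Per-task standardization** to zero mean and unit standard deviation
  is fitted on the *training* rows only and reused for validation and
  test — endpoints with wide ranges (melting points above 200 °C) would
  otherwise dominate the joint loss, and fitting scalers on all data
  would leak test statistics into training. `runCrossValidation()`
  asserts the absence of such leakage on every fold.

## Molecular representations

**Count fingerprints (ECFC6).** Each atom emits one circular-substructure
identifier per radius 0–3 (diameter 6). The radius-0 invariant hashes
element, heavy-atom degree, hydrogen count, formal charge and
aromaticity; each iteration re-hashes an atom's identifier together with
its neighbors' identifiers sorted by (identifier, bond order), which
makes the result independent of input atom order. Identifiers are
*counted*, not OR-ed into bits, and folded to 1024 or 2048 slots by
modulo reduction, so the folded counts always sum to 4 × (heavy atoms) —
a conservation law the tests exploit. The hash is a polynomial rolling
hash modulo the Mersenne prime 2³¹ − 1; all arithmetic stays exact in
doubles. These identifiers are a self-contained convention: they are
deterministic and portable across platforms, but not numerically
compatible with any other toolkit's ECFP identifiers.

**Molecular graphs.** One node per heavy atom, one undirected edge per
bond; bond types are deliberately not distinguished. The 75 atomic input
features are concatenated one-hot/binary blocks: element over a fixed
43-symbol list plus "other" (44), heavy-atom degree 0–10 (11), implicit
hydrogens 0–6 (7), formal charge scalar (1), radical electrons scalar
(1, always 0 here since radicals do not survive standardization),
hybridization SP/SP2/SP3/SP3D/SP3D2 (5), aromatic flag (1), total
hydrogens 0–4 (5). The layout follows the convention of the established
graph-convolution featurizers; hybridization and aromaticity come from
OpenBabel's atom typing (MOL2 types), which can disagree with other
toolkits in edge cases such as ester oxygens — a consistent convention
matters more here than any particular one.

## Networks

**Fully connected (fingerprint) networks.** A pyramid of four rectifier
hidden layers (2000/1000/500/100) with dropout 0.5/0.5/0.25/0, He
weight initialization, hidden biases 0 and the output bias initialized at
−1. Because count fingerprints are sparse, input dropout would mostly
drop zeros; instead, with probability *p* per element (default 0.02
single-task, 0.01 multitask) the count is replaced by |round(N(0, 3))| —
a plausible count — and tanh is applied afterwards to smooth the inputs.
At inference *p* is forced to 0 and dropout is off, so prediction is a
deterministic function; a test asserts bit-stability. The replacement is
per *element*, not per vector: dropping in individual chemical features
is the stated intent of the scheme, and a whole-vector replacement would
destroy the molecule. Learning rate 10⁻³ (Adam), batch size 128, weight
decay 10⁻⁵ and a halve-on-plateau schedule are tunable defaults, labeled
as such: the corresponding published settings were tuned on one endpoint
and not reported.

**Graph convolutional networks.** Two convolution steps of width 128,
`h′_v = ReLU(W_self h_v + W_nb Σ_{u∈N(v)} h_u + b)`, a per-atom dense
layer of 256 units, then a readout that concatenates the mean and the
per-feature maximum over atoms and applies tanh — a 512-dimensional
molecule embedding with every entry strictly inside (−1, 1), invariant
to atom renumbering (asserted to 10⁻⁵ over random molecules, and exactly
in the linear algebra up to float reassociation). One linear output unit
per task sits on the shared embedding; no task-specific hidden layers.
Adam with learning rate 10⁻³, batch size 128, 40 epochs, exponential
learning-rate decay every 1000 steps (factor 0.95 — the published
description fixes the interval but not the factor, so the factor is a
config default). The default layer uses a single shared (W_self, W_nb)
pair — the architecture is meant to be simple — with degree-specific
neighbor matrices available behind `degreeWeights = TRUE` for fidelity to
the original neural-fingerprint formulation. Neighborhood max-pooling
and batch normalization, present in some implementations of this model
family, are accepted as configuration keys but are not implemented and
refuse to switch on: whether they were active in the runs this design
descends from is not stated anywhere, and they must never be silently
on. Both networks are implemented directly in R matrix algebra with
hand-derived backpropagation (verified against finite differences to
10⁻⁴ relative error) because the networks themselves are the point of
the package; BLAS carries the arithmetic.

## Masked multitask loss

With predictions, targets and a label mask of shape batch × tasks, the
per-task loss is the mean squared error over labeled cells; tasks absent
from a minibatch are skipped entirely. "Simple" weighting gives each
present task weight 1/N; "balanced" weighting gives weights proportional
to 1/task-size, normalized over present tasks, so small tasks are
upweighted. Balanced weights use the *global* training-set task sizes by
default: minibatch counts fluctuate wildly for tasks that appear in a
batch only once or twice, and the global form matches the intent of
down-weighting data-rich tasks. A per-minibatch variant is available via
`perBatch = TRUE`. Gradients at unmasked cells are exactly zero (tested,
not approximately). An entirely empty helper task is tolerated — it
never enters any minibatch and gets an identity scaler; an empty modeled
task is an error.

## Validation splits

* **Leave-cluster-out**: k-means (K = 10, Euclidean, k-means++-style
  seeding via `stats::kmeans` under a fixed seed) on folded count
  fingerprints — raw counts, not binarized or TF-IDF-scaled, since counts
  are the representation the models consume. Clusters missing labeled
  compounds of any task are merged, smallest offender first, into the
  nearest *larger* cluster by centroid distance (the size direction is
  specified, the target choice is ours); the loop repeats until every
  fold covers every task. One fold (the one closest to the mean size,
  deterministically) becomes the external test set. A task with fewer
  than two compounds makes coverage infeasible and is an explicit error.
* **Matched random**: a random permutation into folds of exactly the
  cluster plan's sizes, followed by a repair pass that swaps compounds
  between folds — always preserving both folds' coverage — until every
  fold again covers every task.
* **Time splits**: a fixed cutoff date; per task, labeled cells dated
  after it are test, the rest training (taskwise). The date of a cell
  with replicates is the *latest* replicate date — the conservative
  choice that keeps late information out of training. The strict variant
  removes from all training sets any compound occurring in any task's
  test set (those cells become excluded, not test). Tasks without dates
  are split randomly at the overall test fraction. Cutoffs outside the
  observed date range produce empty-side errors rather than silent
  degenerate splits.

## The GSE consistency audit

The general solubility equation, logS_w = −0.01 (LMP − 25) − log K_ow +
0.5 (logS_w in log10 mol/L, LMP in °C), ties three of the panel's
endpoints together thermodynamically. The audit computes (a) the Pearson
correlation between the GSE solubility derived from the model's *own*
melting-point and logD predictions and its predicted solubility, (b) the
same on measured values when available, and (c) the correlation between
−predicted logD and predicted solubility. Comparison of (a) against (c)
separates genuine three-endpoint consistency from the mere
logD–solubility anticorrelation already present in the data; logD stands
in for log K_ow, a documented approximation that is standard at
near-neutral pH.

## The synthetic-data generator

The generator exists so that every pipeline stage is testable without
proprietary assay data. Molecules come from a fragment grammar —
aryl/heteroaryl and saturated cores, polar and lipophilic substituents,
short linkers — yielding valence-valid, drug-like structures with
heavy-atom counts spanning roughly 4–40 and molecular weights centered
near 250. Ground truths are *linear in cheap graph descriptors* so that a
closed-form oracle exists: logKow\* rises with carbon count and falls
with polar-atom count; LMP\* rises with ring and donor counts; logS\*
follows the GSE applied to LMP\* and logKow\* plus independent noise
(zero noise puts the data exactly on the GSE surface, which the tests
use). The observable endpoints are re-noised affine images of these
latents: two logD endpoints from logKow\*, membrane affinity and albumin
binding as affine functions of logKow\*, melting point from LMP\*, and
all five solubility assays from logS\*. Records are then sparsified to
unequal task sizes (the powder-solubility-like task smallest), a fraction
measured twice, a fraction censored — `v` becomes `("<", 2v)` or
`(">", v/2)`, so the qualifier rule approximately recovers `v` and
censoring bias is testable — and dated uniformly over an 8.5-year window.

What the generator does *not* emulate: real assay value distributions,
activity cliffs, nonlinear structure–property relationships, batch
effects, or temporal drift in chemistry. Passing tests on synthetic data
therefore demonstrate that the pipeline is *correct* (shapes, masks,
invariances, recovery of recoverable signal), not that the models reach
any particular accuracy on real compounds.

An ordinary least-squares model on the true latent descriptors
(`oracleDescriptorR2()`) bounds from above the R² any structure-based
model can achieve, since every ground truth is linear in those
descriptors plus independent noise. The parameter-recovery check trains
the multitask graph network on a study of about 2000 unique compounds
and requires held-out R² ≥ 0.6 on the logKow\*-like endpoint, below the
oracle bound.

## Numerical choices and problem sizes

Tolerances: metric and loss implementations match brute-force oracles to
10⁻¹⁰; standardization round-trips to 10⁻⁹; permutation invariance to
10⁻⁵ (float reassociation); backprop to 10⁻⁴ relative against central
differences at ε = 10⁻⁶. Ties: grouped max readout breaks ties by first
atom index (deterministic); Spearman uses average ranks. Degenerate
inputs: constant observation vectors make correlations and R² errors,
not NaNs; non-finite training loss aborts with a diagnostic; zero-atom
molecules are rejected at parse time. Seeds: every stochastic function
takes an explicit seed and restores the caller's RNG state, so fitted
runs reproduce bit-identically on one machine (asserted).

The test suite runs the expensive checks at deliberately chosen sizes:
the recovery and split-invariant checks use one ~2000-compound study;
orchestration tests use ~180-compound studies with reduced network
widths and epochs, since they check bookkeeping, not accuracy; the
helper-task ablation utility defaults to 10 seeds but is exercised with
2 seeds and small networks, and its output is reported, not asserted —
on small synthetic studies the helper effect is within seed noise, and
the honest statement is the computed difference itself.

## Known limitations

* Tautomer canonicalization is a documented no-op (see above).
* OpenBabel atom typing defines hybridization/aromaticity; conventions
  differ across toolkits, so features for edge-case atoms may differ
  from other implementations even though all invariants hold.
* The networks run on CPU only and are trained with plain Adam; no GPU,
  no early stopping (training length is a fixed epoch count by design).
* Fingerprint identifiers are internally consistent but not
  interchangeable with other software's ECFP identifiers.
* The synthetic generator's linear ground truths make recovery
  deliberately easy; it validates machinery, not chemistry.
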