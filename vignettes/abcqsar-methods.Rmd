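---
title: "Methods: curation rules, consensus QSAR, and brain-exposure scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation rules, consensus QSAR, and brain-exposure scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the
record-classification and voting rules, the consensus modeling procedure,
the attribution and applicability-domain machinery, the brain-exposure
score, and the synthetic-data generator that makes all of it testable. It
also records the numerical and design choices that were genuinely open,
and what the test suite does and does not establish.

## From records to datasets

A bioactivity record is one measurement for one chemical × transporter ×
activity type (substrate binding or inhibition), with an endpoint, value,
units and assay metadata. `classify_record()` maps each record to
1 / 0 / 0.5 / NA in three stages:

1. **Exclusions → NA.** ATPase-type assays (binding-affinity readouts that
   produce false substrate/inhibitor calls), records whose assay measured
   a different transporter than the one they are filed under, excluded
   sources, and records missing a usable value or unit. NA records never
   enter any vote.
2. **Unit normalization.** Concentration endpoints are normalized to µM
   (nM inputs divided by 1000); percent-inhibition must be in percent;
   ratio endpoints must be dimensionless. An unconvertible unit is
   treated as missing essential metadata (NA), not guessed.
3. **Threshold table.** The default table (`default_thresholds()`):
   inhibition IC50/Ki/EC50 ≤ 10 µM → 1 and ≥ 50 µM → 0, with the region
   between inconclusive (0.5); percent inhibition ≥ 50 → 1, < 25 → 0;
   substrate efflux ratio (or fold-change) ≥ 2 → 1, < 2 → 0; a reported
   Km with demonstrated transport → 1; apparent permeability alone is
   always 0.5, because a flux measurement without an efflux comparison
   cannot establish carrier-mediated transport. The 25% noninhibitor
   bound and the ratio-2 substrate cut follow standard practice in
   transporter assay interpretation; every bound is plain data and can be
   replaced via `read_curation_config()`. Endpoint/activity combinations
   without a rule (e.g. an inhibition "ratio") yield NA with a warning:
   the engine refuses to guess what a variably-used endpoint means.

`aggregate_chemical()` takes the strict majority of the remaining binary
labels. Records labeled 0.5 are set aside before voting — an inconclusive
measurement carries no directional evidence, and the tie rule is meant for
*conflicting* binary results. An exact 1-vs-0 tie yields 0.5; a chemical
whose records are all NA/0.5 yields NA. Only chemicals with binary final
labels are retained for modeling.

Structure standardization (`standardize_structure()`) retains the largest
organic component (heavy-atom count; "organic" requires carbon), strips
stereochemistry — the pipeline is strictly 2D — and writes OpenBabel
canonical SMILES. One canonicalization dialect is fixed for the whole
pipeline; cross-toolkit SMILES equivalence is out of scope. The operation
is idempotent, which the test suite checks directly. Deduplication keeps,
per canonical structure, the entry with the highest activity: label 1
outranks label 0 (a demonstrated activity beats a negative call), and
among same-label quantitative records the most potent (lowest µM)
representative is kept.

Two balancing tools mirror common practice with public transporter data,
where positives are over-reported: seeded random undersampling of the
majority class, and supplementation of negatives from an external pool
restricted to candidates with MACCS-Tanimoto ≥ 0.8 to at least one
training inactive — the similarity gate keeps supplemented negatives
inside the chemical space where the training negatives live.

Train/external overlap is resolved conservatively: agreeing duplicates are
dropped from the external set only; conflicting duplicates are considered
unreliable in both sources and dropped from both.

## Descriptors

Three descriptor sets per chemical:

* `ECFP6_1024` — circular (Morgan-type) fingerprints with bond radius 3
  (the diameter-6 convention), computed by OpenBabel at 4096 bits and
  folded 4:1 by bitwise OR to 1024 bits. Folding by OR is the standard
  fixed-length construction; collisions are part of the representation.
* `MACCS_166` — the 166 public MACCS substructure keys (OpenBabel's
  SMARTS implementation; the 256-bit container's keys 1–166).
* `PHYSCHEM` — a frozen, named panel (`physchem_panel()`, 28 features):
  whole-molecule properties (MW, logP, molar refractivity, TPSA, H-bond
  donor and acceptor counts) plus atom/bond/ring and functional-group
  counts by SMARTS matching. The panel size is toolkit-specific by
  nature; what matters for reproducibility is that the feature list is
  frozen in the package rather than inherited from whatever a toolkit
  version emits. HBA uses OpenBabel's stricter acceptor definition
  (`HBA2`), which matches the medicinal-chemistry convention (ethanol 1,
  methane 0).

PHYSCHEM features are imputed (training-fold medians) and z-scored with
training-fold statistics inside each cross-validation fold; all-NA and
constant columns are dropped per fold. Fingerprints are left binary.

## Models and the consensus

Four algorithms × three descriptor sets give 12 individual models per
dataset; study-style use across four transporters × substrate/inhibition
gives 8 datasets × (12 + 1) = 104 model artifacts, which the acceptance
suite builds end-to-end on synthetic data.

* **RF** — `randomForest`, tuned over the number of trees {100, 500}.
* **SVM** — `e1071` radial kernel, cost {0.1, 1, 10}, with the library's
  built-in probability calibration (margin outputs are not probabilities,
  and consensus averaging needs probabilities).
* **GBT** — `xgboost` (binary logistic objective), learning rate
  {0.05, 0.1}, single-threaded for determinism.
* **FFNN** — a single-hidden-layer perceptron (`nnet`, 4 hidden units,
  weight decay {1e-3, 1e-2}, 80 BFGS iterations). For descriptor inputs
  of 28–1024 features and datasets of a few hundred chemicals, one hidden
  layer is ample capacity; regularization is by weight decay rather than
  early stopping. Width, depth of training and decay are configurable.

Grid search runs *inside* the training data by stratified internal
cross-validation (default 5-fold), scored by pooled CCR at the 0.5
threshold, with ties broken toward the first candidate; the winner is
refit on the full training input. A flat mode (`tune_folds = 0`) scores
candidates on the training data itself, for comparability with flat
pipelines. Grids are deliberately small and documented; a single-point
grid skips the search entirely, which the structural tests use so that
their runtime measures the pipeline, not the tuning.

The **consensus model** is the unweighted arithmetic mean of the member
probabilities, so it is always bounded by the member range — an invariant
the tests assert per chemical. Class calls use the 0.5-or-higher
convention; a probability of exactly 0.5 is a positive call.

Cross-validation uses stratified fold assignment (each fold's class count
within one chemical of proportionality). Plain random splitting can
produce single-class folds for datasets of the size seen for the less
studied transporters; stratification removes that failure mode while
remaining a random partition.

## Evaluation, applicability domain, attribution

Sensitivity, specificity, CCR = (sensitivity + specificity)/2 and PPV come
from confusion counts at 0.5; AUC is the Wilcoxon rank statistic with
midrank tie handling (cross-checked in the tests against an independent
ROC implementation). Zero-denominator metrics are reported as undefined
(NA), never as 0, and excluded from any averaging — the relevant case
being all-positive external validation sets, where sensitivity is the only
defined metric.

The applicability domain is a probability band: ≥ 0.6 confident positive,
≤ 0.4 confident negative, strictly between out-of-domain and excluded from
in-domain performance summaries. The three-way split and the coverage
identity (in-domain + excluded = n) are tested.

Substructure attribution uses Shapley values on MACCS models, where each
feature is an interpretable substructure. For gradient-boosted trees the
exact tree-path algorithm is used (log-odds space; base value plus
attributions reproduces each prediction, asserted to numerical precision).
For the other algorithms a seeded Monte Carlo permutation estimator
averages marginal contributions over random feature orderings against a
background sample (default: up to 100 training chemicals, fixed seed).
Keys are ranked by mean absolute attribution; the top keys are annotated
with substructure descriptions read from the installed OpenBabel MACCS
definitions, with a plain "MACCS key N" fallback.

The planted-signal benchmark compares the consensus CCR against a
permuted-label null: labels are permuted against the *fixed* out-of-fold
probabilities (the standard permutation test of prediction–label
association). Retraining the full 13-model suite per permutation would
test the same hypothesis at ~1000× the cost; with fold-internal
preprocessing and tuning there is no leakage channel for the fixed
predictions to exploit.

## Brain-exposure score

For compound sets with measured unbound brain-to-plasma ratios
(Kp,uu,brain), the score combines three physicochemical favorability terms
with the efflux prediction:

    score = S_TPSA + S_HBD + S_HBA − S_efflux  ∈ {−1, 0, 1, 2, 3}

with inclusive bounds TPSA ≤ 90 Å², HBD ≤ 5, HBA ≤ 10 (each scoring 1 when
met) and S_efflux = 1 when the predicted substrate probability for P-gp
and/or BCRP is ≥ 0.5. The "and/or" (mode `"either"`) is the default
because either transporter suffices to limit brain exposure at the
blood–brain barrier; single-transporter modes support per-transporter
views. Exposure strata use Kp,uu ≥ 0.1 as high vs low exposure, and
Kp,uu ≥ 1 to isolate very-high-exposure compounds; the summary reports the
substrate-likelihood ratio between the low and high strata, with an
infinite ratio flagged as censored. Compounds lacking a usable efflux
prediction are emitted with a missing score and counted in a warning —
they are neither silently dropped nor given a default.

## The synthetic-data generator

The generator emulates the study conditions end to end. Chemicals are
built by attaching two substituents to a six-scaffold set (benzene,
pyridine, cyclohexane, thiophene, furan, piperidine), guaranteeing
parseable structures and a controllable motif frequency; the default
planted motif is a carboxylic acid (SMARTS `C(=O)[OX2H1]`), a polar group
of the kind that dominates substrate-side substructure attributions, which
gives the SHAP test a known answer. Motif presence is verified by SMARTS
matching on the assembled molecule, so construction can never disagree
with the label-generating indicator; the latent class flips with
probability `activity_noise` (default 0.1).

Defaults, chosen once as realistic study conditions: ~2.5 records per
chemical (public transporter collections average between two and three
records per unique chemical); an inhibition-heavy endpoint mix with IC50
dominant, matching the endpoint composition of public transporter data
(inhibition-related endpoints form the clear majority); conflict,
excludable-assay and stereo-duplicate rates of 5% each; a positive:negative
imbalance of 1.5 reflecting positive-reporting bias. Record values are
drawn log-uniformly inside the class-consistent region of the threshold
table with a two-fold margin from every bound, and concentration units
randomize between nM and µM — a unit-conversion bug therefore flips
classifications outright instead of producing near-threshold noise.
Excludable records carry *class-inconsistent* values, so a curation
pipeline that fails to exclude them visibly corrupts labels. The Kp,uu
companion table draws from two log-normal regimes with medians 0.02
(efflux substrates) and 0.5 (nonsubstrates); sdlog 1.0 gives each regime
a realistic ~10-fold spread while keeping the two regimes separated
across the 0.1 cut.

What the generator does *not* emulate: real medicinal-chemistry diversity
(the library is a small combinatorial family), activity cliffs,
assay-specific systematic biases, or the actual chemical space of public
transporter data. Passing the planted-signal tests therefore shows that
the pipeline recovers a recoverable signal without leakage — not that any
particular real-data accuracy is attainable; headline numbers on the real
curated corpora are outside what synthetic data can certify.

## Problem sizes and numerical choices

The test suite runs the full structural check (8 datasets × 13 models =
104 artifacts) at 60 chemicals per dataset with single-point grids, and
the statistical benchmark at 400 chemicals, 10% label noise, stratified
5-fold cross-validation of the full 12-model suite, against a
1000-permutation null — sizes at which every property under test is
informative while the suite stays comfortably fast on one CPU. Ties in
grid search break toward the first candidate; probabilities are clamped to
[0, 1] after backend prediction; the cyclomatic ring count assumes the
standardized (connected) structure. Seeds are explicit everywhere a
random choice is made: generation, fold assignment, fitting,
undersampling, supplementation, background sampling and the permutation
null.

## Known limitations

* OpenBabel's MACCS SMARTS definitions are a public reimplementation;
  absolute key-by-key agreement with other toolkits is not guaranteed
  (the keys are used consistently within the package).
* The FFNN is a single-hidden-layer perceptron; deeper architectures are
  not provided.
* The physicochemical panel is intentionally compact (28 features);
  fingerprints carry the bulk of the structural signal.
* `Papp` and comment-only endpoints never produce binary labels by
  default; studies that report only permeability will contribute no
  training chemicals unless the threshold table is extended.
* The brain-exposure module scores and stratifies; it does not predict
  Kp,uu numerically.
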