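# abcqsar

Consensus QSAR modeling of ABC transporter substrates and inhibitors, with
a brain-exposure scoring system driven by efflux predictions.

## The problem

The ATP-binding cassette (ABC) efflux transporters P-gp (MDR1), BCRP, MRP1
and MRP2 pump drugs and other xenobiotics out of cells, shaping
pharmacokinetics, drug–drug interaction risk, and the exposure of protected
tissues such as the brain. Public bioactivity databases hold tens of
thousands of substrate and inhibition measurements for these transporters,
but the records are heterogeneous: mixed endpoints (IC50, Ki, EC50,
% inhibition, Km, Papp, efflux ratio), mixed units, conflicting results for
the same chemical, assay types that cannot support a substrate/inhibitor
call (e.g. ATPase assays), records filed under the wrong transporter, and
stereoisomer duplicates.

`abcqsar` is an R package for the full path from such raw records to
deployable classifiers:

1. **Curation** — each record is classified 1 (substrate/inhibitor),
   0 (nonsubstrate/noninhibitor), 0.5 (inconclusive) or NA (not applicable)
   by a configurable threshold table after unit normalization (e.g.
   inhibition IC50 ≤ 10 µM → 1, ≥ 50 µM → 0; substrate efflux ratio ≥ 2 →
   1, < 2 → 0) and rule-driven exclusions. A chemical's final label is the
   strict majority vote of its binary record labels; an exact tie is 0.5,
   and only binary-labeled chemicals enter training. Structures are
   standardized (largest organic component, stereochemistry stripped,
   canonical SMILES) and deduplicated retaining the highest activity.
   Datasets can be balanced by seeded undersampling or by appending pool
   negatives with MACCS-Tanimoto ≥ 0.8 to training inactives.
2. **Descriptors** — three sets per chemical: 1024-bit circular
   fingerprints (bond radius 3), the 166 MACCS substructure keys, and a
   fixed physicochemical panel (`physchem_panel()`).
3. **Modeling** — four algorithms (random forest, radial SVM, gradient
   boosted trees, feed-forward network) × three descriptor sets = 12
   individual models per dataset, each grid-searched by internal stratified
   cross-validation, plus a **consensus model** whose probability is the
   unweighted mean of the 12 member probabilities. Evaluation is by
   stratified 5-fold cross-validation with fold-internal preprocessing.
4. **Evaluation** — sensitivity, specificity, CCR = (sensitivity +
   specificity)/2, PPV, and rank-based AUC; a probability-band
   applicability domain (≥ 0.6 confident positive, ≤ 0.4 confident
   negative, in between out-of-domain); and Shapley attribution that ranks
   MACCS keys by mean absolute contribution to the predictions.
5. **Brain exposure** — the score
   `S = S_TPSA + S_HBD + S_HBA − S_efflux ∈ {−1,…,3}`, where the
   physicochemical terms score 1 for TPSA ≤ 90 Å², HBD ≤ 5, HBA ≤ 10 and
   the efflux term is 1 when the predicted P-gp and/or BCRP substrate
   probability is ≥ 0.5; plus stratified analyses against measured
   Kp,uu,brain at the 0.1 and 1.0 cuts.

A synthetic-data module generates chemical libraries with a planted
substructure motif that drives activity, emits record sets with realistic
curation hazards (conflicts, excludable assays, stereo duplicates, nM/µM
unit mixes), and produces a companion Kp,uu table whose values
anticorrelate with planted efflux-substrate status — so every stage is
testable without external databases.

## Worked example

```r
library(abcqsar)

spec    <- synthetic_spec(n_chemicals = 120, activity_noise = 0.1, seed = 7)
gen     <- generate_chemicals(spec)
records <- emit_records(gen$chemicals, gen$truth, spec,
                        transporter = "P-gp", activity_type = "inhibition")
dataset <- curate_records(records, "P-gp", "inhibition")
dataset
#> <transporter_dataset> P-gp inhibition: 114 chemicals (73 active / 41 inactive)
```

296 raw records collapse to 114 binary-labeled chemicals: conflicted
chemicals vote to 0.5 and are dropped, excludable records never enter the
vote, and stereo duplicates merge during standardization. Cross-validate
the 12-model suite and its consensus:

```r
smi  <- setNames(dataset$canonical_smiles, dataset$chemical_id)
mats <- list(ECFP6_1024 = compute_fingerprint(smi, "ECFP6_1024"),
             MACCS_166  = compute_fingerprint(smi, "MACCS_166"),
             PHYSCHEM   = compute_physchem(smi))
cv <- cross_validate(mats, dataset$label,
                     default_configs(seed = 1,
                                     grids = list(RF = list(ntree = 100),
                                                  SVM = list(cost = 1),
                                                  GBT = list(eta = 0.1),
                                                  FFNN = list(decay = 1e-2))),
                     plan = cv_plan(dataset$label, k = 5, seed = 1))
classification_metrics(cv$y, cv$prob[, "consensus"])[, 1:5]
#>   sensitivity specificity   ccr   ppv   auc
#> 1       0.904       0.829 0.867 0.904 0.875
```

The consensus recovers the planted structure–activity signal (CCR 0.867
against a chance level of 0.5; the 10% label noise caps attainable
accuracy). Restricting to the applicability domain trims 3 out-of-domain
chemicals and nudges the in-domain CCR to 0.886:

```r
ad <- metrics_in_domain(cv$y, cv$prob[, "consensus"])
ad$n_excluded      #> 3
ad$metrics$ccr     #> 0.886
```

Brain-exposure scoring for any compound set:

```r
props <- compute_brain_props(c(drug = "CC(=O)Oc1ccccc1C(=O)O"))
exposure_score(sub_scores(props), efflux_flag(0.2, 0.1))
#> 3  (TPSA 63.6, HBD 1, HBA 4 all favorable; predicted nonsubstrate)
```

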