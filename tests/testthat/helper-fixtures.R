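# Shared fixtures: record builders and a memoized small synthetic study so
# expensive chemistry/training is computed once per test run.

make_record <- function(chemical_id = "chem1", smiles = "c1ccccc1CC",
                        transporter = "P-gp", activity_type = "inhibition",
                        endpoint = "IC50", value = 5, units = "uM",
                        assay_type = "monolayer_flux",
                        target_as_assayed = transporter,
                        source_id = "src_01", comment = "") {
  data.frame(chemical_id = chemical_id, smiles = smiles,
             transporter = transporter, activity_type = activity_type,
             endpoint = endpoint, value = value, units = units,
             assay_type = assay_type, target_as_assayed = target_as_assayed,
             source_id = source_id, comment = comment,
             stringsAsFactors = FALSE)
}

make_dataset <- function(labels, transporter = "P-gp",
                         activity_type = "inhibition",
                         smiles = sprintf("S%03d", seq_along(labels))) {
  transporter_dataset(
    data.frame(chemical_id = sprintf("c%03d", seq_along(labels)),
               canonical_smiles = smiles, label = labels,
               stringsAsFactors = FALSE),
    transporter, activity_type)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small generated library with descriptor matrices, shared across files
small_synth <- function() {
  cached("small_synth", {
    spec <- synthetic_spec(n_chemicals = 60, activity_noise = 0,
                           conflict_rate = 0, excludable_assay_rate = 0,
                           stereo_duplicate_rate = 0, imbalance_ratio = 1,
                           seed = 42)
    gen <- generate_chemicals(spec)
    smi <- setNames(gen$chemicals$smiles, gen$chemicals$chemical_id)
    list(spec = spec, chemicals = gen$chemicals, truth = gen$truth,
         smiles = smi,
         matrices = list(ECFP6_1024 = compute_fingerprint(smi, "ECFP6_1024"),
                         MACCS_166 = compute_fingerprint(smi, "MACCS_166"),
                         PHYSCHEM = compute_physchem(smi)),
         y = gen$truth$true_class)
  })
}

# single-point grids: skip the internal grid search where the test is about
# pipeline structure rather than hyperparameter tuning
point_grids <- function() {
  list(RF = list(ntree = 100), SVM = list(cost = 1),
       GBT = list(eta = 0.1), FFNN = list(decay = 1e-2))
}
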