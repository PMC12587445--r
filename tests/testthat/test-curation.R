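# Record classification, majority voting, standardization, deduplication
# and dataset balancing.

test_that("record classification follows the threshold and exclusion rules", {
  # potency endpoints, canonical and nM units
  expect_equal(classify_record(make_record(endpoint = "IC50", value = 5, units = "uM")), 1)
  expect_equal(classify_record(make_record(endpoint = "IC50", value = 5000, units = "nM")), 1)
  expect_equal(classify_record(make_record(endpoint = "Ki", value = 100, units = "uM")), 0)
  expect_equal(classify_record(make_record(endpoint = "EC50", value = 20, units = "uM")), 0.5)
  # percent inhibition, including the <25% noninhibitor bound
  expect_equal(classify_record(make_record(endpoint = "pct_inhibition", value = 20, units = "percent")), 0)
  expect_equal(classify_record(make_record(endpoint = "pct_inhibition", value = 60, units = "percent")), 1)
  expect_equal(classify_record(make_record(endpoint = "pct_inhibition", value = 30, units = "percent")), 0.5)
  # substrate assays: the ratio-0.9 nonsubstrate case and the 2x substrate call
  er <- make_record(activity_type = "substrate", endpoint = "efflux_ratio",
                    value = 0.9, units = "ratio")
  expect_equal(classify_record(er), 0)
  er$value <- 3.5
  expect_equal(classify_record(er), 1)
  km <- make_record(activity_type = "substrate", endpoint = "Km",
                    value = 40, units = "uM")
  expect_equal(classify_record(km), 1)
  papp <- make_record(activity_type = "substrate", endpoint = "Papp",
                      value = 1e-5, units = "cm_per_s")
  expect_equal(classify_record(papp), 0.5)
})

test_that("excluded and malformed records return NA, never crash", {
  expect_true(is.na(classify_record(make_record(assay_type = "ATPase"))))
  expect_true(is.na(classify_record(make_record(assay_type = "atpase membrane"))))
  wrong <- make_record(transporter = "BCRP", target_as_assayed = "P-gp")
  expect_true(is.na(classify_record(wrong)))
  expect_true(is.na(classify_record(make_record(value = NA))))
  # mismatched units cannot be normalized
  expect_true(is.na(classify_record(make_record(units = "percent"))))
  # unknown endpoint combination warns and yields NA
  odd <- make_record(endpoint = "efflux_ratio", units = "ratio", value = 3)
  expect_warning(lab <- classify_record(odd), "no threshold rule")
  expect_true(is.na(lab))
  # source-level exclusion
  excl <- default_exclusions(sources = "src_01")
  expect_true(is.na(classify_record(make_record(), exclusions = excl)))
  # free-text comments
  cmt <- make_record(endpoint = "activity_comment", value = NA, comment = "substrate of P-gp")
  expect_equal(classify_record(cmt), 1)
  cmt$comment <- "confirmed nonsubstrate"
  expect_equal(classify_record(cmt), 0)
  cmt$comment <- "active"
  expect_warning(lab <- classify_record(cmt), "comment")
  expect_true(is.na(lab))
})

test_that("majority vote follows the strict-majority / tie / NA rules", {
  expect_equal(aggregate_chemical(c(1, 1, 0)), 1)
  expect_equal(aggregate_chemical(c(1, 0)), 0.5)
  expect_equal(aggregate_chemical(c(0, 0, 1)), 0)
  expect_true(is.na(aggregate_chemical(c(NA, NA))))
  expect_true(is.na(aggregate_chemical(numeric(0))))
  # inconclusive records carry no directional evidence
  expect_equal(aggregate_chemical(c(1, 0.5, 0.5)), 1)
  expect_true(is.na(aggregate_chemical(c(0.5, 0.5))))
  expect_equal(aggregate_chemical(c(0.5, 1, 0)), 0.5)
})

test_that("majority vote is invariant to record order", {
  set.seed(7)
  for (i in 1:25) {
    labs <- sample(c(0, 1, 0.5, NA), size = sample(1:6, 1), replace = TRUE)
    ref <- aggregate_chemical(labs)
    for (j in 1:5) {
      expect_identical(aggregate_chemical(sample(labs)), ref)
    }
  }
})

test_that("standardization keeps the largest organic component and strips stereo", {
  s <- standardize_structure("CCO.[Na+].[Cl-]")
  expect_equal(unname(s[1]), unname(standardize_structure("CCO")[1]))
  rej <- standardize_structure("[Na+].[Cl-]")
  expect_true(is.na(rej[1]))
  expect_match(attr(rej, "reason")[1], "organic")
  # enantiomers merge
  pair <- standardize_structure(c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O"))
  expect_equal(pair[[1]], pair[[2]])
  # unparseable input is rejected with a reason, not an error
  bad <- standardize_structure("xyz(((")
  expect_true(is.na(bad[1]))
  expect_match(attr(bad, "reason")[1], "unparseable")
  # largest component wins over a smaller organic counter-fragment
  mix <- standardize_structure("CC(=O)O.c1ccccc1CCCN")
  expect_equal(unname(mix[1]), unname(standardize_structure("c1ccccc1CCCN")[1]))
})

test_that("standardization is idempotent", {
  raw <- c("CCO.[Na+].[Cl-]", "C[C@H](N)C(=O)O", "c1ccc(CC(=O)O)cc1CC",
           small_synth()$chemicals$smiles[1:10])
  once <- standardize_structure(raw)
  twice <- standardize_structure(once)
  expect_equal(unname(twice), unname(once))
})

test_that("deduplication keeps the highest activity", {
  ent <- data.frame(chemical_id = c("a", "b"),
                    canonical_smiles = c("X", "X"),
                    label = c(1, 0), potency = c(NA, NA))
  expect_equal(deduplicate(ent)$label, 1)
  ent$label <- c(0, 0)
  d <- deduplicate(ent)
  expect_equal(nrow(d), 1)
  expect_equal(d$label, 0)
  ent2 <- data.frame(chemical_id = c("a", "b"),
                     canonical_smiles = "X", label = 1, potency = c(8, 2))
  expect_equal(deduplicate(ent2)$potency, 2)
})

test_that("train/external overlap resolution drops conflicts from both sets", {
  train <- make_dataset(c(1, 0, 1), smiles = c("A", "B", "C"))
  external <- make_dataset(c(1, 1, 0), smiles = c("A", "B", "D"))
  res <- resolve_external_conflicts(train, external)
  # A agrees: dropped from external only; B conflicts: dropped from both
  expect_setequal(res$train$canonical_smiles, c("A", "C"))
  expect_setequal(res$external$canonical_smiles, "D")
  # no overlap leaves both unchanged
  res2 <- resolve_external_conflicts(make_dataset(1, smiles = "A"),
                                     make_dataset(1, smiles = "Z"))
  expect_equal(nrow(res2$train), 1)
  expect_equal(nrow(res2$external), 1)
})

test_that("undersampling balances classes reproducibly", {
  ds <- make_dataset(c(rep(1, 100), rep(0, 40)))
  bal <- balance_undersample(ds, seed = 3)
  expect_equal(sum(bal$label == 1), 40)
  expect_equal(sum(bal$label == 0), 40)
  expect_identical(balance_undersample(ds, seed = 3)$chemical_id, bal$chemical_id)
  even <- make_dataset(c(rep(1, 10), rep(0, 10)))
  expect_identical(balance_undersample(even, seed = 1)$chemical_id, even$chemical_id)
})

test_that("similarity supplementation matches brute-force Tanimoto selection", {
  ds <- make_dataset(c(1, 1, 1, 0),
                     smiles = c("c1ccccc1CCN", "c1ccncc1CC", "CC(C)CCO", "CCO"))
  pool <- data.frame(
    chemical_id = c("p1", "p2", "p3"),
    canonical_smiles = c("CCO",                      # identical to a negative
                         "OCC",                      # same molecule, different writing
                         "c1ccc2ccccc2c1SC(F)(F)F"), # dissimilar
    stringsAsFactors = FALSE)
  # brute-force qualification using the scalar tanimoto on MACCS keys
  fp_pool <- compute_fingerprint(setNames(pool$canonical_smiles, pool$chemical_id),
                                 "MACCS_166")
  fp_neg <- compute_fingerprint("CCO", "MACCS_166")
  brute <- vapply(seq_len(nrow(fp_pool)), function(i) {
    max(vapply(seq_len(nrow(fp_neg)), function(j) {
      tanimoto(fp_pool[i, ], fp_neg[j, ])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(brute[1], 1)     # identical fingerprint
  expect_true(brute[3] < 0.8)   # dissimilar pool member must not qualify
  out <- suppressWarnings(supplement_by_similarity(pool, ds, cutoff = 0.8, seed = 1))
  added <- setdiff(out$chemical_id, ds$chemical_id)
  expect_true(all(added %in% pool$chemical_id[brute >= 0.8]))
  expect_true(all(out$label[out$chemical_id %in% added] == 0))
})

test_that("adding an exclusion rule never increases dataset size", {
  spec <- synthetic_spec(n_chemicals = 40, seed = 9, activity_noise = 0,
                         conflict_rate = 0, stereo_duplicate_rate = 0,
                         excludable_assay_rate = 0.3)
  gen <- generate_chemicals(spec)
  rec <- emit_records(gen$chemicals, gen$truth, spec)
  base <- curate_records(rec, "P-gp", "inhibition",
                         exclusions = default_exclusions())
  stricter <- curate_records(rec, "P-gp", "inhibition",
                             exclusions = default_exclusions(sources = c("src_01", "src_02")))
  expect_lte(nrow(stricter), nrow(base))
})
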