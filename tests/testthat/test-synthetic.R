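# The synthetic-data generator: determinism, planted signal, hazards, and
# the brain-exposure companion table.

test_that("spec validation rejects out-of-range parameters and bad motifs", {
  expect_error(synthetic_spec(n_chemicals = 1))
  expect_error(synthetic_spec(activity_noise = 1.5))
  expect_error(synthetic_spec(conflict_rate = -0.1))
  expect_error(synthetic_spec(imbalance_ratio = 0))
  bad <- synthetic_spec(n_chemicals = 10, planted_motif = "[[[not-smarts")
  expect_error(generate_chemicals(bad), "planted_motif")
  # a parseable pattern carried by no library substituent is a config error
  unmatched <- synthetic_spec(n_chemicals = 10, planted_motif = "[Se]")
  expect_error(generate_chemicals(unmatched), "matches no substituent")
})

test_that("identical specs generate byte-identical outputs", {
  spec <- synthetic_spec(n_chemicals = 25, seed = 42)
  a <- generate_chemicals(spec)
  b <- generate_chemicals(spec)
  expect_identical(a, b)
  expect_identical(emit_records(a$chemicals, a$truth, spec),
                   emit_records(b$chemicals, b$truth, spec))
  expect_identical(generate_kpuu_table(a$chemicals, a$truth, spec),
                   generate_kpuu_table(b$chemicals, b$truth, spec))
})

test_that("noise-free planting yields exactly the requested positives", {
  spec <- synthetic_spec(n_chemicals = 10, activity_noise = 0,
                         imbalance_ratio = 1, seed = 3)
  gen <- generate_chemicals(spec)
  expect_equal(sum(gen$chemicals$has_motif), 5)
  expect_identical(gen$truth$true_class, as.integer(gen$chemicals$has_motif))
  expect_true(all(ob_valid <- !is.na(standardize_structure(gen$chemicals$smiles))))
})

test_that("label noise flips the motif indicator at the requested rate", {
  spec <- synthetic_spec(n_chemicals = 200, activity_noise = 0.1, seed = 7)
  gen <- generate_chemicals(spec)
  flipped <- mean(gen$truth$true_class != as.integer(gen$chemicals$has_motif))
  # binomial 3-sigma band around 0.1 at n = 200
  expect_gt(flipped, 0.1 - 3 * sqrt(0.1 * 0.9 / 200))
  expect_lt(flipped, 0.1 + 3 * sqrt(0.1 * 0.9 / 200))
})

test_that("forced conflicts aggregate every chemical to 0.5", {
  spec <- synthetic_spec(n_chemicals = 15, conflict_rate = 1,
                         records_per_chemical = 2, activity_noise = 0,
                         excludable_assay_rate = 0, stereo_duplicate_rate = 0,
                         seed = 5)
  gen <- generate_chemicals(spec)
  rec <- emit_records(gen$chemicals, gen$truth, spec)
  labs <- classify_record(rec)
  agg <- vapply(split(labs, rec$chemical_id), aggregate_chemical, numeric(1))
  expect_true(all(agg == 0.5))
})

test_that("hazard-free curation recovers the latent truth exactly", {
  for (at in c("inhibition", "substrate")) {
    spec <- synthetic_spec(n_chemicals = 40, activity_noise = 0,
                           conflict_rate = 0, excludable_assay_rate = 0,
                           stereo_duplicate_rate = 0, seed = 11)
    gen <- generate_chemicals(spec)
    rec <- emit_records(gen$chemicals, gen$truth, spec,
                        transporter = "BCRP", activity_type = at)
    ds <- curate_records(rec, "BCRP", at)
    expect_equal(nrow(ds), 40)
    truth <- gen$truth$true_class[match(ds$chemical_id, gen$truth$chemical_id)]
    expect_identical(as.integer(ds$label), truth)
  }
})

test_that("excludable-assay hazards are neutralized by the exclusion rules", {
  spec <- synthetic_spec(n_chemicals = 50, activity_noise = 0,
                         conflict_rate = 0, excludable_assay_rate = 0.5,
                         stereo_duplicate_rate = 0, seed = 13)
  gen <- generate_chemicals(spec)
  rec <- emit_records(gen$chemicals, gen$truth, spec)
  expect_true(any(rec$assay_type == "ATPase"))
  expect_true(any(rec$target_as_assayed != rec$transporter))
  ds <- curate_records(rec, "P-gp", "inhibition")
  truth <- gen$truth$true_class[match(ds$chemical_id, gen$truth$chemical_id)]
  # every chemical that survives curation carries its true label
  expect_identical(as.integer(ds$label), truth)
})

test_that("stereo duplicates standardize onto one entry", {
  spec <- synthetic_spec(n_chemicals = 30, activity_noise = 0,
                         conflict_rate = 0, excludable_assay_rate = 0,
                         stereo_duplicate_rate = 0.5, seed = 17)
  gen <- generate_chemicals(spec)
  rec <- emit_records(gen$chemicals, gen$truth, spec)
  expect_true(any(grepl("_iso$", rec$chemical_id)))
  ds <- curate_records(rec, "P-gp", "inhibition")
  expect_false(anyDuplicated(ds$canonical_smiles) > 0)
  expect_lte(nrow(ds), 30)
})

test_that("raising the conflict rate raises the count of 0.5 chemicals", {
  count_half <- function(rate, seed) {
    spec <- synthetic_spec(n_chemicals = 40, conflict_rate = rate,
                           activity_noise = 0, excludable_assay_rate = 0,
                           stereo_duplicate_rate = 0, seed = seed)
    gen <- generate_chemicals(spec)
    rec <- emit_records(gen$chemicals, gen$truth, spec)
    labs <- classify_record(rec)
    agg <- vapply(split(labs, rec$chemical_id), aggregate_chemical, numeric(1))
    sum(agg == 0.5, na.rm = TRUE)
  }
  lo <- sum(vapply(1:3, function(s) count_half(0.05, s), numeric(1)))
  hi <- sum(vapply(1:3, function(s) count_half(0.6, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("Kp,uu regimes enrich substrates below the 0.1 cut", {
  spec <- synthetic_spec(n_chemicals = 200, seed = 19)
  gen <- generate_chemicals(spec)
  # degenerate regimes: all substrates far below the cut, nonsubstrates above
  all_sub <- gen$truth; all_sub$true_class <- 1L
  kp <- generate_kpuu_table(gen$chemicals, all_sub, spec, sdlog = 0.2)
  expect_true(all(kp$kpuu < 0.1))
  none <- gen$truth; none$true_class <- 0L
  kp0 <- generate_kpuu_table(gen$chemicals, none, spec, sdlog = 0.2)
  expect_gte(median(kp0$kpuu), 0.1)
  # mixed set under the default regimes: substrate fraction higher below 0.1
  kp_mix <- generate_kpuu_table(gen$chemicals, gen$truth, spec)
  is_sub <- gen$truth$true_class == 1
  low <- kp_mix$kpuu < 0.1
  expect_gt(mean(is_sub[low]), mean(is_sub[!low]))
})

test_that("record tables round-trip through CSV", {
  spec <- synthetic_spec(n_chemicals = 10, seed = 23)
  gen <- generate_chemicals(spec)
  rec <- emit_records(gen$chemicals, gen$truth, spec)
  path <- tempfile(fileext = ".csv")
  write_records(rec, path)
  back <- read_records(path)
  expect_equal(back$chemical_id, rec$chemical_id)
  expect_equal(back$value, rec$value, tolerance = 1e-12)
  expect_equal(back$smiles, rec$smiles)
})
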