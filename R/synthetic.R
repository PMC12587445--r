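# Synthetic chemical libraries and bioactivity record sets with a planted
# structure-activity signal and controllable curation hazards, plus a
# brain-exposure companion table. Everything is deterministic under the
# spec seed.

# Scaffold templates with two substitution slots. Substituents are written
# as SMILES branch fragments; every (scaffold, s1, s2) combination is a
# valid molecule by construction.
SYNTH_SCAFFOLDS <- c(
  benzene     = "c1ccc(%s)cc1%s",
  pyridine    = "c1ccnc(%s)c1%s",
  cyclohexane = "C1CCC(%s)CC1%s",
  thiophene   = "c1cc(%s)sc1%s",
  furan       = "c1cc(%s)oc1%s",
  piperidine  = "C1CCN(%s)CC1%s"
)

# Substituent library. Polar entries carry the kinds of functional groups a
# motif pattern may target; the default planted motif (carboxylic acid)
# matches "CC(=O)O" and "C(=O)O" only.
SYNTH_SUBSTITUENTS <- c(
  "C", "CC", "CCC", "CCCC", "CC(C)C", "CCN", "OC", "OCC", "N(C)C",
  "Cl", "F", "Br", "C#N", "C(F)(F)F", "SC", "CCOC",
  "CC(=O)O", "C(=O)O", "CCC(=O)O", "CC(C)C(=O)O",
  "S(N)(=O)=O", "C(N)=O"
)

# chiral fragment pair used to mint stereoisomer duplicates
SYNTH_CHIRAL <- c("[C@@H](C)N", "[C@H](C)N")

#' Specification for a synthetic study dataset
#'
#' Bundles and validates every knob of the generator: library size, the
#' planted substructure motif that drives activity, the label-flip noise,
#' record multiplicity, hazard rates (conflicting records, excludable
#' assays, stereoisomer duplicates), the endpoint mix, the target class
#' ratio and the seed. The same spec always generates byte-identical
#' output.
#'
#' @param n_chemicals number of base chemicals (>= 2).
#' @param planted_motif SMARTS pattern whose presence drives activity. It
#'   must match at least one substituent of the generator's library;
#'   patterns OpenBabel cannot parse, or that no library substituent
#'   carries, raise a configuration error at generation time.
#' @param activity_noise probability in \[0,1\] of flipping a latent label
#'   away from the motif indicator.
#' @param records_per_chemical mean number of records per chemical (>= 1;
#'   counts are 1 + Poisson(mean - 1)).
#' @param conflict_rate probability a chemical receives an exactly tied set
#'   of contradictory records.
#' @param endpoint_mix named non-negative weights over the endpoints
#'   IC50, Ki, EC50, pct_inhibition, Km, Papp, efflux_ratio. The default is
#'   inhibition-heavy (IC50 dominant) for inhibition datasets and
#'   efflux-ratio-heavy for substrate datasets.
#' @param excludable_assay_rate probability a record carries an excludable
#'   assay type (ATPase) or a wrong-target annotation; such records get
#'   class-inconsistent values, so failing to exclude them corrupts labels.
#' @param stereo_duplicate_rate probability a chemical is emitted together
#'   with a stereoisomer duplicate under a separate identifier.
#' @param imbalance_ratio target positive:negative ratio of latent classes.
#' @param seed integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chemicals = 200,
                           planted_motif = "C(=O)[OX2H1]",
                           activity_noise = 0.1,
                           records_per_chemical = 2.5,
                           conflict_rate = 0.05,
                           endpoint_mix = NULL,
                           excludable_assay_rate = 0.05,
                           stereo_duplicate_rate = 0.05,
                           imbalance_ratio = 1.5,
                           seed = 1) {
  stopifnot(n_chemicals >= 2,
            activity_noise >= 0, activity_noise <= 1,
            records_per_chemical >= 1,
            conflict_rate >= 0, conflict_rate <= 1,
            excludable_assay_rate >= 0, excludable_assay_rate <= 1,
            stereo_duplicate_rate >= 0, stereo_duplicate_rate <= 1,
            imbalance_ratio > 0)
  if (!is.null(endpoint_mix)) {
    stopifnot(!is.null(names(endpoint_mix)), all(endpoint_mix >= 0),
              sum(endpoint_mix) > 0)
  }
  structure(list(n_chemicals = as.integer(n_chemicals),
                 planted_motif = planted_motif,
                 activity_noise = activity_noise,
                 records_per_chemical = records_per_chemical,
                 conflict_rate = conflict_rate,
                 endpoint_mix = endpoint_mix,
                 excludable_assay_rate = excludable_assay_rate,
                 stereo_duplicate_rate = stereo_duplicate_rate,
                 imbalance_ratio = imbalance_ratio,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# default endpoint mixes per activity type (inhibition data dominate public
# transporter records, with IC50 the most common endpoint)
default_endpoint_mix <- function(activity_type) {
  if (activity_type == "inhibition") {
    c(IC50 = 0.45, pct_inhibition = 0.30, Ki = 0.15, EC50 = 0.10)
  } else {
    c(efflux_ratio = 0.60, Km = 0.20, Papp = 0.20)
  }
}

# which substituents match / avoid the motif SMARTS, probed on an actual
# benzene attachment so ring-context patterns behave as in real molecules
motif_substituent_split <- function(planted_motif) {
  probes <- sprintf("c1ccc(%s)cc1C", SYNTH_SUBSTITUENTS)
  counts <- tryCatch({
    ob_smarts_count(setNames(probes, sprintf("p%02d", seq_along(probes))),
                    planted_motif)
  }, error = function(e) {
    stop("invalid planted_motif pattern '", planted_motif, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (all(counts == 0) || all(is.na(counts))) {
    stop("planted_motif '", planted_motif,
         "' matches no substituent in the generator library", call. = FALSE)
  }
  list(motif = SYNTH_SUBSTITUENTS[counts > 0],
       decor = SYNTH_SUBSTITUENTS[counts == 0])
}

#' Generate a synthetic chemical library with a planted activity motif
#'
#' Chemicals are assembled by attaching two substituents to a small scaffold
#' set, which guarantees parseable structures and a controllable motif
#' frequency. A fraction `imbalance_ratio / (1 + imbalance_ratio)` of the
#' library carries a motif-matching substituent. Motif presence is then
#' *verified* on the assembled molecule by SMARTS matching (construction can
#' never disagree with the indicator), and the latent class is this
#' indicator flipped with probability `activity_noise`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `chemicals` (data.frame `chemical_id`, `smiles`,
#'   `has_motif`, `has_stereo`) and `truth` (data.frame `chemical_id`,
#'   `true_class`).
#' @export
generate_chemicals <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  subs <- motif_substituent_split(spec$planted_motif)
  n <- spec$n_chemicals
  r <- spec$imbalance_ratio
  n_pos <- round(n * r / (1 + r))

  with_seed(spec$seed, {
    want_motif <- sample(c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
    has_stereo <- runif(n) < spec$stereo_duplicate_rate
    smiles <- character(n)
    seen <- character(0)
    for (i in seq_len(n)) {
      for (try in 1:200) {
        scaf <- sample(SYNTH_SCAFFOLDS, 1)
        s1 <- if (want_motif[i]) sample(subs$motif, 1) else sample(subs$decor, 1)
        s2 <- if (has_stereo[i]) SYNTH_CHIRAL[1] else sample(subs$decor, 1)
        cand <- sprintf(scaf, s1, s2)
        if (!cand %in% seen) break
        if (try == 200) stop("combinatorial space exhausted; reduce n_chemicals")
      }
      smiles[i] <- cand
      seen <- c(seen, cand)
    }
    ids <- sprintf("SYN%05d", seq_len(n))
    present <- ob_smarts_count(setNames(smiles, ids), spec$planted_motif) > 0
    flip <- runif(n) < spec$activity_noise
    true_class <- as.integer(xor(present, flip))
    list(
      chemicals = data.frame(chemical_id = ids, smiles = smiles,
                             has_motif = present, has_stereo = has_stereo,
                             stringsAsFactors = FALSE),
      truth = data.frame(chemical_id = ids, true_class = true_class,
                         stringsAsFactors = FALSE)
    )
  })
}

# class-consistent value regions per endpoint (canonical units), with a
# two-fold margin from every threshold so unit-conversion bugs surface as
# misclassifications rather than near-misses
synth_value <- function(endpoint, positive, n = 1) {
  draw_log <- function(lo, hi) exp(runif(n, log(lo), log(hi)))
  switch(endpoint,
    IC50 = , Ki = , EC50 = if (positive) draw_log(0.1, 5) else draw_log(100, 2000),
    pct_inhibition = if (positive) runif(n, 70, 100) else runif(n, 0, 12.5),
    efflux_ratio = if (positive) draw_log(4, 40) else draw_log(0.1, 1),
    Km = draw_log(1, 100),
    Papp = draw_log(1e-6, 5e-5),
    stop("no value model for endpoint ", endpoint)
  )
}

# endpoints able to encode a given class decisively
decisive_endpoints <- function(activity_type, positive) {
  if (activity_type == "inhibition") {
    c("IC50", "Ki", "EC50", "pct_inhibition")
  } else if (positive) {
    c("efflux_ratio", "Km")
  } else {
    "efflux_ratio"
  }
}

#' Emit bioactivity records for a synthetic chemical library
#'
#' Every chemical receives at least one record whose value is drawn inside
#' the class-consistent region of the default threshold table, so that
#' hazard-free curation recovers the latent truth exactly. Hazards are
#' injected on top: conflicted chemicals get an exactly tied pair of
#' contradictory decisive records (vote 0.5); excludable records (ATPase
#' assay type or wrong-target annotation) carry class-inconsistent values;
#' stereo-flagged chemicals are re-emitted as a stereoisomer duplicate under
#' a separate identifier. Concentration endpoints randomize between nM and
#' uM to exercise unit normalization.
#'
#' @param chemicals,truth as returned by [generate_chemicals()].
#' @param spec the [synthetic_spec()] used to generate them.
#' @param transporter,activity_type dataset the records belong to.
#' @return data.frame of bioactivity records (one row per record).
#' @export
emit_records <- function(chemicals, truth, spec,
                         transporter = "P-gp", activity_type = "inhibition") {
  transporter <- match.arg(transporter, TRANSPORTERS)
  activity_type <- match.arg(activity_type, ACTIVITY_TYPES)
  mix <- spec$endpoint_mix %||% default_endpoint_mix(activity_type)
  allowed <- if (activity_type == "inhibition") {
    c("IC50", "Ki", "EC50", "pct_inhibition")
  } else {
    c("efflux_ratio", "Km", "Papp")
  }
  mix <- mix[names(mix) %in% allowed]
  if (length(mix) == 0 || sum(mix) == 0) {
    stop("endpoint_mix has no endpoints usable for ", activity_type, " data")
  }
  assays <- c("monolayer_flux", "vesicle_uptake", "cell_accumulation")
  other_targets <- setdiff(TRANSPORTERS, transporter)

  with_seed(spec$seed + 1L, {
    rows <- vector("list", nrow(chemicals) * 2)
    ri <- 0
    emit_one <- function(chem_id, smi, positive, decisive_first) {
      n_rec <- 1 + rpois(1, spec$records_per_chemical - 1)
      eps <- sample(names(mix), n_rec, replace = TRUE, prob = mix)
      dec <- decisive_endpoints(activity_type, positive)
      if (decisive_first && !any(eps %in% dec)) {
        eps[1] <- sample(dec, 1)
      }
      out <- vector("list", n_rec)
      for (k in seq_len(n_rec)) {
        ep <- eps[k]
        can_encode <- ep %in% decisive_endpoints(activity_type, positive)
        cls <- positive
        assay <- sample(assays, 1)
        tgt <- transporter
        if (runif(1) < spec$excludable_assay_rate) {
          # excludable hazard: wrong value region + excludable metadata
          if (runif(1) < 0.5) assay <- "ATPase" else tgt <- sample(other_targets, 1)
          cls <- !positive
          if (!ep %in% decisive_endpoints(activity_type, cls)) {
            ep <- sample(decisive_endpoints(activity_type, cls), 1)
          }
        } else if (!can_encode && ep != "Papp") {
          ep <- sample(decisive_endpoints(activity_type, positive), 1)
        }
        val <- synth_value(ep, cls)
        units <- switch(ep,
          IC50 = , Ki = , EC50 = , Km = sample(c("uM", "nM"), 1),
          pct_inhibition = "percent",
          efflux_ratio = "ratio",
          Papp = "cm_per_s")
        if (units == "nM") val <- val * 1000
        out[[k]] <- data.frame(
          chemical_id = chem_id, smiles = smi, transporter = transporter,
          activity_type = activity_type, endpoint = ep, value = val,
          units = units, assay_type = assay, target_as_assayed = tgt,
          source_id = sprintf("src_%02d", sample.int(20, 1)), comment = "",
          stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }
    emit_conflict <- function(chem_id, smi) {
      # exactly tied decisive evidence: one positive-region record per
      # negative-region record
      n_pairs <- max(1, round((1 + rpois(1, spec$records_per_chemical - 1)) / 2))
      pair <- function(positive) {
        ep <- sample(decisive_endpoints(activity_type, positive), 1)
        val <- synth_value(ep, positive)
        units <- switch(ep,
          IC50 = , Ki = , EC50 = , Km = sample(c("uM", "nM"), 1),
          pct_inhibition = "percent", efflux_ratio = "ratio")
        if (units == "nM") val <- val * 1000
        data.frame(chemical_id = chem_id, smiles = smi,
                   transporter = transporter, activity_type = activity_type,
                   endpoint = ep, value = val, units = units,
                   assay_type = sample(assays, 1), target_as_assayed = transporter,
                   source_id = sprintf("src_%02d", sample.int(20, 1)),
                   comment = "", stringsAsFactors = FALSE)
      }
      do.call(rbind, c(replicate(n_pairs, pair(TRUE), simplify = FALSE),
                       replicate(n_pairs, pair(FALSE), simplify = FALSE)))
    }

    for (i in seq_len(nrow(chemicals))) {
      id <- chemicals$chemical_id[i]
      smi <- chemicals$smiles[i]
      positive <- truth$true_class[truth$chemical_id == id] == 1
      conflicted <- runif(1) < spec$conflict_rate
      ri <- ri + 1
      rows[[ri]] <- if (conflicted) emit_conflict(id, smi)
                    else emit_one(id, smi, positive, decisive_first = TRUE)
      if (chemicals$has_stereo[i] && !conflicted) {
        # stereoisomer duplicate: epimeric SMILES, own identifier
        iso <- sub(SYNTH_CHIRAL[1], SYNTH_CHIRAL[2], smi, fixed = TRUE)
        ri <- ri + 1
        rows[[ri]] <- emit_one(paste0(id, "_iso"), iso, positive,
                               decisive_first = TRUE)
      }
    }
    res <- do.call(rbind, rows[seq_len(ri)])
    rownames(res) <- NULL
    res
  })
}

#' Generate a companion unbound brain-to-plasma ratio table
#'
#' Kp,uu,brain values are drawn from two log-normal regimes straddling the
#' 0.1 exposure cut: efflux substrates from median 0.02 and nonsubstrates
#' from median 0.5 (sdlog 1), so substrates are enriched below 0.1.
#'
#' @param chemicals,truth as returned by [generate_chemicals()].
#' @param spec the [synthetic_spec()].
#' @param median_substrate,median_nonsubstrate,sdlog regime parameters.
#' @return data.frame with columns `chemical_id`, `kpuu`.
#' @export
generate_kpuu_table <- function(chemicals, truth, spec,
                                median_substrate = 0.02,
                                median_nonsubstrate = 0.5,
                                sdlog = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cls <- truth$true_class[match(chemicals$chemical_id, truth$chemical_id)]
  with_seed(spec$seed + 2L, {
    med <- ifelse(cls == 1, median_substrate, median_nonsubstrate)
    data.frame(chemical_id = chemicals$chemical_id,
               kpuu = rlnorm(nrow(chemicals), meanlog = log(med), sdlog = sdlog),
               stringsAsFactors = FALSE)
  })
}

#' Build the eight synthetic study datasets
#'
#' One dataset per transporter x activity type, each generated from its own
#' derived seed and curated end-to-end from emitted records (classification,
#' vote, standardization, deduplication).
#'
#' @param n_chemicals chemicals per dataset.
#' @param seed base seed; dataset k uses `seed + k`.
#' @param ... further arguments passed to [synthetic_spec()].
#' @return named list of eight [transporter_dataset()] objects
#'   (`"P-gp.substrate"`, `"P-gp.inhibition"`, ...).
#' @export
synthesize_study <- function(n_chemicals = 80, seed = 1, ...) {
  combos <- expand.grid(transporter = TRANSPORTERS,
                        activity_type = ACTIVITY_TYPES,
                        stringsAsFactors = FALSE)
  out <- vector("list", nrow(combos))
  names(out) <- paste(combos$transporter, combos$activity_type, sep = ".")
  for (k in seq_len(nrow(combos))) {
    spec <- synthetic_spec(n_chemicals = n_chemicals, seed = seed + k, ...)
    gen <- generate_chemicals(spec)
    rec <- emit_records(gen$chemicals, gen$truth, spec,
                        transporter = combos$transporter[k],
                        activity_type = combos$activity_type[k])
    out[[k]] <- curate_records(rec, combos$transporter[k],
                               combos$activity_type[k])
  }
  out
}

#' Write / read bioactivity record tables as CSV
#'
#' Plain-text interchange for the record schema; SMILES are written
#' unescaped.
#'
#' @param records data.frame of records.
#' @param path file path.
#' @export
write_records <- function(records, path) {
  stopifnot(all(RECORD_COLUMNS %in% names(records)))
  write.csv(records[RECORD_COLUMNS], path, row.names = FALSE)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(value = "numeric"))
}
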