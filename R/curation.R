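# Curation: record classification, majority voting, structure
# standardization, deduplication, and dataset balancing.

RECORD_COLUMNS <- c("chemical_id", "smiles", "transporter", "activity_type",
                    "endpoint", "value", "units", "assay_type",
                    "target_as_assayed", "source_id", "comment")

#' Classify bioactivity records into 1 / 0 / 0.5 / NA
#'
#' Applies the exclusion rules and the endpoint threshold table to each
#' record of a bioactivity table. A record is not-applicable (`NA`) when its
#' assay type is excluded (e.g. ATPase), when the assay actually measured a
#' different transporter than the record's, when its source is excluded, or
#' when essential data (a finite value for a quantitative endpoint, a
#' resolvable unit) are missing. Otherwise the value is normalized to the
#' endpoint's canonical unit and compared against the positive and negative
#' rules: 1 (substrate/inhibitor), 0 (nonsubstrate/noninhibitor), or 0.5
#' (inconclusive) when it falls between the two regions.
#'
#' `activity_comment` endpoints are classified from the free-text `comment`
#' field: an explicit "substrate"/"inhibitor" annotation maps to 1 and a
#' "nonsubstrate"/"noninhibitor" annotation to 0; anything else (including
#' bare "active") is NA with a warning, since such comments do not carry a
#' usable activity type.
#'
#' Unknown (activity type, endpoint) combinations yield NA with a warning,
#' never an error: the engine refuses to guess what, e.g., an inhibition
#' "ratio" endpoint means.
#'
#' @param records data.frame of bioactivity records (see [emit_records()]
#'   for the column schema).
#' @param thresholds threshold table, see [default_thresholds()].
#' @param exclusions exclusion rules, see [default_exclusions()].
#' @return numeric vector of labels in \{1, 0, 0.5, NA\}, one per record.
#' @export
#' @examples
#' rec <- data.frame(chemical_id = "x", smiles = "c1ccccc1",
#'                   transporter = "P-gp", activity_type = "inhibition",
#'                   endpoint = "IC50", value = 5, units = "uM",
#'                   assay_type = "monolayer_flux",
#'                   target_as_assayed = "P-gp", source_id = "s1", comment = "")
#' classify_record(rec)  # 1: IC50 of 5 uM is at or below the 10 uM bound
classify_record <- function(records, thresholds = default_thresholds(),
                            exclusions = default_exclusions()) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  lab <- rep(NA_real_, n)
  if (n == 0) return(lab)

  assay <- as.character(records$assay_type %||% rep("", n))
  excluded <- rep(FALSE, n)
  for (pat in exclusions$assay_types) {
    excluded <- excluded | grepl(pat, assay, ignore.case = TRUE)
  }
  if (length(exclusions$sources)) {
    excluded <- excluded | (as.character(records$source_id) %in% exclusions$sources)
  }
  target <- as.character(records$target_as_assayed %||% records$transporter)
  wrong_target <- !is.na(target) & nzchar(target) & target != as.character(records$transporter)
  excluded <- excluded | wrong_target

  endpoint <- as.character(records$endpoint)
  activity <- as.character(records$activity_type)
  value <- as.numeric(records$value)
  units <- as.character(records$units)
  comment <- tolower(as.character(records$comment %||% rep("", n)))

  # free-text classification comments
  is_comment <- endpoint == "activity_comment" & !excluded
  if (any(is_comment)) {
    neg <- grepl("non[ -]?substrate|non[ -]?inhibitor|not a substrate|not an inhibitor",
                 comment)
    pos <- !neg & grepl("\\bsubstrate\\b|\\binhibitor\\b", comment)
    lab[is_comment & pos] <- 1
    lab[is_comment & neg] <- 0
    unresolved <- is_comment & !pos & !neg
    if (any(unresolved)) {
      warning(sum(unresolved), " activity_comment record(s) without an ",
              "interpretable classification comment; marked NA", call. = FALSE)
    }
  }

  quantitative <- !is_comment & !excluded
  idx <- which(quantitative)
  if (length(idx)) {
    key <- paste(activity, endpoint, sep = "|")
    tkey <- paste(thresholds$activity_type, thresholds$endpoint, sep = "|")
    row <- match(key, tkey)
    unknown <- quantitative & is.na(row)
    if (any(unknown)) {
      warning("no threshold rule for endpoint(s): ",
              paste(unique(key[unknown]), collapse = ", "),
              "; marked NA", call. = FALSE)
    }
    for (i in idx) {
      r <- row[i]
      if (is.na(r)) next
      v <- normalize_value(value[i], units[i], thresholds$unit_class[r])
      if (is.na(v) || !is.finite(v)) next  # missing/unconvertible -> NA
      pos_hit <- !is.na(thresholds$pos_cmp[r]) &&
        do.call(thresholds$pos_cmp[r], list(v, thresholds$pos_value[r]))
      neg_hit <- !is.na(thresholds$neg_cmp[r]) &&
        do.call(thresholds$neg_cmp[r], list(v, thresholds$neg_value[r]))
      lab[i] <- if (pos_hit) 1 else if (neg_hit) 0 else 0.5
    }
  }
  lab
}

#' Aggregate per-record labels into a chemical-level label by majority vote
#'
#' Not-applicable records are removed first; inconclusive (0.5) records are
#' then set aside, as they carry no directional evidence. A strict majority
#' of the remaining binary labels decides the chemical's class; an equal
#' number of conflicting binary labels yields 0.5; if nothing remains the
#' result is NA. The vote is invariant to record order.
#'
#' @param labels numeric vector of per-record labels in \{1, 0, 0.5, NA\}.
#' @return a single value in \{1, 0, 0.5, NA\}.
#' @export
#' @examples
#' aggregate_chemical(c(1, 1, 0))  # 1
#' aggregate_chemical(c(1, 0))     # 0.5: one inhibitor vs one noninhibitor
aggregate_chemical <- function(labels) {
  if (length(labels) == 0) return(NA_real_)
  v <- labels[!is.na(labels)]
  v <- v[v %in% c(0, 1)]
  if (length(v) == 0) return(NA_real_)
  n1 <- sum(v == 1); n0 <- sum(v == 0)
  if (n1 > n0) 1 else if (n0 > n1) 0 else 0.5
}

#' Standardize structures to stereochemistry-free canonical SMILES
#'
#' For each input SMILES the largest organic component (by heavy-atom count;
#' "organic" requires at least one carbon) is retained, counter-ions and
#' solvents are discarded, stereochemistry is stripped (the pipeline is
#' strictly 2D), and the result is written as OpenBabel canonical SMILES.
#' Inorganic-only and unparseable inputs are rejected: the returned vector
#' holds `NA` at their positions and the attached `"reason"` attribute says
#' why. The operation is idempotent: re-standardizing an output returns it
#' unchanged.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES (NA where rejected) with a
#'   `"reason"` character attribute aligned with the input.
#' @export
#' @examples
#' standardize_structure("CCO.[Na+].[Cl-]")   # keeps the ethanol component
#' standardize_structure("[Na+].[Cl-]")       # rejected: inorganic
standardize_structure <- function(smiles) {
  smiles <- as.character(smiles)
  out <- rep(NA_character_, length(smiles))
  reason <- rep(NA_character_, length(smiles))
  if (length(smiles) == 0) return(structure(out, reason = reason))

  # split disconnected components (the SMILES dot is always top-level)
  comp_list <- strsplit(smiles, ".", fixed = TRUE)
  comp_all <- unique(unlist(comp_list))
  comp_all <- comp_all[!is.na(comp_all) & nzchar(comp_all)]
  if (length(comp_all) == 0) {
    reason[] <- "empty SMILES"
    return(structure(out, reason = reason))
  }
  ok <- ob_valid_smiles(comp_all)
  counts <- t(vapply(comp_all, count_atoms_smiles, numeric(2)))
  lookup <- setNames(seq_along(comp_all), comp_all)

  chosen <- rep(NA_character_, length(smiles))
  for (i in seq_along(smiles)) {
    comps <- comp_list[[i]]
    comps <- comps[!is.na(comps) & nzchar(comps)]
    if (length(comps) == 0) { reason[i] <- "empty SMILES"; next }
    j <- lookup[comps]
    if (any(!ok[j])) { reason[i] <- "unparseable SMILES"; next }
    organic <- counts[j, "n_carbon"] > 0
    if (!any(organic)) { reason[i] <- "no organic component"; next }
    chosen[i] <- comps[organic][which.max(counts[j, "n_heavy"][organic])]
  }

  todo <- which(!is.na(chosen))
  if (length(todo)) {
    canon <- ob_canonical(strip_stereo_smiles(chosen[todo]))
    out[todo] <- canon
    reason[todo][is.na(canon)] <- "canonicalization failed"
  }
  structure(out, reason = reason)
}

#' Deduplicate standardized entries, retaining the highest activity
#'
#' Entries sharing a canonical SMILES (typically stereoisomers merged by
#' standardization) are collapsed to one. When duplicate labels disagree the
#' positive label wins (a demonstrated activity outranks a negative call);
#' among records with the retained label the most potent representative
#' value (lowest concentration / highest ratio rank encoded as `potency`)
#' is kept.
#'
#' @param entries data.frame with columns `chemical_id`, `canonical_smiles`,
#'   `label` (0/1) and optionally `potency` (canonical-unit concentration;
#'   lower = more potent; NA allowed).
#' @return data.frame with one row per canonical SMILES.
#' @export
deduplicate <- function(entries) {
  stopifnot(all(c("chemical_id", "canonical_smiles", "label") %in% names(entries)))
  if (!"potency" %in% names(entries)) entries$potency <- NA_real_
  entries <- entries[!is.na(entries$canonical_smiles), , drop = FALSE]
  split_idx <- split(seq_len(nrow(entries)), entries$canonical_smiles)
  keep <- vapply(split_idx, function(ix) {
    sub <- entries[ix, , drop = FALSE]
    best_label <- max(sub$label)
    sub_ix <- ix[sub$label == best_label]
    pot <- entries$potency[sub_ix]
    pot[is.na(pot)] <- Inf
    ord <- order(pot, entries$chemical_id[sub_ix])
    sub_ix[ord[1]]
  }, integer(1))
  res <- entries[sort(unname(keep)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Construct a curated binary dataset object
#'
#' A thin data.frame subclass carrying the transporter, activity type and
#' per-source provenance counts as attributes. Entries must be unique by
#' canonical SMILES and strictly binary.
#'
#' @param entries data.frame with columns `chemical_id`, `canonical_smiles`,
#'   `label` (and optionally `potency`).
#' @param transporter one of P-gp, BCRP, MRP1, MRP2.
#' @param activity_type "substrate" or "inhibition".
#' @param provenance optional named vector of record counts per source.
#' @return object of class `transporter_dataset`.
#' @export
transporter_dataset <- function(entries, transporter, activity_type,
                                provenance = NULL) {
  transporter <- match.arg(transporter, TRANSPORTERS)
  activity_type <- match.arg(activity_type, ACTIVITY_TYPES)
  stopifnot(all(entries$label %in% c(0, 1)),
            !anyDuplicated(entries$canonical_smiles))
  structure(as.data.frame(entries),
            transporter = transporter,
            activity_type = activity_type,
            provenance = provenance,
            class = c("transporter_dataset", "data.frame"))
}

#' @export
print.transporter_dataset <- function(x, ...) {
  cat(sprintf("<transporter_dataset> %s %s: %d chemicals (%d active / %d inactive)\n",
              attr(x, "transporter"), attr(x, "activity_type"), nrow(x),
              sum(x$label == 1), sum(x$label == 0)))
  invisible(x)
}

#' Run the full curation pipeline on a raw record table
#'
#' Classifies every record, aggregates records per chemical by majority
#' vote, keeps only chemicals with a binary (0/1) final label,
#' standardizes their structures, computes a representative potency for
#' duplicate resolution, and deduplicates by canonical SMILES.
#'
#' @param records data.frame of bioactivity records.
#' @param transporter,activity_type which dataset to build; records for
#'   other transporters/activities are ignored.
#' @param thresholds,exclusions see [classify_record()].
#' @return a [transporter_dataset()].
#' @export
curate_records <- function(records, transporter, activity_type,
                           thresholds = default_thresholds(),
                           exclusions = default_exclusions()) {
  transporter <- match.arg(transporter, TRANSPORTERS)
  activity_type <- match.arg(activity_type, ACTIVITY_TYPES)
  rec <- records[records$transporter == transporter &
                 records$activity_type == activity_type, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records for ", transporter, " ", activity_type)
  rec$.label <- classify_record(rec, thresholds, exclusions)

  per_chem <- split(rec, rec$chemical_id)
  agg <- vapply(per_chem, function(d) aggregate_chemical(d$.label), numeric(1))
  binary <- !is.na(agg) & agg %in% c(0, 1)
  chems <- names(per_chem)[binary]
  if (length(chems) == 0) stop("no chemicals with binary labels after curation")

  smiles <- vapply(per_chem[chems], function(d) as.character(d$smiles[1]), character(1))
  canon <- standardize_structure(smiles)
  kept <- !is.na(canon)

  # representative potency: most potent normalized concentration among the
  # records agreeing with the final label
  tkey <- paste(thresholds$activity_type, thresholds$endpoint, sep = "|")
  potency <- vapply(seq_along(chems), function(k) {
    d <- per_chem[[chems[k]]]
    d <- d[!is.na(d$.label) & d$.label == agg[chems[k]], , drop = FALSE]
    r <- match(paste(d$activity_type, d$endpoint, sep = "|"), tkey)
    conc <- which(!is.na(r) & thresholds$unit_class[r] == "conc_uM")
    if (!length(conc)) return(NA_real_)
    v <- normalize_value(d$value[conc], d$units[conc], "conc_uM")
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  }, numeric(1))

  entries <- data.frame(chemical_id = chems[kept],
                        canonical_smiles = unname(canon[kept]),
                        label = unname(agg[chems])[kept],
                        potency = potency[kept],
                        stringsAsFactors = FALSE)
  entries <- deduplicate(entries)
  prov <- table(rec$source_id[!is.na(rec$.label)])
  transporter_dataset(entries, transporter, activity_type,
                      provenance = as.vector(prov) |> setNames(names(prov)))
}

#' Resolve chemical overlap between a training and an external set
#'
#' External-set chemicals that also occur in the training set are dropped
#' from the external set; when the two sources disagree on the label the
#' chemical is considered unreliable and dropped from both sets.
#'
#' @param train,external [transporter_dataset()] objects.
#' @return list with elements `train` and `external`.
#' @export
resolve_external_conflicts <- function(train, external) {
  m <- match(external$canonical_smiles, train$canonical_smiles)
  overlap <- !is.na(m)
  conflict <- overlap & external$label != train$label[m]
  new_train <- train[!train$canonical_smiles %in%
                       external$canonical_smiles[conflict], , drop = FALSE]
  new_external <- external[!overlap, , drop = FALSE]
  list(
    train = transporter_dataset(new_train, attr(train, "transporter"),
                                attr(train, "activity_type"),
                                attr(train, "provenance")),
    external = transporter_dataset(new_external, attr(external, "transporter"),
                                   attr(external, "activity_type"),
                                   attr(external, "provenance"))
  )
}

#' Balance a dataset by random undersampling of the majority class
#'
#' @param dataset a [transporter_dataset()].
#' @param seed integer seed; the retained subset is reproducible.
#' @return a balanced [transporter_dataset()].
#' @export
balance_undersample <- function(dataset, seed = 1) {
  n1 <- sum(dataset$label == 1); n0 <- sum(dataset$label == 0)
  if (n1 == n0) return(dataset)
  maj <- if (n1 > n0) 1 else 0
  n_keep <- min(n1, n0)
  maj_idx <- which(dataset$label == maj)
  keep <- with_seed(seed, sample(maj_idx, n_keep))
  res <- dataset[sort(c(which(dataset$label != maj), keep)), , drop = FALSE]
  rownames(res) <- NULL
  transporter_dataset(res, attr(dataset, "transporter"),
                      attr(dataset, "activity_type"),
                      attr(dataset, "provenance"))
}

#' Supplement negatives by MACCS-Tanimoto similarity to training inactives
#'
#' Candidate negatives from an external pool qualify when their MACCS-keys
#' Tanimoto similarity to at least one inactive training chemical reaches
#' the cutoff (default 0.8). Qualifying candidates are appended (random,
#' seeded selection) until the positive:negative ratio reaches
#' `target_ratio`; if too few qualify, all are appended and the shortfall is
#' reported in a warning.
#'
#' @param pool data.frame with columns `chemical_id`, `canonical_smiles`
#'   (assumed standardized, labeled inactive).
#' @param dataset a [transporter_dataset()] to supplement.
#' @param cutoff Tanimoto cutoff in \[0, 1\].
#' @param target_ratio desired positive:negative ratio after supplementation.
#' @param seed integer seed for the random selection among qualifiers.
#' @return the supplemented [transporter_dataset()].
#' @export
supplement_by_similarity <- function(pool, dataset, cutoff = 0.8,
                                     target_ratio = 1, seed = 1) {
  n1 <- sum(dataset$label == 1); n0 <- sum(dataset$label == 0)
  needed <- ceiling(n1 / target_ratio) - n0
  if (needed <= 0) return(dataset)
  pool <- pool[!pool$canonical_smiles %in% dataset$canonical_smiles, , drop = FALSE]
  negatives <- dataset$canonical_smiles[dataset$label == 0]
  if (length(negatives) == 0 || nrow(pool) == 0) {
    warning("no training negatives or empty pool; dataset unchanged")
    return(dataset)
  }
  fp_pool <- compute_fingerprint(setNames(pool$canonical_smiles, pool$chemical_id),
                                 "MACCS_166")
  fp_neg <- compute_fingerprint(negatives, "MACCS_166")
  sim <- tanimoto_matrix(fp_pool, fp_neg)
  qualifies <- apply(sim, 1, max) >= cutoff
  qual_idx <- which(qualifies)
  if (length(qual_idx) < needed) {
    warning(sprintf("only %d of %d needed similar negatives found",
                    length(qual_idx), needed))
    take <- qual_idx
  } else {
    take <- with_seed(seed, sample(qual_idx, needed))
  }
  if (length(take) == 0) return(dataset)
  add <- data.frame(chemical_id = pool$chemical_id[take],
                    canonical_smiles = pool$canonical_smiles[take],
                    label = 0,
                    potency = NA_real_,
                    stringsAsFactors = FALSE)
  base <- as.data.frame(dataset)
  if (!"potency" %in% names(base)) base$potency <- NA_real_
  transporter_dataset(rbind(base[names(add)], add),
                      attr(dataset, "transporter"),
                      attr(dataset, "activity_type"),
                      attr(dataset, "provenance"))
}
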