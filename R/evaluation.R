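# Evaluation: confusion counts, the sensitivity/specificity/CCR/PPV/AUC
# metric set, the probability-band applicability domain, external
# validation, permutation nulls, and Shapley-based substructure ranking.

#' Confusion counts at a probability threshold
#'
#' Uses the 0.5-or-higher convention: a probability at or above the
#' threshold is a positive (substrate/inhibitor) call, so a probability of
#' exactly 0.5 with a negative label counts as a false positive.
#'
#' @param labels binary labels (0/1).
#' @param probabilities predicted class-1 probabilities.
#' @param threshold positive-call threshold (default 0.5).
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(0.9, 0.4, 0.2, 0.6))  # tp=1 fp=1 tn=1 fn=1
confusion <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities),
            all(labels %in% c(0, 1)))
  pred <- as.integer(probabilities >= threshold)
  c(tp = sum(pred == 1 & labels == 1),
    fp = sum(pred == 1 & labels == 0),
    tn = sum(pred == 0 & labels == 0),
    fn = sum(pred == 0 & labels == 1))
}

# Wilcoxon rank-statistic AUC with midrank tie handling
auc_rank <- function(labels, probabilities) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probabilities)  # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Performance metrics for a set of predictions
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), CCR = their mean,
#' PPV = TP/(TP+FP), and AUC from the full probability ranking (midrank
#' statistic). Metrics with a zero denominator are reported as `NA`
#' ("undefined"), never coerced to 0, so single-class evaluations report
#' only what is measurable.
#'
#' @param labels binary labels.
#' @param probabilities predicted probabilities.
#' @param threshold positive-call threshold.
#' @return data.frame row with `sensitivity`, `specificity`, `ccr`, `ppv`,
#'   `auc`, `n` and the confusion counts.
#' @export
classification_metrics <- function(labels, probabilities, threshold = 0.5) {
  cc <- confusion(labels, probabilities, threshold)
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- frac(cc["tp"], cc["tp"] + cc["fn"])
  spec <- frac(cc["tn"], cc["tn"] + cc["fp"])
  ccr <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  data.frame(sensitivity = unname(sens), specificity = unname(spec),
             ccr = unname(ccr),
             ppv = unname(frac(cc["tp"], cc["tp"] + cc["fp"])),
             auc = auc_rank(labels, probabilities),
             n = length(labels),
             tp = unname(cc["tp"]), fp = unname(cc["fp"]),
             tn = unname(cc["tn"]), fn = unname(cc["fn"]))
}

#' Apply the probability-band applicability domain
#'
#' Predictions at or above `high` are confident positives, at or below
#' `low` confident negatives, and strictly between the bands out-of-domain
#' (excluded from in-domain performance evaluation).
#'
#' @param probabilities numeric vector in \[0, 1\].
#' @param low,high band boundaries (defaults 0.4 / 0.6).
#' @return factor with levels `in_domain_negative`, `out_of_domain`,
#'   `in_domain_positive`.
#' @export
#' @examples
#' apply_ad(c(0.6, 0.4, 0.5))
apply_ad <- function(probabilities, low = 0.4, high = 0.6) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1), low < high)
  out <- ifelse(probabilities >= high, "in_domain_positive",
         ifelse(probabilities <= low, "in_domain_negative", "out_of_domain"))
  factor(out, levels = c("in_domain_negative", "out_of_domain",
                         "in_domain_positive"))
}

#' Evaluate predictions restricted to the applicability domain
#'
#' @param labels,probabilities aligned vectors.
#' @param low,high AD band boundaries.
#' @return list with `metrics` (on in-domain chemicals), `ad` (the
#'   three-way factor), `n_excluded`.
#' @export
metrics_in_domain <- function(labels, probabilities, low = 0.4, high = 0.6) {
  ad <- apply_ad(probabilities, low, high)
  keep <- ad != "out_of_domain"
  list(metrics = classification_metrics(labels[keep], probabilities[keep]),
       ad = ad, n_excluded = sum(!keep))
}

#' Validate a model on an external dataset
#'
#' Computes the model's descriptor matrices for the external chemicals and
#' reports performance. External validation sets collected from
#' substrate/inhibitor registries are typically all-positive; in that case
#' sensitivity is the only defined metric and the others are `NA`.
#'
#' @param model an `abcqsar_model` or `abcqsar_consensus`.
#' @param external a [transporter_dataset()] (already conflict-resolved
#'   against the training set).
#' @param ad apply the 0.4/0.6 applicability domain before scoring.
#' @return data.frame of metrics (plus `n_excluded` when `ad = TRUE`).
#' @export
external_validate <- function(model, external, ad = FALSE) {
  if (nrow(external) == 0) stop("external set is empty")
  smiles <- setNames(external$canonical_smiles, external$chemical_id)
  sets <- if (inherits(model, "abcqsar_consensus")) {
    unique(vapply(model$members, `[[`, character(1), "descriptor_set"))
  } else {
    model$descriptor_set
  }
  matrices <- list()
  for (s in sets) {
    matrices[[s]] <- if (s == "PHYSCHEM") compute_physchem(smiles)
                     else compute_fingerprint(smiles, s)
  }
  p <- predict_proba(model, matrices)
  if (ad) {
    res <- metrics_in_domain(external$label, p)
    cbind(res$metrics, n_excluded = res$n_excluded)
  } else {
    classification_metrics(external$label, p)
  }
}

#' Permutation null distribution of a performance statistic
#'
#' Permutes the labels against the fixed predictions B times and recomputes
#' the statistic, giving the null distribution of prediction-label
#' association for this set of predictions.
#'
#' @param labels,probabilities aligned vectors.
#' @param statistic function(labels, probabilities) -> scalar; defaults to
#'   pooled CCR at 0.5.
#' @param B number of permutations.
#' @param seed integer seed.
#' @return numeric vector of B null statistics.
#' @export
permutation_null <- function(labels, probabilities,
                             statistic = function(l, p) ccr_at(l, p),
                             B = 1000, seed = 1) {
  with_seed(seed, {
    vapply(seq_len(B), function(b) {
      statistic(sample(labels), probabilities)
    }, numeric(1))
  })
}

# ---- Shapley attribution ---------------------------------------------------

#' Per-chemical Shapley attributions for a trained model
#'
#' For gradient-boosted trees the exact tree-path algorithm is used (via
#' the booster's contribution predictions, in log-odds space; the base
#' value plus the per-feature attributions reproduces each prediction
#' exactly). For the other algorithms a seeded Monte Carlo permutation
#' estimator is used in probability space, averaging marginal contributions
#' over `nsim` random feature orderings against a background sample.
#'
#' @param model an `abcqsar_model`.
#' @param x descriptor matrix of the chemicals to explain (model's set).
#' @param background background matrix for the sampling estimator (default:
#'   up to 100 rows sampled from `x` with the given seed).
#' @param nsim permutations for the sampling estimator.
#' @param seed integer seed.
#' @return list with `phi` (chemicals x features attribution matrix),
#'   `base` (baseline prediction), and `space` ("logit" or "probability").
#' @export
shap_values <- function(model, x, background = NULL, nsim = 30, seed = 1) {
  stopifnot(inherits(model, "abcqsar_model"))
  xt <- apply_preprocess(model$prep, x)
  if (model$algorithm == "GBT") {
    contrib <- predict(model$fit, xgboost::xgb.DMatrix(xt, nthread = 1),
                       predcontrib = TRUE)
    base_col <- ncol(contrib)
    phi <- contrib[, -base_col, drop = FALSE]
    colnames(phi) <- colnames(xt)
    return(list(phi = phi, base = contrib[1, base_col], space = "logit"))
  }
  if (is.null(background)) {
    take <- with_seed(seed, sample.int(nrow(xt), min(100, nrow(xt))))
    background <- xt[take, , drop = FALSE]
  } else {
    background <- apply_preprocess(model$prep, background)
  }
  predfun <- function(m) predict_backend(model$algorithm, model$fit, m)
  mc_shapley(predfun, xt, background, nsim = nsim, seed = seed)
}

# Monte Carlo permutation Shapley (Strumbelj-Kononenko): walk a random
# feature ordering from a background row towards the explained row,
# attributing each prediction change to the feature switched in. All
# states of one permutation are stacked into a single predict call.
mc_shapley <- function(predfun, x, background, nsim = 30, seed = 1) {
  p <- ncol(x); n <- nrow(x)
  phi <- matrix(0, n, p, dimnames = list(rownames(x), colnames(x)))
  base_acc <- 0
  with_seed(seed, {
    for (s in seq_len(nsim)) {
      perm <- sample.int(p)
      b <- background[sample.int(nrow(background), n, replace = TRUE), ,
                      drop = FALSE]
      states <- vector("list", p + 1)
      cur <- b
      states[[1]] <- cur
      for (k in seq_len(p)) {
        cur[, perm[k]] <- x[, perm[k]]
        states[[k + 1]] <- cur
      }
      preds <- predfun(do.call(rbind, states))
      preds <- matrix(preds, nrow = n)  # column k = state k-1 features switched
      for (k in seq_len(p)) {
        phi[, perm[k]] <- phi[, perm[k]] + (preds[, k + 1] - preds[, k])
      }
      base_acc <- base_acc + mean(preds[, 1])
    }
  })
  list(phi = phi / nsim, base = base_acc / nsim, space = "probability")
}

#' Rank MACCS keys by mean absolute Shapley attribution
#'
#' Substructure attribution is reported for MACCS-keys models only, where
#' each feature is an interpretable substructure; the ranking is by the
#' mean absolute attribution over the evaluation set, and the top keys are
#' annotated with their substructure definitions.
#'
#' @param model an `abcqsar_model` trained on `MACCS_166`.
#' @param x MACCS descriptor matrix of the evaluation chemicals.
#' @param top number of top-ranked keys to annotate (all keys are returned).
#' @param ... passed to [shap_values()].
#' @return data.frame with `rank`, `feature`, `key`, `mean_abs_shap`,
#'   `description` (annotated for the top keys), sorted by rank.
#' @export
shap_rank <- function(model, x, top = 20, ...) {
  if (model$descriptor_set != "MACCS_166" || ncol(x) != 166) {
    stop("substructure ranking requires a MACCS_166 model and matrix")
  }
  sv <- shap_values(model, x, ...)
  mas <- colMeans(abs(sv$phi))
  ord <- order(mas, decreasing = TRUE)
  key_num <- as.integer(sub("MACCS_", "", names(mas)[ord]))
  out <- data.frame(rank = seq_along(ord),
                    feature = names(mas)[ord],
                    key = key_num,
                    mean_abs_shap = unname(mas[ord]),
                    description = NA_character_,
                    stringsAsFactors = FALSE)
  ann <- seq_len(min(top, nrow(out)))
  out$description[ann] <- maccs_key_description(out$key[ann])
  out
}
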