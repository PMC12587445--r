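# Modeling: per-algorithm training with grid search, stratified k-fold
# cross-validation, and the consensus model (unweighted mean of member
# probabilities). Four algorithms x three descriptor sets = 12 individual
# models per dataset, plus one consensus.

#' Default hyperparameter search grids
#'
#' Deliberately small, documented grids: random forest trees in \{100, 500\};
#' SVM cost in \{0.1, 1, 10\} (radial kernel); gradient-boosted-tree learning
#' rate in \{0.05, 0.1\}; network weight decay in \{1e-3, 1e-2\}. Any grid can
#' be overridden (including to a single point, which skips the internal
#' search) through [model_config()].
#'
#' @param algorithm one of FFNN, RF, SVM, GBT.
#' @return named list of candidate value vectors.
#' @export
default_grid <- function(algorithm) {
  switch(match.arg(algorithm, ALGORITHMS),
    RF = list(ntree = c(100, 500)),
    SVM = list(cost = c(0.1, 1, 10)),
    GBT = list(eta = c(0.05, 0.1)),
    FFNN = list(decay = c(1e-3, 1e-2)))
}

#' Configuration for one individual model
#'
#' @param algorithm one of FFNN (feed-forward network), RF (random forest),
#'   SVM (radial support vector machine), GBT (gradient boosted trees).
#' @param descriptor_set one of ECFP6_1024, MACCS_166, PHYSCHEM.
#' @param grid named list of hyperparameter candidate vectors (defaults to
#'   [default_grid()]); a single-combination grid is fit directly.
#' @param seed integer seed controlling fitting and the internal search.
#' @return object of class `model_config`.
#' @export
model_config <- function(algorithm, descriptor_set, grid = NULL, seed = 1) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  descriptor_set <- match.arg(descriptor_set, DESCRIPTOR_SETS)
  structure(list(algorithm = algorithm, descriptor_set = descriptor_set,
                 grid = grid %||% default_grid(algorithm),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' The full 12-configuration suite for one dataset
#'
#' @param seed base seed; each configuration derives its own.
#' @param grids optional named list (by algorithm) of grid overrides.
#' @return list of 12 [model_config()] objects named `ALGO.DESCRIPTORS`.
#' @export
default_configs <- function(seed = 1, grids = NULL) {
  combos <- expand.grid(algorithm = ALGORITHMS, descriptor_set = DESCRIPTOR_SETS,
                        stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    model_config(combos$algorithm[i], combos$descriptor_set[i],
                 grid = grids[[combos$algorithm[i]]], seed = seed + i)
  })
  names(out) <- paste(combos$algorithm, combos$descriptor_set, sep = ".")
  out
}

# ---- preprocessing (fit inside training data only) -------------------------

# For PHYSCHEM: drop all-NA and constant columns, impute NAs with training
# medians, z-score with training statistics. Fingerprints pass through
# unchanged (binary features).
fit_preprocess <- function(x, standardize = FALSE) {
  if (!standardize) {
    return(structure(list(standardize = FALSE, cols = colnames(x)),
                     class = "abcqsar_prep"))
  }
  med <- apply(x, 2, median, na.rm = TRUE)
  keep <- !is.na(med)
  xi <- x[, keep, drop = FALSE]
  med <- med[keep]
  for (j in seq_len(ncol(xi))) xi[is.na(xi[, j]), j] <- med[j]
  sds <- apply(xi, 2, sd)
  keep2 <- sds > 0
  structure(list(standardize = TRUE,
                 cols = colnames(xi)[keep2],
                 medians = med[keep2],
                 centers = colMeans(xi[, keep2, drop = FALSE]),
                 scales = sds[keep2]),
            class = "abcqsar_prep")
}

apply_preprocess <- function(prep, x) {
  missing_cols <- setdiff(prep$cols, colnames(x))
  if (length(missing_cols)) {
    stop("descriptor matrix lacks required feature(s): ",
         paste(head(missing_cols, 5), collapse = ", "))
  }
  xt <- x[, prep$cols, drop = FALSE]
  if (!prep$standardize) return(xt)
  for (j in seq_len(ncol(xt))) xt[is.na(xt[, j]), j] <- prep$medians[j]
  scale(xt, center = prep$centers, scale = prep$scales)
}

# ---- algorithm backends ----------------------------------------------------

fit_backend <- function(algorithm, x, y, params, seed) {
  switch(algorithm,
    RF = with_seed(seed,
      randomForest::randomForest(
        x = x, y = factor(y, levels = c(0, 1)),
        ntree = params$ntree %||% 300,
        mtry = params$mtry %||% max(1, floor(sqrt(ncol(x)))))),
    SVM = with_seed(seed,
      e1071::svm(x = x, y = factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = params$cost %||% 1,
                 gamma = params$gamma %||% (1 / ncol(x)),
                 probability = TRUE, scale = FALSE)),
    GBT = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 4,
                    eta = params$eta %||% 0.1,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = params$nrounds %||% 100, verbose = 0),
    FFNN = with_seed(seed,
      nnet::nnet(x = x, y = y, size = params$size %||% 4,
                 decay = params$decay %||% 1e-3,
                 maxit = params$maxit %||% 80,
                 entropy = TRUE, trace = FALSE, MaxNWts = 200000)))
}

predict_backend <- function(algorithm, fit, x) {
  p <- switch(algorithm,
    RF = predict(fit, x, type = "prob")[, "1"],
    SVM = attr(predict(fit, x, probability = TRUE), "probabilities")[, "1"],
    GBT = predict(fit, xgboost::xgb.DMatrix(x, nthread = 1)),
    FFNN = as.numeric(predict(fit, x)))
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

# ---- training with grid search --------------------------------------------

#' Train one individual model, with grid search by internal cross-validation
#'
#' When the configuration's grid holds more than one hyperparameter
#' combination, candidates are scored by stratified internal
#' cross-validation (default 5-fold) on the training data only, using the
#' correct classification rate of pooled held-out predictions; the best
#' combination (first on ties) is then refit on the full training input.
#' `tune_folds = 0` selects flat mode: candidates are scored on the
#' training data itself. Descriptor imputation/scaling statistics are
#' computed on the training rows only and frozen into the model.
#'
#' @param x descriptor matrix (rows align with `y`).
#' @param y binary labels (0/1); both classes must be present.
#' @param config a [model_config()].
#' @param tune_folds internal folds for the grid search (0 = flat).
#' @return object of class `abcqsar_model`, which [predict_proba()] accepts.
#' @export
train_model <- function(x, y, config, tune_folds = 5) {
  stopifnot(inherits(config, "model_config"), nrow(x) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("training data contain a single class; cannot fit a classifier")
  }
  prep <- fit_preprocess(x, standardize = config$descriptor_set == "PHYSCHEM")
  xt <- apply_preprocess(prep, x)

  grid <- expand.grid(config$grid, stringsAsFactors = FALSE)
  if (nrow(grid) > 1) {
    scores <- vapply(seq_len(nrow(grid)), function(g) {
      params <- as.list(grid[g, , drop = FALSE])
      if (tune_folds > 0) {
        plan <- cv_plan(y, k = tune_folds, seed = config$seed)
        oof <- rep(NA_real_, length(y))
        for (f in seq_len(plan$k)) {
          tr <- plan$fold != f
          fit <- fit_backend(config$algorithm, xt[tr, , drop = FALSE], y[tr],
                             params, config$seed)
          oof[!tr] <- predict_backend(config$algorithm, fit, xt[!tr, , drop = FALSE])
        }
        ccr_at(y, oof)
      } else {
        fit <- fit_backend(config$algorithm, xt, y, params, config$seed)
        ccr_at(y, predict_backend(config$algorithm, fit, xt))
      }
    }, numeric(1))
    best <- which.max(scores)
  } else {
    best <- 1L
  }
  params <- as.list(grid[best, , drop = FALSE])
  fit <- fit_backend(config$algorithm, xt, y, params, config$seed)
  structure(list(config = config, algorithm = config$algorithm,
                 descriptor_set = config$descriptor_set,
                 params = params, prep = prep, fit = fit,
                 n_train = length(y),
                 training_fingerprint = dataset_hash(x, y)),
            class = "abcqsar_model")
}

# pooled CCR at the 0.5 threshold (used as the tuning criterion)
ccr_at <- function(y, p, threshold = 0.5) {
  pred <- as.integer(p >= threshold)
  sens <- mean(pred[y == 1] == 1)
  spec <- mean(pred[y == 0] == 0)
  (sens + spec) / 2
}

# cheap deterministic content hash tying a model to its training data
dataset_hash <- function(x, y) {
  v <- c(as.numeric(x[!is.na(x)]), as.numeric(y))
  sprintf("%d:%.8g:%.8g", length(v), sum(v), sum(v * seq_along(v) %% 97))
}

#' @export
print.abcqsar_model <- function(x, ...) {
  cat(sprintf("<abcqsar_model> %s on %s (n = %d)\n",
              x$algorithm, x$descriptor_set, x$n_train))
  invisible(x)
}

#' Combine individual models into a consensus model
#'
#' The consensus probability is the unweighted arithmetic mean of the member
#' probabilities and therefore always lies within the member range.
#'
#' @param members list of [train_model()] objects (typically the 12
#'   algorithm x descriptor-set combinations).
#' @return object of class `abcqsar_consensus`.
#' @export
consensus_model <- function(members) {
  stopifnot(length(members) >= 1,
            all(vapply(members, inherits, logical(1), "abcqsar_model")))
  structure(list(members = members), class = "abcqsar_consensus")
}

#' @export
print.abcqsar_consensus <- function(x, ...) {
  cat(sprintf("<abcqsar_consensus> %d member models\n", length(x$members)))
  invisible(x)
}

#' Predict class-1 probabilities
#'
#' For an individual model, `newdata` is the descriptor matrix of the
#' model's descriptor set. For a consensus model, `newdata` is a named list
#' of matrices keyed by descriptor set covering every member. Class calls
#' use the 0.5-or-higher convention (probability >= 0.5 means
#' substrate/inhibitor).
#'
#' @param model an `abcqsar_model` or `abcqsar_consensus`.
#' @param newdata matrix, or named list of matrices for a consensus model.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, newdata) UseMethod("predict_proba")

#' @export
predict_proba.abcqsar_model <- function(model, newdata) {
  if (is.list(newdata) && !is.data.frame(newdata)) {
    if (!model$descriptor_set %in% names(newdata)) {
      stop("no matrix for descriptor set ", model$descriptor_set)
    }
    newdata <- newdata[[model$descriptor_set]]
  }
  xt <- apply_preprocess(model$prep, newdata)
  predict_backend(model$algorithm, model$fit, xt)
}

#' @export
predict_proba.abcqsar_consensus <- function(model, newdata) {
  probs <- vapply(model$members, predict_proba, newdata = newdata,
                  numeric(nrow(if (is.list(newdata) && !is.data.frame(newdata))
                               newdata[[1]] else newdata)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

# ---- cross-validation ------------------------------------------------------

#' Build a stratified k-fold cross-validation plan
#'
#' Chemicals are split into k folds with the class ratio of each fold within
#' one chemical of the global ratio, so every fold contains both classes
#' even for small datasets. Every chemical is tested exactly once.
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list with `k`, `fold` (integer assignment per chemical), `seed`.
#' @export
cv_plan <- function(y, k = 5, seed = 1) {
  y <- as.integer(y)
  stopifnot(k >= 2, length(y) >= k)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  list(k = k, fold = fold, seed = seed)
}

#' Cross-validate a model suite and its consensus
#'
#' For each fold, every configuration is trained on the training folds
#' (including its internal grid search and its descriptor
#' imputation/scaling, which never see the held-out fold) and predicts the
#' held-out fold. The consensus column is the mean of the 12 member
#' probabilities per chemical. Every chemical receives exactly one
#' out-of-fold probability per model.
#'
#' @param matrices named list of descriptor matrices (by descriptor set);
#'   rows align with `y`.
#' @param y binary labels.
#' @param configs list of [model_config()]s (default: the 12-model suite).
#' @param plan a [cv_plan()]; defaults to stratified 5-fold.
#' @param tune_folds grid-search folds inside each training fold.
#' @return list with `prob` (matrix n x models+1, last column
#'   `"consensus"`), `y`, and `plan`.
#' @export
cross_validate <- function(matrices, y, configs = default_configs(),
                           plan = cv_plan(y, 5, 1), tune_folds = 5) {
  y <- as.integer(y)
  n <- length(y)
  stopifnot(all(vapply(matrices, nrow, integer(1)) == n))
  prob <- matrix(NA_real_, n, length(configs),
                 dimnames = list(NULL, names(configs) %||%
                   vapply(configs, function(cfg)
                     paste(cfg$algorithm, cfg$descriptor_set, sep = "."),
                     character(1))))
  for (f in seq_len(plan$k)) {
    tr <- plan$fold != f
    for (j in seq_along(configs)) {
      cfg <- configs[[j]]
      xm <- matrices[[cfg$descriptor_set]]
      if (is.null(xm)) stop("no matrix for descriptor set ", cfg$descriptor_set)
      fit <- train_model(xm[tr, , drop = FALSE], y[tr], cfg,
                         tune_folds = tune_folds)
      prob[!tr, j] <- predict_proba(fit, xm[!tr, , drop = FALSE])
    }
  }
  prob <- cbind(prob, consensus = rowMeans(prob))
  list(prob = prob, y = y, plan = plan)
}

#' Train the full model suite (12 individual + 1 consensus) on one dataset
#'
#' @param matrices named list of descriptor matrices.
#' @param y binary labels.
#' @param seed base seed for the configurations.
#' @param grids,tune_folds passed through to [default_configs()] /
#'   [train_model()].
#' @return named list of 12 `abcqsar_model`s plus `consensus`.
#' @export
train_model_suite <- function(matrices, y, seed = 1, grids = NULL,
                              tune_folds = 5) {
  configs <- default_configs(seed = seed, grids = grids)
  models <- lapply(configs, function(cfg) {
    train_model(matrices[[cfg$descriptor_set]], y, cfg, tune_folds = tune_folds)
  })
  models$consensus <- consensus_model(models)
  models
}
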