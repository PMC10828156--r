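#' Nested-CV prediction with concatenated features
#'
#' Runs the full pipeline for one algorithm over every outer fold of the
#' plan: scaling fitted on the training subjects, optional train-only
#' confound regression of the target, hyperparameter selection by inner
#' k-fold CV (minimizing MAE), refit on the full outer-train, evaluation
#' on the outer-test (MAE, R^2, Pearson r) together with a train-mean
#' dummy regressor evaluated identically.
#'
#' @param features a `feature_matrix` or plain subjects x features matrix
#'   (rownames = subject ids).
#' @param target numeric vector aligned with the feature rows.
#' @param config a [model_config()] for a regression algorithm.
#' @param plan a [make_cv_plan()].
#' @param deconf optional [deconfound_spec()].
#' @param extra_features optional subjects x k matrix appended to the
#'   features (standardized like brain features).
#' @param keep_weights record per-fold feature weights (|coefficients| or
#'   RF importances) for importance analyses.
#' @return object of class `fold_results`: list with `folds` (data.frame
#'   of per-fold metrics), `predictions` (per fold: ids, observed adjusted
#'   target, predicted), `weights` (folds x features matrix or NULL),
#'   `feature_names`, `algorithm`.
#' @export
fit_predict_concat <- function(features, target, config, plan,
                               deconf = NULL, extra_features = NULL,
                               keep_weights = FALSE) {
  stopifnot(inherits(config, "model_config"), inherits(plan, "cv_plan"))
  if (!config$algorithm %in% REGRESSORS)
    stop("fit_predict_concat expects a regression algorithm")
  X <- if (inherits(features, "feature_matrix")) features$values
       else as.matrix(features)
  if (!is.null(extra_features)) {
    ed <- as.matrix(extra_features)
    colnames(ed) <- colnames(ed) %||% paste0("extra", seq_len(ncol(ed)))
    X <- cbind(X, ed)
  }
  stop_if_na(X, "features")
  align_plan(plan, X, target)

  rows <- vector("list", length(plan$outer))
  preds <- vector("list", length(plan$outer))
  weights <- if (keep_weights)
    matrix(NA_real_, length(plan$outer), ncol(X)) else NULL
  for (i in seq_along(plan$outer)) {
    entry <- plan$outer[[i]]
    tr <- match(entry$train_ids, rownames(X))
    te <- match(entry$test_ids, rownames(X))
    sc <- scaler_fit(X[tr, , drop = FALSE])
    Xtr <- scaler_apply(sc, X[tr, , drop = FALSE])
    Xte <- scaler_apply(sc, X[te, , drop = FALSE])
    y <- apply_deconfound(target, deconf, tr, te)

    sd_fold <- fold_seed(plan, entry)
    tuned <- tune_inner(config$algorithm, Xtr, y$train, config$hyper_grid,
                        plan$inner_k, sd_fold, metric = "mae")
    params <- as.list(config$hyper_grid[tuned$best, , drop = FALSE])
    model <- fit_one(config$algorithm, Xtr, y$train, params, seed = sd_fold)
    pred <- predict_one(model, Xte)
    dummy <- rep(mean(y$train), length(te))

    rows[[i]] <- data.frame(
      repeat_ = entry$repeat_, fold = entry$fold, n_test = length(te),
      mae = mae_score(y$test, pred), r2 = r2_score(y$test, pred),
      pearson_r = pearson_safe(y$test, pred),
      dummy_mae = mae_score(y$test, dummy),
      dummy_r2 = r2_score(y$test, dummy),
      chosen = I(list(params)))
    preds[[i]] <- list(ids = entry$test_ids, observed = y$test,
                       predicted = pred)
    if (keep_weights) weights[i, ] <- model_weights(model)
  }
  structure(list(folds = do.call(rbind, rows), predictions = preds,
                 weights = weights, feature_names = colnames(X),
                 algorithm = config$algorithm),
            class = "fold_results")
}

#' Nested-CV prediction with fold-preserving stacking
#'
#' Two-layer stacked generalization. Layer 1: per modality, the algorithm
#' is tuned by inner k-fold CV on the outer-train subjects; out-of-fold
#' predictions over the outer-train (via the same inner splits) become the
#' layer-2 training features, and the tuned model refitted on the full
#' outer-train produces the layer-2 test features. Layer 2: a random
#' forest meta-estimator with its own grid, tuned by a fresh inner k-fold
#' on the stacked training rows. Outer train/test identities are retained
#' across layers, so layer-2 test rows are out-of-sample everywhere.
#'
#' @param modalities named list of feature matrices (one block per
#'   modality; an `extra` demographics block may be included as its own
#'   modality).
#' @inheritParams fit_predict_concat
#' @param meta_grid hyperparameter grid for the RF meta-estimator.
#' @return a `fold_results` whose `weights` are the meta-estimator's
#'   per-modality importances (folds x modalities) and whose `layer1`
#'   element records per-fold training/test ids for bookkeeping audits.
#' @export
fit_predict_stacking <- function(modalities, target, config, plan,
                                 deconf = NULL, meta_grid = build_grid("rf")) {
  stopifnot(inherits(config, "model_config"), inherits(plan, "cv_plan"))
  if (length(modalities) < 2L)
    stop("stacking needs at least 2 modalities")
  if (is.null(names(modalities)) || any(names(modalities) == ""))
    names(modalities) <- paste0("modality", seq_along(modalities))
  Xs <- lapply(modalities, function(m)
    if (inherits(m, "feature_matrix")) m$values else as.matrix(m))
  ids <- rownames(Xs[[1]])
  for (m in Xs) {
    if (!identical(rownames(m), ids))
      stop("modality subject mismatch")
    stop_if_na(m, "features")
  }
  align_plan(plan, Xs[[1]], target)
  nmod <- length(Xs)

  rows <- vector("list", length(plan$outer))
  preds <- vector("list", length(plan$outer))
  weights <- matrix(NA_real_, length(plan$outer), nmod,
                    dimnames = list(NULL, names(Xs)))
  layer1 <- vector("list", length(plan$outer))
  for (i in seq_along(plan$outer)) {
    entry <- plan$outer[[i]]
    tr <- match(entry$train_ids, ids)
    te <- match(entry$test_ids, ids)
    y <- apply_deconfound(target, deconf, tr, te)
    sd_fold <- fold_seed(plan, entry)
    inner <- make_inner_folds(length(tr), plan$inner_k, sd_fold)

    z_train <- matrix(NA_real_, length(tr), nmod,
                      dimnames = list(entry$train_ids, names(Xs)))
    z_test <- matrix(NA_real_, length(te), nmod,
                     dimnames = list(entry$test_ids, names(Xs)))
    for (m in seq_len(nmod)) {
      Xm <- Xs[[m]]
      sc <- scaler_fit(Xm[tr, , drop = FALSE])
      Xtr <- scaler_apply(sc, Xm[tr, , drop = FALSE])
      Xte <- scaler_apply(sc, Xm[te, , drop = FALSE])
      tuned <- tune_inner(config$algorithm, Xtr, y$train,
                          config$hyper_grid, plan$inner_k, sd_fold,
                          metric = "mae")
      params <- as.list(config$hyper_grid[tuned$best, , drop = FALSE])
      # out-of-fold training predictions with the tuned configuration
      for (f in seq_len(plan$inner_k)) {
        hold <- inner == f
        model_f <- fit_one(config$algorithm, Xtr[!hold, , drop = FALSE],
                           y$train[!hold], params,
                           seed = substream_seed(sd_fold, paste0("oof", f)))
        z_train[hold, m] <- predict_one(model_f, Xtr[hold, , drop = FALSE])
      }
      model <- fit_one(config$algorithm, Xtr, y$train, params,
                       seed = sd_fold)
      z_test[, m] <- predict_one(model, Xte)
    }

    # layer 2: RF meta-estimator, fresh inner split on the stacked rows
    meta_seed <- fold_seed(plan, entry, "meta")
    tuned <- tune_inner("rf", z_train, y$train, meta_grid, plan$inner_k,
                        meta_seed, metric = "mae")
    mparams <- as.list(meta_grid[tuned$best, , drop = FALSE])
    meta <- fit_one("rf", z_train, y$train, mparams, seed = meta_seed)
    pred <- predict_one(meta, z_test)
    dummy <- rep(mean(y$train), length(te))

    rows[[i]] <- data.frame(
      repeat_ = entry$repeat_, fold = entry$fold, n_test = length(te),
      mae = mae_score(y$test, pred), r2 = r2_score(y$test, pred),
      pearson_r = pearson_safe(y$test, pred),
      dummy_mae = mae_score(y$test, dummy),
      dummy_r2 = r2_score(y$test, dummy),
      chosen = I(list(mparams)))
    preds[[i]] <- list(ids = entry$test_ids, observed = y$test,
                       predicted = pred)
    weights[i, ] <- model_weights(meta)
    layer1[[i]] <- list(train_ids = entry$train_ids,
                        test_ids = entry$test_ids)
  }
  structure(list(folds = do.call(rbind, rows), predictions = preds,
                 weights = weights, feature_names = names(Xs),
                 algorithm = paste0(config$algorithm, "+rf_meta"),
                 layer1 = layer1),
            class = "fold_results")
}

#' Audit fold exclusivity of a stacking run
#'
#' Asserts that no test subject of any outer fold appears in the training
#' structure (layer 1 or layer 2 share the same outer-train ids by
#' construction) of that fold.
#'
#' @param result a `fold_results` from [fit_predict_stacking()].
#' @return `TRUE` invisibly; errors on violation.
#' @export
check_stacking_exclusivity <- function(result) {
  if (is.null(result$layer1)) stop("not a stacking result")
  for (entry in result$layer1) {
    if (length(intersect(entry$test_ids, entry$train_ids)))
      stop("fold exclusivity violated: test id found in training ids")
  }
  invisible(TRUE)
}

#' Nested-CV binary classification
#'
#' Same outer scheme as regression with accuracy as the per-fold metric
#' and a majority-class dummy; inner tuning maximizes accuracy. Outer
#' training folds containing a single class are skipped with a warning.
#'
#' @param features feature matrix (as in [fit_predict_concat()]).
#' @param labels 0/1 integer vector.
#' @param config a [model_config()] for a classifier.
#' @param plan a [make_cv_plan()].
#' @return a `fold_results` with columns `accuracy` and `dummy_accuracy`.
#' @export
fit_classify <- function(features, labels, config, plan) {
  stopifnot(inherits(config, "model_config"), inherits(plan, "cv_plan"))
  if (!config$algorithm %in% CLASSIFIERS)
    stop("fit_classify expects a classifier")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  X <- if (inherits(features, "feature_matrix")) features$values
       else as.matrix(features)
  stop_if_na(X, "features")
  align_plan(plan, X, labels)

  rows <- list()
  for (i in seq_along(plan$outer)) {
    entry <- plan$outer[[i]]
    tr <- match(entry$train_ids, rownames(X))
    te <- match(entry$test_ids, rownames(X))
    if (length(unique(labels[tr])) < 2L) {
      warning(sprintf("single-class training fold (repeat %d fold %d) skipped",
                      entry$repeat_, entry$fold))
      next
    }
    sc <- scaler_fit(X[tr, , drop = FALSE])
    Xtr <- scaler_apply(sc, X[tr, , drop = FALSE])
    Xte <- scaler_apply(sc, X[te, , drop = FALSE])
    sd_fold <- fold_seed(plan, entry)
    tuned <- tune_inner(config$algorithm, Xtr, labels[tr],
                        config$hyper_grid, plan$inner_k, sd_fold,
                        metric = "accuracy")
    params <- as.list(config$hyper_grid[tuned$best, , drop = FALSE])
    model <- fit_one(config$algorithm, Xtr, labels[tr], params,
                     seed = sd_fold)
    pred <- predict_one(model, Xte)
    maj <- as.numeric(mean(labels[tr]) >= 0.5)
    rows[[length(rows) + 1L]] <- data.frame(
      repeat_ = entry$repeat_, fold = entry$fold, n_test = length(te),
      accuracy = mean(pred == labels[te]),
      dummy_accuracy = mean(labels[te] == maj),
      chosen = I(list(params)))
  }
  structure(list(folds = do.call(rbind, rows), predictions = NULL,
                 weights = NULL, algorithm = config$algorithm),
            class = "fold_results")
}

#' Summarize fold results
#'
#' Mean and sd of MAE, R^2 and Pearson r across folds, plus the percentage
#' of folds in which the model's R^2 strictly exceeds the dummy
#' regressor's (MAE comparison reported alongside). Classification runs
#' are summarized by accuracy.
#'
#' @param result a `fold_results`.
#' @return object of class `performance_summary` (a one-row data.frame).
#' @export
summarize_performance <- function(result) {
  f <- result$folds
  if (is.null(f) || !nrow(f)) stop("no fold results to summarize")
  out <- if ("accuracy" %in% names(f)) {
    data.frame(algorithm = result$algorithm, n_folds = nrow(f),
               mean_accuracy = mean(f$accuracy),
               sd_accuracy = stats::sd(f$accuracy),
               mean_dummy_accuracy = mean(f$dummy_accuracy),
               pct_beats_dummy = 100 * mean(f$accuracy > f$dummy_accuracy))
  } else {
    data.frame(algorithm = result$algorithm, n_folds = nrow(f),
               mean_mae = mean(f$mae), sd_mae = stats::sd(f$mae),
               mean_r2 = mean(f$r2), sd_r2 = stats::sd(f$r2),
               mean_r = mean(f$pearson_r), sd_r = stats::sd(f$pearson_r),
               mean_dummy_mae = mean(f$dummy_mae),
               mean_dummy_r2 = mean(f$dummy_r2),
               pct_beats_dummy = 100 * mean(f$r2 > f$dummy_r2),
               pct_beats_dummy_mae = 100 * mean(f$mae < f$dummy_mae))
  }
  class(out) <- c("performance_summary", "data.frame")
  out
}

#' @export
print.fold_results <- function(x, ...) {
  cat(sprintf("fold results [%s]: %d folds\n", x$algorithm, nrow(x$folds)))
  print(summarize_performance(x))
  invisible(x)
}

align_plan <- function(plan, X, target) {
  if (is.null(rownames(X)))
    stop("feature matrix must carry subject ids as rownames")
  if (!setequal(plan$subject_ids, rownames(X)))
    stop("cv plan subjects do not match feature rows")
  if (length(target) != nrow(X))
    stop("target length does not match feature rows")
  invisible(TRUE)
}
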