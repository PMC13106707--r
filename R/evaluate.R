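#' Classification metrics on held-out originals
#'
#' Accuracy, macro-F1 (unweighted mean of per-class F1, empty classes
#' contributing 0), one-vs-rest macro AUC, and the confusion matrix (rows =
#' true class, columns = predicted; row sums equal the evaluation class
#' counts). Classes absent from the evaluation set are skipped in the AUC
#' average with a warning.
#'
#' @param y_true true labels.
#' @param prob row-stochastic probability matrix with one column per level
#'   of `y_true` (column order = factor levels).
#' @param levels class levels (default from `y_true`).
#' @return list with `accuracy`, `macro_f1`, `macro_auc`, `confusion`.
#' @export
classification_metrics <- function(y_true, prob, levels = NULL) {
  y_true <- as.factor(y_true)
  if (is.null(levels)) levels <- levels(y_true)
  y_true <- factor(as.character(y_true), levels = levels)
  pred <- factor(levels[max.col(prob)], levels = levels)
  confusion <- table(true = y_true, predicted = pred)
  acc <- mean(pred == y_true)
  f1 <- vapply(levels, function(cl) {
    tp <- sum(pred == cl & y_true == cl)
    fp <- sum(pred == cl & y_true != cl)
    fn <- sum(pred != cl & y_true == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  aucs <- numeric(0)
  for (k in seq_along(levels)) {
    resp <- y_true == levels[k]
    if (length(unique(resp)) < 2) {
      warning("class '", levels[k], "' absent from evaluation set; AUC skipped",
        call. = FALSE
      )
      next
    }
    aucs <- c(aucs, as.numeric(pROC::auc(
      pROC::roc(resp, prob[, k], quiet = TRUE, direction = "<")
    )))
  }
  list(
    accuracy = acc, macro_f1 = mean(f1), macro_auc = mean(aucs),
    confusion = confusion, per_class_f1 = f1
  )
}

#' Cross-validated evaluation of the extractor + boosting pipeline
#'
#' For each fold of a leakage-safe [make_folds()] plan: standardizes on the
#' fold's original training rows, augments them (SMOTE + noise), trains the
#' feature extractor and then the boosted classifier on the augmented
#' embeddings, and scores only the fold's original validation rows.
#'
#' @param cohort cohort data.frame.
#' @param folds a [make_folds()] plan over the cohort.
#' @param extractor_cfg an [extractor_config()].
#' @param gbm_cfg a [gbm_config()].
#' @param smote_k,noise_sigma augmentation parameters.
#' @param seed augmentation seed.
#' @return object of class `fitrx_metrics`: per-fold metrics plus pooled
#'   metrics over all held-out predictions.
#' @export
evaluate_cv <- function(cohort, folds = make_folds(cohort$category),
                        extractor_cfg = extractor_config(),
                        gbm_cfg = gbm_config(),
                        smote_k = 5, noise_sigma = 0.1, seed = 42) {
  x <- compact_features(cohort)
  y <- cohort$category
  lev <- levels(as.factor(y))
  pooled_prob <- matrix(NA_real_, nrow(x), length(lev))
  per_fold <- list()
  for (f in seq_len(folds$n_folds)) {
    fd <- prepare_fold(x, y, folds, f, smote_k, noise_sigma, seed)
    ext <- fit_extractor(
      tensorize(fd$x_train), fd$y_train,
      tensorize(fd$x_val), fd$y_val,
      config = extractor_cfg
    )
    z_train <- predict(ext, tensorize(fd$x_train))
    z_val <- predict(ext, tensorize(fd$x_val))
    gbm <- fit_gbm(z_train, fd$y_train, gbm_cfg)
    prob <- predict_proba(gbm, z_val)
    # align columns to the global level order
    prob_full <- matrix(0, nrow(prob), length(lev), dimnames = list(NULL, lev))
    prob_full[, colnames(prob)] <- prob
    pooled_prob[fd$val_idx, ] <- prob_full
    per_fold[[f]] <- classification_metrics(y[fd$val_idx], prob_full, lev)
  }
  pooled <- classification_metrics(y, pooled_prob, lev)
  structure(
    list(per_fold = per_fold, pooled = pooled, n_folds = folds$n_folds),
    class = "fitrx_metrics"
  )
}

#' @export
print.fitrx_metrics <- function(x, ...) {
  cat(sprintf(
    "Cross-validated metrics (%d folds, pooled over held-out originals)\n",
    x$n_folds
  ))
  cat(sprintf(
    "  accuracy %.3f | macro-F1 %.3f | macro AUC %.3f\n",
    x$pooled$accuracy, x$pooled$macro_f1, x$pooled$macro_auc
  ))
  invisible(x)
}

#' Report metrics as JSON / confusion matrix as CSV
#'
#' @param metrics a `fitrx_metrics`.
#' @param json_path,confusion_csv_path output paths (either may be `NULL`).
#' @export
write_metrics_report <- function(metrics, json_path = NULL, confusion_csv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(
      pooled = metrics$pooled[c("accuracy", "macro_f1", "macro_auc")],
      per_fold = lapply(metrics$per_fold, function(m) m[c("accuracy", "macro_f1", "macro_auc")])
    )
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(confusion_csv_path)) {
    utils::write.csv(as.data.frame.matrix(metrics$pooled$confusion), confusion_csv_path)
  }
  invisible(metrics)
}

#' Pipeline vs. multinomial-linear baseline on one held-out split
#'
#' Holds one stratified fold out, trains the augmented extractor + boosting
#' pipeline on the rest, and compares its held-out macro-F1 with a
#' multinomial logistic regression fitted on the same original
#' (unaugmented) standardized 18-column features. Used as an ordering
#' benchmark on synthetic cohorts whose class signal sits in the lap-time
#' fatigue slope.
#'
#' @param cohort cohort data.frame.
#' @param seed split/augmentation/training seed.
#' @param extractor_cfg,gbm_cfg model configurations.
#' @param n_folds stratified folds (fold 1 is held out).
#' @param smote_k,noise_sigma augmentation parameters.
#' @return list with `pipeline_f1`, `baseline_f1`, `n_val`.
#' @export
pipeline_vs_baseline <- function(cohort, seed,
                                 extractor_cfg = extractor_config(seed = seed),
                                 gbm_cfg = gbm_config(seed = seed),
                                 n_folds = 5, smote_k = 5, noise_sigma = 0.1) {
  x <- compact_features(cohort)
  y <- as.factor(cohort$category)
  folds <- make_folds(y, n_folds, seed = seed)
  fd <- prepare_fold(x, y, folds, 1, smote_k, noise_sigma, seed)
  ext <- fit_extractor(
    tensorize(fd$x_train), fd$y_train,
    tensorize(fd$x_val), fd$y_val,
    config = extractor_cfg
  )
  gbm <- fit_gbm(predict(ext, tensorize(fd$x_train)), fd$y_train, gbm_cfg)
  prob <- predict_proba(gbm, predict(ext, tensorize(fd$x_val)))
  pipe <- classification_metrics(fd$y_val, prob, levels(fd$y_val))
  # linear baseline on the original (unaugmented) standardized compact features
  train_df <- data.frame(y = droplevels(y[fd$train_idx]),
    standardize(x[fd$train_idx, ], fd$stats)$x
  )
  base_fit <- nnet::multinom(y ~ ., data = train_df, trace = FALSE, maxit = 200)
  val_df <- data.frame(standardize(x[fd$val_idx, ], fd$stats)$x)
  base_prob <- predict(base_fit, newdata = val_df, type = "probs")
  base_prob <- matrix(base_prob, nrow(val_df), nlevels(train_df$y))
  base <- classification_metrics(fd$y_val, base_prob, levels(train_df$y))
  list(
    pipeline_f1 = pipe$macro_f1, baseline_f1 = base$macro_f1,
    pipeline = pipe, baseline = base, n_val = length(fd$val_idx)
  )
}
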