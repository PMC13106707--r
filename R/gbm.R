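#' Configuration of the boosted classification stage
#'
#' Leaf-wise gradient-boosted decision trees over the pooled embeddings,
#' with the regularized logistic objective: L1 strength `lambda1 = 1.2` and
#' L2 strength `lambda2 = 0.8` on the leaf weights. Tree count, learning
#' rate and leaf limit are unconstrained by the source protocol and default
#' to 200 / 0.1 / 31.
#'
#' @param nrounds number of boosting rounds.
#' @param learning_rate shrinkage per round.
#' @param max_leaves leaf cap per tree (leaf-wise growth).
#' @param min_child_weight minimum hessian per child.
#' @param lambda1,lambda2 L1 / L2 leaf-weight regularization.
#' @param n_class number of classes.
#' @param multiclass `"softmax"` (one softmax objective over the classes,
#'   default) or `"ovr"` (one-vs-rest binary models).
#' @param seed integer seed.
#' @return object of class `gbm_config`.
#' @export
gbm_config <- function(nrounds = 200L, learning_rate = 0.1, max_leaves = 31L,
                       min_child_weight = 1, lambda1 = 1.2, lambda2 = 0.8,
                       n_class = 4L, multiclass = c("softmax", "ovr"),
                       seed = 42L) {
  multiclass <- match.arg(multiclass)
  if (lambda1 < 0 || lambda2 < 0) stop("lambda1/lambda2 must be >= 0", call. = FALSE)
  if (nrounds < 1) stop("`nrounds` must be >= 1", call. = FALSE)
  structure(
    list(
      nrounds = as.integer(nrounds), learning_rate = learning_rate,
      max_leaves = as.integer(max_leaves), min_child_weight = min_child_weight,
      lambda1 = lambda1, lambda2 = lambda2, n_class = as.integer(n_class),
      multiclass = multiclass, seed = as.integer(seed)
    ),
    class = "gbm_config"
  )
}

#' Regularized logistic loss
#'
#' Negative log-likelihood plus elastic-style penalties on the leaf weights:
#' `NLL + lambda1 * ||theta||_1 + lambda2 * ||theta||_2^2`. For two classes
#' `p` may be a probability vector of the positive class; for more classes,
#' a row-stochastic matrix whose softmax NLL restricts to the printed binary
#' form when `K = 2`. Probabilities at exactly 0 or 1 are clipped to
#' `[1e-12, 1 - 1e-12]` with a warning.
#'
#' @param p predicted probabilities (vector for binary, N x K matrix
#'   otherwise).
#' @param y labels: 0/1 for the binary form, or integer class indices /
#'   factor for the matrix form.
#' @param theta numeric vector of leaf weights.
#' @param lambda1,lambda2 penalty strengths.
#' @return scalar loss.
#' @examples
#' regularized_logistic_loss(0.5, 1, theta = 0) # log(2)
#' @export
regularized_logistic_loss <- function(p, y, theta = numeric(0),
                                      lambda1 = 1.2, lambda2 = 0.8) {
  if (any(!is.finite(theta))) stop("`theta` must be finite", call. = FALSE)
  eps <- 1e-12
  if (is.matrix(p)) {
    if (any(p <= 0 | p >= 1)) {
      warning("probabilities at 0/1 clipped to [1e-12, 1-1e-12]", call. = FALSE)
      p <- pmin(pmax(p, eps), 1 - eps)
    }
    y_int <- if (is.factor(y)) as.integer(y) else as.integer(y)
    nll <- -sum(log(p[cbind(seq_len(nrow(p)), y_int)]))
  } else {
    if (any(p <= 0 | p >= 1)) {
      warning("probabilities at 0/1 clipped to [1e-12, 1-1e-12]", call. = FALSE)
      p <- pmin(pmax(p, eps), 1 - eps)
    }
    nll <- -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  nll + lambda1 * sum(abs(theta)) + lambda2 * sum(theta^2)
}

#' Fit the boosted classifier on embeddings
#'
#' Trains a leaf-wise gradient-boosted tree ensemble minimizing the
#' regularized softmax objective (`alpha = lambda1`, `lambda = lambda2` act
#' on the leaf weights). Deterministic given the config seed and a single
#' thread.
#'
#' @param z numeric feature matrix (one embedding per row).
#' @param y class labels (factor or coercible); at least 2 classes present.
#' @param config a [gbm_config()].
#' @return object of class `fitrx_gbm` wrapping the booster(s), the class
#'   levels, feature width and config.
#' @export
fit_gbm <- function(z, y, config = gbm_config()) {
  z <- as.matrix(z)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training labels contain a single class", call. = FALSE)
  if (nrow(z) != length(y)) stop("`z` rows and `y` length differ", call. = FALSE)
  lev <- levels(y)
  common <- list(
    eta = config$learning_rate,
    max_depth = 0L, grow_policy = "lossguide",
    max_leaves = config$max_leaves,
    min_child_weight = config$min_child_weight,
    alpha = config$lambda1, lambda = config$lambda2,
    tree_method = "hist", nthread = 1L, seed = config$seed
  )
  if (config$multiclass == "softmax") {
    params <- c(common, list(
      objective = "multi:softprob", num_class = length(lev),
      eval_metric = "mlogloss"
    ))
    dtrain <- xgboost::xgb.DMatrix(z, label = as.integer(y) - 1L)
    booster <- xgboost::xgb.train(params, dtrain,
      nrounds = config$nrounds, verbose = 0,
      evals = list(train = dtrain)
    )
    boosters <- list(booster)
  } else {
    boosters <- lapply(seq_along(lev), function(k) {
      params <- c(common, list(objective = "binary:logistic", eval_metric = "logloss"))
      dtrain <- xgboost::xgb.DMatrix(z, label = as.integer(y == lev[k]))
      xgboost::xgb.train(params, dtrain, nrounds = config$nrounds, verbose = 0)
    })
  }
  structure(
    list(boosters = boosters, levels = lev, n_features = ncol(z), config = config),
    class = "fitrx_gbm"
  )
}

#' Posterior class probabilities from the boosted classifier
#'
#' @param model a `fitrx_gbm`.
#' @param z embedding matrix with the training feature width.
#' @return row-stochastic `N x K` matrix (columns named by class); an empty
#'   input yields a `0 x K` matrix.
#' @export
predict_proba <- function(model, z) {
  stopifnot(inherits(model, "fitrx_gbm"))
  z <- as.matrix(z)
  k <- length(model$levels)
  if (nrow(z) == 0) {
    return(matrix(numeric(0), 0, k, dimnames = list(NULL, model$levels)))
  }
  if (ncol(z) != model$n_features) {
    stop(
      "feature width mismatch: model expects ", model$n_features,
      " columns, got ", ncol(z),
      call. = FALSE
    )
  }
  if (model$config$multiclass == "softmax") {
    p <- predict(model$boosters[[1]], xgboost::xgb.DMatrix(z))
    p <- matrix(p, nrow(z), k)
  } else {
    p <- vapply(
      model$boosters,
      function(b) predict(b, xgboost::xgb.DMatrix(z)),
      numeric(nrow(z))
    )
    p <- matrix(p, nrow(z), k)
    p <- p / rowSums(p)
  }
  colnames(p) <- model$levels
  p
}

#' @export
predict.fitrx_gbm <- function(object, z, type = c("prob", "class", "margin"), ...) {
  type <- match.arg(type)
  if (type == "prob") {
    return(predict_proba(object, z))
  }
  if (type == "margin") {
    z <- as.matrix(z)
    k <- length(object$levels)
    if (object$config$multiclass != "softmax") {
      stop("margins are available for the softmax objective only", call. = FALSE)
    }
    m <- predict(object$boosters[[1]], xgboost::xgb.DMatrix(z), outputmargin = TRUE)
    m <- matrix(m, nrow(z), k)
    colnames(m) <- object$levels
    return(m)
  }
  p <- predict_proba(object, z)
  factor(object$levels[max.col(p)], levels = object$levels)
}

#' @export
print.fitrx_gbm <- function(x, ...) {
  cat(sprintf(
    "Boosted classifier: %d class(es), %d features, %d rounds (%s), lambda1 %.2f lambda2 %.2f\n",
    length(x$levels), x$n_features, x$config$nrounds,
    x$config$multiclass, x$config$lambda1, x$config$lambda2
  ))
  invisible(x)
}

#' Training-loss trace of a fitted softmax booster
#'
#' @param model a `fitrx_gbm` fitted with the softmax objective.
#' @return numeric vector of training multiclass log-loss per round.
#' @export
gbm_training_curve <- function(model) {
  stopifnot(inherits(model, "fitrx_gbm"), model$config$multiclass == "softmax")
  log <- attributes(model$boosters[[1]])$evaluation_log
  as.numeric(log$train_mlogloss)
}
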