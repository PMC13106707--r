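#' Standardize a compact feature matrix
#'
#' Column-wise z-scoring. When `stats` is `NULL` the centering/scaling
#' statistics are fitted from `x` (training data); when supplied they are
#' applied unchanged -- validation and test data must never refit them.
#'
#' @param x numeric matrix.
#' @param stats optional list with `center` and `scale` from a previous fit.
#' @return list with `x` (standardized matrix) and `stats`.
#' @export
standardize <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    zero <- which(scale == 0 | !is.finite(scale))
    if (length(zero)) {
      nm <- colnames(x)[zero]
      if (is.null(nm)) nm <- as.character(zero)
      stop(
        "zero-variance column(s): ", paste(nm, collapse = ", "),
        "; cannot fit standardization statistics",
        call. = FALSE
      )
    }
    stats <- list(center = center, scale = scale)
  }
  out <- sweep(sweep(x, 2, stats$center, "-"), 2, stats$scale, "/")
  list(x = out, stats = stats)
}

#' SMOTE oversampling to a uniform class histogram
#'
#' Balances every class up to the majority count by synthesizing minority
#' samples on the segment between a minority row and one of its `k` nearest
#' same-class neighbours (Euclidean distance, neighbour ties broken by lowest
#' row index): `x_new = x_i + u * (x_nb - x_i)` with `u ~ U(0, 1)`. Original
#' rows are preserved verbatim and flagged.
#'
#' @param x numeric feature matrix (one row per sample).
#' @param y class labels (factor or coercible).
#' @param k neighbour count (default 5); clipped to `class size - 1` with a
#'   warning when a class is too small.
#' @param seed integer seed.
#' @return list with `x`, `y` (originals first, then synthetics), `origin`
#'   (factor `original` / `synthetic`), and `parents` (data.frame with
#'   `parent_a`, `parent_b`, `u` per row; `NA` for originals).
#' @export
smote_oversample <- function(x, y, k = 5, seed = 42) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (nrow(x) != length(y)) stop("`x` rows and `y` length differ", call. = FALSE)
  counts <- table(y)
  counts <- counts[counts > 0]
  target <- max(counts)
  n0 <- nrow(x)
  small <- names(counts)[counts < 2 & counts < target]
  if (length(small)) {
    stop(
      "class(es) with fewer than 2 members cannot be oversampled: ",
      paste(small, collapse = ", "),
      " (lower `k` is not enough; merge or drop the class)",
      call. = FALSE
    )
  }
  syn_x <- list()
  syn_y <- list()
  syn_parents <- list()
  with_seed(seed, {
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need == 0) next
      idx <- which(y == cl)
      n_c <- length(idx)
      k_c <- k
      if (k_c > n_c - 1) {
        k_c <- n_c - 1
        warning(
          sprintf(
            "class '%s' has %d members; k clipped from %d to %d",
            cl, n_c, k, k_c
          ),
          call. = FALSE
        )
      }
      d <- as.matrix(stats::dist(x[idx, , drop = FALSE]))
      diag(d) <- Inf
      # k nearest same-class neighbours per row, ties to the lowest index
      nn <- apply(d, 1, function(r) order(r, seq_along(r))[seq_len(k_c)])
      nn <- matrix(nn, nrow = k_c)
      base_pick <- sample.int(n_c, need, replace = TRUE)
      nb_pick <- sample.int(k_c, need, replace = TRUE)
      u <- stats::runif(need)
      a <- idx[base_pick]
      b <- idx[nn[cbind(nb_pick, base_pick)]]
      new_x <- x[a, , drop = FALSE] + u * (x[b, , drop = FALSE] - x[a, , drop = FALSE])
      syn_x[[cl]] <- new_x
      syn_y[[cl]] <- rep(cl, need)
      syn_parents[[cl]] <- data.frame(parent_a = a, parent_b = b, u = u)
    }
  })
  if (length(syn_x)) {
    x_out <- rbind(x, do.call(rbind, syn_x))
    y_out <- factor(c(as.character(y), unlist(syn_y)), levels = levels(y))
    parents <- rbind(
      data.frame(parent_a = NA_integer_, parent_b = NA_integer_, u = NA_real_)[rep(1, n0), ],
      do.call(rbind, syn_parents)
    )
  } else {
    x_out <- x
    y_out <- y
    parents <- data.frame(
      parent_a = rep(NA_integer_, n0),
      parent_b = NA_integer_, u = NA_real_
    )
  }
  rownames(x_out) <- NULL
  rownames(parents) <- NULL
  origin <- factor(
    rep(c("original", "synthetic"), c(n0, nrow(x_out) - n0)),
    levels = c("original", "synthetic")
  )
  list(x = x_out, y = y_out, origin = origin, parents = parents)
}

#' Inject zero-mean Gaussian noise
#'
#' Applied on the compact (18-column) standardized representation before
#' tensorization, so the scalar-replication invariant of the sequence tensor
#' stays exact. `sigma` is in standardized units.
#'
#' @param x numeric matrix.
#' @param sigma noise SD (>= 0; default 0.1).
#' @param seed integer seed.
#' @return matrix of the same shape.
#' @export
inject_noise <- function(x, sigma = 0.1, seed = 42) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  x <- as.matrix(x)
  if (sigma == 0) {
    return(x)
  }
  with_seed(seed, x + matrix(stats::rnorm(length(x), 0, sigma), nrow(x), ncol(x)))
}

#' Build the N x 15 x 4 sequence tensor
#'
#' Channel 1 carries the 15 lap times; channels 2-4 replicate the pull-up,
#' sit-up and shuttle scalars across all 15 time steps (exactly, so every
#' constant channel is byte-identical over time).
#'
#' @param x compact matrix with 18 columns (15 laps + 3 scalars).
#' @return numeric array of dim `c(N, 15, 4)`.
#' @export
tensorize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 18L) stop("compact matrix must have 18 columns", call. = FALSE)
  n <- nrow(x)
  arr <- array(0, c(n, 15L, 4L))
  arr[, , 1] <- x[, 1:15]
  for (ch in 2:4) {
    arr[, , ch] <- matrix(x[, 14L + ch], n, 15L)
  }
  arr
}

#' @rdname tensorize
#' @param tensor array of dim `c(N, 15, 4)`.
#' @export
detensorize <- function(tensor) {
  stopifnot(length(dim(tensor)) == 3L, dim(tensor)[2] == 15L, dim(tensor)[3] == 4L)
  cbind(
    matrix(tensor[, , 1], dim(tensor)[1], 15L),
    tensor[, 1, 2], tensor[, 1, 3], tensor[, 1, 4]
  )
}

#' Stratified cross-validation fold plan
#'
#' Assigns every original subject to one of `n_folds` validation folds,
#' stratified by class so each fold's class counts are within one subject of
#' an even split. Augmentation is applied later, per fold, to training rows
#' only (see [prepare_fold()]).
#'
#' @param y class labels.
#' @param n_folds number of folds (default 5); every class must have at least
#'   `n_folds` members.
#' @param seed integer seed.
#' @return object of class `fitrx_folds`: list with `fold` (integer vector),
#'   `n_folds`, `seed`.
#' @export
make_folds <- function(y, n_folds = 5, seed = 42) {
  y <- as.factor(y)
  counts <- table(y)
  counts <- counts[counts > 0]
  if (any(counts < n_folds)) {
    stop(
      "every class needs >= n_folds members; too small: ",
      paste(names(counts)[counts < n_folds], collapse = ", "),
      call. = FALSE
    )
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  structure(list(fold = fold, n_folds = as.integer(n_folds), seed = as.integer(seed)),
    class = "fitrx_folds"
  )
}

#' Assemble one leakage-safe training/validation fold
#'
#' For validation fold `fold`: fits standardization statistics on that fold's
#' original training rows only, standardizes train and validation with them,
#' rebalances the training rows with [smote_oversample()], and injects
#' Gaussian noise into the augmented training set (originals and synthetics
#' alike). Validation rows remain original and noise-free. The manifest flags
#' every synthetic row with its interpolation parents.
#'
#' @param x compact feature matrix over all original subjects.
#' @param y class labels.
#' @param folds a [make_folds()] plan.
#' @param fold which fold to hold out for validation.
#' @param smote_k SMOTE neighbour count.
#' @param noise_sigma augmentation noise SD (standardized units).
#' @param seed integer seed for the augmentation draws.
#' @return list with `x_train`, `y_train`, `origin`, `x_val`, `y_val`,
#'   `train_idx`, `val_idx` (original-subject indices), `stats`, and
#'   `manifest` (data.frame `row_id, fold, origin, source_idx, parent_a,
#'   parent_b, u`; `source_idx` and the parents are original-subject indices,
#'   `NA` where not applicable).
#' @export
prepare_fold <- function(x, y, folds, fold, smote_k = 5, noise_sigma = 0.1,
                         seed = 42) {
  stopifnot(inherits(folds, "fitrx_folds"))
  y <- as.factor(y)
  val_idx <- which(folds$fold == fold)
  train_idx <- which(folds$fold != fold)
  if (!length(val_idx) || !length(train_idx)) stop("empty fold", call. = FALSE)
  std <- standardize(as.matrix(x)[train_idx, , drop = FALSE])
  x_val <- standardize(as.matrix(x)[val_idx, , drop = FALSE], std$stats)$x
  sm <- smote_oversample(std$x, droplevels(y[train_idx]), k = smote_k,
    seed = seed + fold
  )
  x_train <- inject_noise(sm$x, noise_sigma, seed = seed + 1000L + fold)
  parents <- sm$parents
  # map parent indices back to original-subject indices
  parents$parent_a <- train_idx[parents$parent_a]
  parents$parent_b <- train_idx[parents$parent_b]
  n_syn <- sum(sm$origin == "synthetic")
  manifest <- data.frame(
    row_id = seq_len(nrow(x_train)),       # row in the augmented training set
    fold = fold,
    origin = sm$origin,
    source_idx = c(train_idx, rep(NA_integer_, n_syn)), # original subject index
    parents
  )
  list(
    x_train = x_train, y_train = sm$y, origin = sm$origin,
    x_val = x_val, y_val = droplevels(y[val_idx]),
    train_idx = train_idx, val_idx = val_idx,
    stats = std$stats, manifest = manifest
  )
}

#' Write a per-fold augmentation manifest as CSV
#'
#' @param manifest manifest data.frame from [prepare_fold()] (or several
#'   rbind-ed together).
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
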