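#' Configuration of the sequence feature extractor
#'
#' The extractor maps an `N x 15 x 4` fitness-sequence tensor to a
#' `d`-dimensional embedding through three strided 1D convolutions
#' (filters 64/128/256, kernel 5, stride 2, ReLU; sequence length
#' 15 -> 8 -> 4 -> 2 by ceiling division), eight-head scaled dot-product
#' attention (per-head width `d/h` = 32, dropout 0.3 on the attention
#' probabilities) joined back residually with layer normalization, and
#' global average pooling over time. Training uses Adam
#' (lr 0.001, beta 0.9/0.999), an L2 penalty of 1e-4 on all trainable
#' weights, Gaussian noise (sd 0.05) on the post-attention features before
#' pooling, early stopping with patience 10, and the weighted per-metric
#' loss with an attention-entropy regularizer (lambda 0.1); see
#' [extractor_loss()].
#'
#' @param conv_filters channel depths of the three conv layers.
#' @param kernel,stride conv kernel length and stride.
#' @param heads number of attention heads; must divide the model width
#'   (the last conv depth).
#' @param attn_dropout dropout rate on attention probabilities (training only).
#' @param lambda_attn weight of the attention-entropy sparsity penalty.
#' @param metric_weights per-metric loss weights, order 3,000 m run,
#'   pull-ups, sit-ups, shuttle; must sum to 1.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param weight_decay L2 penalty coefficient on all trainable parameters.
#' @param hidden_noise SD of the Gaussian noise injected into the
#'   post-attention features before pooling during training.
#' @param patience early-stopping patience in epochs.
#' @param max_epochs training epoch cap.
#' @param batch_size minibatch size.
#' @param n_class number of output classes of the auxiliary head.
#' @param loss_mode `"per_metric"` (default): each component loss is the
#'   cross-entropy of a forward pass with all input channels except that
#'   metric's zero-masked; `"standard"`: a single unmasked cross-entropy.
#' @param seed integer seed deriving all initialization, shuffling, dropout
#'   and noise draws.
#' @return object of class `extractor_config`.
#' @export
extractor_config <- function(conv_filters = c(64L, 128L, 256L),
                             kernel = 5L, stride = 2L, heads = 8L,
                             attn_dropout = 0.3, lambda_attn = 0.1,
                             metric_weights = c(0.4, 0.2, 0.2, 0.2),
                             lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                             weight_decay = 1e-4, hidden_noise = 0.05,
                             patience = 10L, max_epochs = 100L,
                             batch_size = 64L, n_class = 4L,
                             loss_mode = c("per_metric", "standard"),
                             seed = 42L) {
  loss_mode <- match.arg(loss_mode)
  d <- conv_filters[length(conv_filters)]
  if (d %% heads != 0) stop("model width must be divisible by `heads`", call. = FALSE)
  if (abs(sum(metric_weights) - 1) > 1e-9 || length(metric_weights) != 4L) {
    stop("`metric_weights` must be 4 values summing to 1", call. = FALSE)
  }
  for (r in c(attn_dropout = attn_dropout, beta1 = beta1, beta2 = beta2)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (lambda_attn < 0 || weight_decay < 0 || hidden_noise < 0 || lr <= 0) {
    stop("lambda_attn, weight_decay, hidden_noise must be >= 0 and lr > 0", call. = FALSE)
  }
  structure(
    list(
      conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
      stride = as.integer(stride), heads = as.integer(heads),
      d = as.integer(d), head_dim = as.integer(d %/% heads),
      attn_dropout = attn_dropout, lambda_attn = lambda_attn,
      metric_weights = metric_weights, lr = lr, beta1 = beta1, beta2 = beta2,
      weight_decay = weight_decay, hidden_noise = hidden_noise,
      patience = as.integer(patience), max_epochs = as.integer(max_epochs),
      batch_size = as.integer(batch_size), n_class = as.integer(n_class),
      loss_mode = loss_mode, seed = as.integer(seed)
    ),
    class = "extractor_config"
  )
}

#' Initialize extractor parameters
#'
#' He initialization for the convolutional kernels, scaled-Gaussian for the
#' attention projections and classification head, unit gain / zero shift for
#' layer normalization. Deterministic given `seed`.
#'
#' @param config an [extractor_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param in_channels input channel count (4 fitness metrics).
#' @return flat named list of parameter matrices/vectors.
#' @export
init_extractor_params <- function(config, seed = config$seed, in_channels = 4L) {
  with_seed(seed, init_extractor_params_raw(config, in_channels))
}

# --- forward pieces -------------------------------------------------------

# strided 1D convolution with "same"-with-stride zero padding realizing
# ceil(L / stride) output positions
conv1d_layer <- function(h, w, b, kernel, stride) {
  n <- dim(h)[1]
  len <- dim(h)[2]
  cin <- dim(h)[3]
  cout <- ncol(w)
  lout <- ceiling(len / stride)
  if (lout < 1) stop("sequence collapsed to length 0", call. = FALSE)
  total_pad <- max((lout - 1) * stride + kernel - len, 0)
  pl <- total_pad %/% 2
  hp <- array(0, c(n, len + total_pad, cin))
  hp[, pl + seq_len(len), ] <- h
  z <- array(0, c(n, lout, cout))
  wins <- vector("list", lout)
  for (t in seq_len(lout)) {
    m <- matrix(hp[, (t - 1) * stride + seq_len(kernel), , drop = FALSE], n, kernel * cin)
    wins[[t]] <- m
    z[, t, ] <- m %*% w + matrix(b, n, cout, byrow = TRUE)
  }
  list(
    a = pmax(z, 0), z = z, wins = wins,
    pl = pl, len = len, lout = lout, cin = cin, cout = cout
  )
}

conv1d_backward <- function(layer, w, da, kernel, stride) {
  n <- dim(da)[1]
  dz <- da * (layer$z > 0)
  dw <- matrix(0, nrow(w), ncol(w))
  db <- numeric(ncol(w))
  lp <- layer$len + max((layer$lout - 1) * stride + kernel - layer$len, 0)
  dhp <- array(0, c(n, lp, layer$cin))
  for (t in seq_len(layer$lout)) {
    dzt <- matrix(dz[, t, ], n, layer$cout)
    dw <- dw + crossprod(layer$wins[[t]], dzt)
    db <- db + colSums(dzt)
    g <- array(dzt %*% t(w), c(n, kernel, layer$cin))
    pos <- (t - 1) * stride + seq_len(kernel)
    dhp[, pos, ] <- dhp[, pos, ] + g
  }
  dh <- dhp[, layer$pl + seq_len(layer$len), , drop = FALSE]
  list(dh = dh, dw = dw, db = db)
}

#' Run the strided convolutional block
#'
#' Applies the three ReLU conv layers to a sequence tensor, halving the time
#' axis (ceiling) at each layer.
#'
#' @param x array `N x T x F`.
#' @param params extractor parameters (see [init_extractor_params()]).
#' @param config an [extractor_config()].
#' @return list with `h` (final hidden sequence `N x T' x d`) and `lengths`
#'   (time-axis length after each layer).
#' @export
conv_block_forward <- function(x, params, config) {
  h <- x
  lengths <- integer(0)
  for (l in seq_along(config$conv_filters)) {
    layer <- conv1d_layer(
      h, params[[paste0("conv", l, "_W")]], params[[paste0("conv", l, "_b")]],
      config$kernel, config$stride
    )
    h <- layer$a
    lengths <- c(lengths, layer$lout)
  }
  list(h = h, lengths = lengths)
}

row_softmax <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

#' Multi-head self-attention with residual connection and layer norm
#'
#' Computes `LayerNorm(H + Concat(head_1..head_h) W_O)` where each head is
#' scaled dot-product attention `softmax(Q K' / sqrt(d/h)) V` over the time
#' positions. Dropout on the attention probabilities is active only when
#' `training = TRUE`; the returned attention map holds the pre-dropout,
#' row-stochastic probabilities.
#'
#' @param h hidden sequence, array `N x T' x d`.
#' @param params extractor parameters.
#' @param config an [extractor_config()].
#' @param training logical; enables attention dropout (draws from the
#'   current RNG state).
#' @param cache logical; keep intermediates for backpropagation.
#' @return list with `h_attn` (array `N x T' x d`) and `attention`
#'   (array `N x h x T' x T'`, rows over the last index sum to 1).
#' @export
attention_forward <- function(h, params, config, training = FALSE, cache = FALSE) {
  dims <- dim(h)
  n <- dims[1]
  tp <- dims[2]
  d <- dims[3]
  if (d != config$d) stop("hidden width must equal the model width d", call. = FALSE)
  nh <- config$heads
  dh <- config$head_dim
  m <- matrix(h, n * tp, d)
  q <- m %*% params$Wq
  k <- m %*% params$Wk
  v <- m %*% params$Wv
  scale <- 1 / sqrt(dh)
  attention <- array(0, c(n, nh, tp, tp))
  chead <- matrix(0, n * tp, d)
  head_cache <- if (cache) vector("list", nh) else NULL
  drop_p <- if (training) config$attn_dropout else 0
  for (hh in seq_len(nh)) {
    cols <- (hh - 1) * dh + seq_len(dh)
    qa <- array(q[, cols], c(n, tp, dh))
    ka <- array(k[, cols], c(n, tp, dh))
    va <- array(v[, cols], c(n, tp, dh))
    s <- array(0, c(n, tp, tp))
    for (i in seq_len(tp)) {
      for (j in seq_len(tp)) {
        s[, i, j] <- rowSums(matrix(qa[, i, ], n, dh) * matrix(ka[, j, ], n, dh)) * scale
      }
    }
    p <- array(0, c(n, tp, tp))
    for (i in seq_len(tp)) {
      p[, i, ] <- row_softmax(matrix(s[, i, ], n, tp))
    }
    attention[, hh, , ] <- p
    if (drop_p > 0) {
      dmask <- array(
        stats::rbinom(n * tp * tp, 1, 1 - drop_p) / (1 - drop_p),
        c(n, tp, tp)
      )
      pd <- p * dmask
    } else {
      dmask <- NULL
      pd <- p
    }
    oh <- array(0, c(n, tp, dh))
    for (i in seq_len(tp)) {
      for (j in seq_len(tp)) {
        oh[, i, ] <- matrix(oh[, i, ], n, dh) + pd[, i, j] * matrix(va[, j, ], n, dh)
      }
    }
    chead[, cols] <- matrix(oh, n * tp, dh)
    if (cache) {
      head_cache[[hh]] <- list(p = p, dmask = dmask, pd = pd, qa = qa, ka = ka, va = va)
    }
  }
  o <- chead %*% params$Wo
  r <- m + o
  mu <- rowMeans(r)
  xc <- r - mu
  va_r <- rowMeans(xc^2)
  inv <- 1 / sqrt(va_r + 1e-5)
  xhat <- xc * inv
  y <- sweep(xhat, 2, params$ln_gamma, "*")
  y <- sweep(y, 2, params$ln_beta, "+")
  out <- list(h_attn = array(y, c(n, tp, d)), attention = attention)
  if (cache) {
    out$cache <- list(
      m = m, q = q, k = k, v = v, chead = chead,
      xhat = xhat, inv = inv, heads = head_cache,
      n = n, tp = tp, d = d
    )
  }
  out
}

#' Global average pooling over the time axis
#'
#' @param h_attn array `N x T' x d`.
#' @return matrix `N x d`; column `j` is the time-mean of feature `j`.
#' @export
pool_features <- function(h_attn) {
  dims <- dim(h_attn)
  if (is.null(dims) || length(dims) != 3L || dims[2] < 1L) {
    stop("`h_attn` must be an N x T' x d array with a non-empty time axis", call. = FALSE)
  }
  n <- dims[1]
  tp <- dims[2]
  d <- dims[3]
  z <- matrix(0, n, d)
  for (t in seq_len(tp)) {
    z <- z + matrix(h_attn[, t, ], n, d)
  }
  z / tp
}

#' Mean Shannon entropy of attention rows
#'
#' The attention sparsity penalty: the entropy (nats) of every attention
#' distribution, averaged over samples, heads and query positions. Zero iff
#' every row is one-hot; `ln T'` for uniform rows.
#'
#' @param a attention array whose last dimension indexes the distribution
#'   (e.g. `N x h x T' x T'`), rows summing to 1 within 1e-4.
#' @return non-negative scalar.
#' @export
attention_entropy <- function(a) {
  dims <- dim(a)
  if (is.null(dims)) {
    a <- matrix(a, 1)
    dims <- dim(a)
  }
  tp <- dims[length(dims)]
  rows <- matrix(a, prod(dims) / tp, tp)
  if (any(rows < -1e-12)) stop("attention entries must be non-negative", call. = FALSE)
  if (any(abs(rowSums(rows) - 1) > 1e-4)) {
    stop("attention rows must sum to 1 (tolerance 1e-4)", call. = FALSE)
  }
  plogp <- ifelse(rows > 0, rows * log(rows), 0)
  mean(-rowSums(plogp))
}

#' Total extractor training loss
#'
#' Combines the four per-metric losses with the attention-entropy
#' regularizer: `0.4 L_run + 0.2 L_pull + 0.2 L_sit + 0.2 L_shuttle +
#' lambda * entropy(A)`. Each per-metric loss is the class cross-entropy of
#' a forward pass in which every input channel except that metric's is
#' zero-masked.
#'
#' @param components numeric vector of 4 finite per-metric losses.
#' @param attention attention map (see [attention_entropy()]).
#' @param config an [extractor_config()].
#' @return scalar loss.
#' @export
extractor_loss <- function(components, attention, config = extractor_config()) {
  if (length(components) != 4L || any(!is.finite(components))) {
    stop("`components` must be 4 finite losses", call. = FALSE)
  }
  sum(config$metric_weights * components) +
    config$lambda_attn * attention_entropy(attention)
}

mask_channels <- function(x, keep) {
  if (is.null(keep)) {
    return(x)
  }
  out <- array(0, dim(x))
  out[, , keep] <- x[, , keep]
  out
}

#' Full extractor forward pass
#'
#' @param params parameter list.
#' @param x sequence tensor `N x T x F` (or a compact 18-column matrix,
#'   which is [tensorize()]d first).
#' @param config an [extractor_config()].
#' @param training logical; enables attention dropout and hidden noise
#'   (both drawn from the current RNG state).
#' @param mask optional metric index 1-4; all other input channels are
#'   zeroed (used by the per-metric loss).
#' @param keep_cache keep intermediates for backpropagation.
#' @return list with `z` (N x d embedding), `logits`, `prob`, `attention`,
#'   and (optionally) `cache`.
#' @export
extractor_forward <- function(params, x, config, training = FALSE, mask = NULL,
                              keep_cache = FALSE) {
  if (is.matrix(x)) x <- tensorize(x)
  x <- mask_channels(x, mask)
  n <- dim(x)[1]
  conv <- list()
  h <- x
  for (l in seq_along(config$conv_filters)) {
    layer <- conv1d_layer(
      h, params[[paste0("conv", l, "_W")]], params[[paste0("conv", l, "_b")]],
      config$kernel, config$stride
    )
    conv[[l]] <- layer
    h <- layer$a
  }
  att <- attention_forward(h, params, config, training = training, cache = keep_cache)
  h_out <- att$h_attn
  if (training && config$hidden_noise > 0) {
    h_out <- h_out + array(
      stats::rnorm(length(h_out), 0, config$hidden_noise),
      dim(h_out)
    )
  }
  z <- pool_features(h_out)
  logits <- z %*% params$head_W + matrix(params$head_b, n, config$n_class, byrow = TRUE)
  prob <- row_softmax(logits)
  out <- list(z = z, logits = logits, prob = prob, attention = att$attention)
  if (keep_cache) {
    out$cache <- list(conv = conv, att = att$cache, z = z, tp = dim(h_out)[2], n = n)
  }
  out
}

# Backpropagate d(loss)/d(logits) (and optionally d(loss)/d(attention
# probabilities), pre-dropout) to all parameters.
extractor_backward <- function(params, fw, config, dlogits, dattn = NULL) {
  cache <- fw$cache
  n <- cache$n
  tp <- cache$tp
  d <- config$d
  nh <- config$heads
  dh <- config$head_dim
  g <- lapply(params, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p)))

  g$head_W <- crossprod(cache$z, dlogits)
  g$head_b <- colSums(dlogits)
  dz <- dlogits %*% t(params$head_W)
  # pooling: each time step receives dz / T'; hidden noise is additive
  dy <- matrix(0, n * tp, d)
  for (t in seq_len(tp)) {
    dy[(t - 1) * n + seq_len(n), ] <- dz / tp
  }
  ac <- cache$att
  # layer norm backward
  g$ln_gamma <- colSums(dy * ac$xhat)
  g$ln_beta <- colSums(dy)
  dxhat <- sweep(dy, 2, params$ln_gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * ac$xhat)
  dr <- ac$inv * (dxhat - m1 - ac$xhat * m2)
  dm <- dr
  do <- dr
  g$Wo <- crossprod(ac$chead, do)
  dchead <- do %*% t(params$Wo)
  dq <- matrix(0, n * tp, d)
  dk <- matrix(0, n * tp, d)
  dv <- matrix(0, n * tp, d)
  scale <- 1 / sqrt(dh)
  for (hh in seq_len(nh)) {
    cols <- (hh - 1) * dh + seq_len(dh)
    hc <- ac$heads[[hh]]
    doa <- array(dchead[, cols], c(n, tp, dh))
    dpd <- array(0, c(n, tp, tp))
    dva <- array(0, c(n, tp, dh))
    for (i in seq_len(tp)) {
      doi <- matrix(doa[, i, ], n, dh)
      for (j in seq_len(tp)) {
        dpd[, i, j] <- rowSums(doi * matrix(hc$va[, j, ], n, dh))
        dva[, j, ] <- matrix(dva[, j, ], n, dh) + hc$pd[, i, j] * doi
      }
    }
    dp <- if (is.null(hc$dmask)) dpd else dpd * hc$dmask
    if (!is.null(dattn)) {
      dp <- dp + array(dattn[, hh, , ], c(n, tp, tp))
    }
    ds <- array(0, c(n, tp, tp))
    for (i in seq_len(tp)) {
      pi <- matrix(hc$p[, i, ], n, tp)
      dpi <- matrix(dp[, i, ], n, tp)
      ds[, i, ] <- pi * (dpi - rowSums(dpi * pi))
    }
    dqa <- array(0, c(n, tp, dh))
    dka <- array(0, c(n, tp, dh))
    for (i in seq_len(tp)) {
      for (j in seq_len(tp)) {
        dqa[, i, ] <- matrix(dqa[, i, ], n, dh) +
          ds[, i, j] * matrix(hc$ka[, j, ], n, dh) * scale
        dka[, j, ] <- matrix(dka[, j, ], n, dh) +
          ds[, i, j] * matrix(hc$qa[, i, ], n, dh) * scale
      }
    }
    dq[, cols] <- matrix(dqa, n * tp, dh)
    dk[, cols] <- matrix(dka, n * tp, dh)
    dv[, cols] <- matrix(dva, n * tp, dh)
  }
  g$Wq <- crossprod(ac$m, dq)
  g$Wk <- crossprod(ac$m, dk)
  g$Wv <- crossprod(ac$m, dv)
  dm <- dm + dq %*% t(params$Wq) + dk %*% t(params$Wk) + dv %*% t(params$Wv)
  dh_cnn <- array(dm, c(n, tp, d))
  # conv stack backward
  da <- dh_cnn
  for (l in rev(seq_along(config$conv_filters))) {
    bk <- conv1d_backward(
      cache$conv[[l]], params[[paste0("conv", l, "_W")]], da,
      config$kernel, config$stride
    )
    g[[paste0("conv", l, "_W")]] <- bk$dw
    g[[paste0("conv", l, "_b")]] <- bk$db
    da <- bk$dh
  }
  g
}

softmax_ce <- function(logits, y_int, n_class) {
  n <- nrow(logits)
  prob <- row_softmax(logits)
  eps <- 1e-12
  loss <- -mean(log(pmax(prob[cbind(seq_len(n), y_int)], eps)))
  onehot <- matrix(0, n, n_class)
  onehot[cbind(seq_len(n), y_int)] <- 1
  list(loss = loss, dlogits = (prob - onehot) / n)
}

# early-stopping bookkeeping: improvement resets the wait counter; `stop`
# turns TRUE after `patience` consecutive non-improving epochs
early_stop_init <- function() {
  list(best = Inf, best_epoch = 0L, wait = 0L, stop = FALSE)
}

early_stop_update <- function(state, loss, epoch, patience) {
  if (loss < state$best - 1e-12) {
    state$best <- loss
    state$best_epoch <- epoch
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= patience) state$stop <- TRUE
  }
  state
}

loss_masks <- function(config) {
  if (config$loss_mode == "per_metric") {
    list(masks = as.list(1:4), weights = config$metric_weights)
  } else {
    list(masks = list(NULL), weights = 1)
  }
}

# data + entropy loss of one set of samples in evaluation mode
extractor_eval_loss <- function(params, x, y_int, config) {
  lm <- loss_masks(config)
  comp <- numeric(length(lm$masks))
  ent <- numeric(length(lm$masks))
  for (m in seq_along(lm$masks)) {
    fw <- extractor_forward(params, x, config, training = FALSE, mask = lm$masks[[m]])
    comp[m] <- softmax_ce(fw$logits, y_int, config$n_class)$loss
    ent[m] <- attention_entropy(fw$attention)
  }
  sum(lm$weights * comp) + config$lambda_attn * mean(ent)
}

#' Train the sequence feature extractor
#'
#' Minimizes the weighted per-metric cross-entropy plus the
#' attention-entropy regularizer and the L2 weight penalty with Adam, using
#' minibatches, attention dropout and hidden-feature noise during training.
#' Stops early when the validation loss (data + entropy terms, evaluation
#' mode) has not improved for `patience` consecutive epochs, and returns the
#' weights of the best validation epoch. Fully deterministic given
#' `config$seed`.
#'
#' @param x_train,y_train training tensor (`N x 15 x 4` or compact matrix)
#'   and labels.
#' @param x_val,y_val validation data, disjoint from training; used only for
#'   early stopping.
#' @param config an [extractor_config()].
#' @return object of class `fitrx_extractor` with elements `params` (best
#'   weights), `config`, `history` (per-epoch train/validation loss),
#'   `best_epoch`, `stopped_epoch`, `levels` (class labels).
#' @export
fit_extractor <- function(x_train, y_train, x_val = NULL, y_val = NULL,
                          config = extractor_config()) {
  if (is.matrix(x_train)) x_train <- tensorize(x_train)
  if (!is.null(x_val) && is.matrix(x_val)) x_val <- tensorize(x_val)
  y_train <- as.factor(y_train)
  lev <- levels(y_train)
  if (length(lev) > config$n_class) {
    stop("more classes than the configured head width", call. = FALSE)
  }
  y_int <- as.integer(y_train)
  n <- dim(x_train)[1]
  if (n < 1) stop("empty training set", call. = FALSE)
  has_val <- !is.null(x_val)
  yv_int <- if (has_val) as.integer(factor(as.character(y_val), levels = lev))
  lm <- loss_masks(config)
  history <- data.frame(epoch = integer(), train_loss = numeric(), val_loss = numeric())
  res <- with_seed(config$seed, {
    params <- init_extractor_params_raw(config)
    adam_m <- lapply(params, function(p) p * 0)
    adam_v <- lapply(params, function(p) p * 0)
    adam_t <- 0
    es <- early_stop_init()
    best_params <- params
    stopped <- config$max_epochs
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batch_losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        bidx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- x_train[bidx, , , drop = FALSE]
        yb <- y_int[bidx]
        grads <- NULL
        comp <- numeric(length(lm$masks))
        ent <- numeric(length(lm$masks))
        for (m in seq_along(lm$masks)) {
          fw <- extractor_forward(params, xb, config,
            training = TRUE,
            mask = lm$masks[[m]], keep_cache = TRUE
          )
          ce <- softmax_ce(fw$logits, yb, config$n_class)
          comp[m] <- ce$loss
          ent[m] <- attention_entropy(fw$attention)
          dattn <- NULL
          if (config$lambda_attn > 0) {
            a <- fw$attention
            n_rows <- length(a) / dim(a)[4]
            coef <- config$lambda_attn / (length(lm$masks) * n_rows)
            dattn <- -coef * (log(pmax(a, 1e-12)) + 1)
          }
          gb <- extractor_backward(params, fw, config,
            dlogits = lm$weights[m] * ce$dlogits, dattn = dattn
          )
          grads <- if (is.null(grads)) gb else mapply(`+`, grads, gb, SIMPLIFY = FALSE)
        }
        data_loss <- sum(lm$weights * comp) + config$lambda_attn * mean(ent)
        if (!is.finite(data_loss)) stop("non-finite training loss", call. = FALSE)
        l2 <- 0
        if (config$weight_decay > 0) {
          for (nm in names(params)) {
            grads[[nm]] <- grads[[nm]] + 2 * config$weight_decay * params[[nm]]
            l2 <- l2 + sum(params[[nm]]^2)
          }
        }
        batch_losses <- c(batch_losses, data_loss + config$weight_decay * l2)
        adam_t <- adam_t + 1
        for (nm in names(params)) {
          adam_m[[nm]] <- config$beta1 * adam_m[[nm]] + (1 - config$beta1) * grads[[nm]]
          adam_v[[nm]] <- config$beta2 * adam_v[[nm]] + (1 - config$beta2) * grads[[nm]]^2
          mhat <- adam_m[[nm]] / (1 - config$beta1^adam_t)
          vhat <- adam_v[[nm]] / (1 - config$beta2^adam_t)
          params[[nm]] <- params[[nm]] - config$lr * mhat / (sqrt(vhat) + 1e-8)
        }
      }
      monitored <- if (has_val) {
        extractor_eval_loss(params, x_val, yv_int, config)
      } else {
        extractor_eval_loss(params, x_train, y_int, config)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(batch_losses), val_loss = monitored
      ))
      improved <- monitored < es$best - 1e-12
      es <- early_stop_update(es, monitored, epoch, config$patience)
      if (improved) best_params <- params
      stopped <- epoch
      if (es$stop) break
    }
    list(best_params = best_params, best_epoch = es$best_epoch, stopped = stopped)
  })
  structure(
    list(
      params = res$best_params, config = config, history = history,
      best_epoch = res$best_epoch, stopped_epoch = res$stopped, levels = lev
    ),
    class = "fitrx_extractor"
  )
}

# init inside an already-seeded context (fit_extractor manages the seed)
init_extractor_params_raw <- function(config, in_channels = 4L) {
  p <- list()
  cin <- in_channels
  for (l in seq_along(config$conv_filters)) {
    cout <- config$conv_filters[l]
    fan_in <- config$kernel * cin
    p[[paste0("conv", l, "_W")]] <-
      matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
    p[[paste0("conv", l, "_b")]] <- numeric(cout)
    cin <- cout
  }
  d <- config$d
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    p[[nm]] <- matrix(stats::rnorm(d * d, 0, sqrt(1 / d)), d, d)
  }
  p$ln_gamma <- rep(1, d)
  p$ln_beta <- rep(0, d)
  p$head_W <- matrix(stats::rnorm(d * config$n_class, 0, sqrt(1 / d)), d, config$n_class)
  p$head_b <- numeric(config$n_class)
  p
}

#' @export
print.fitrx_extractor <- function(x, ...) {
  cat("Sequence feature extractor (1D conv + multi-head attention)\n")
  cat(sprintf(
    "  conv filters: %s | kernel %d stride %d | heads %d (dim %d) | d = %d\n",
    paste(x$config$conv_filters, collapse = "/"), x$config$kernel,
    x$config$stride, x$config$heads, x$config$head_dim, x$config$d
  ))
  cat(sprintf(
    "  trained %d epoch(s), best validation loss %.4f at epoch %d\n",
    x$stopped_epoch, min(x$history$val_loss), x$best_epoch
  ))
  invisible(x)
}

#' Embed or classify with a trained extractor
#'
#' Evaluation-mode forward pass (no dropout, no noise): two calls on the
#' same input agree bitwise.
#'
#' @param object a `fitrx_extractor`.
#' @param x sequence tensor or compact matrix.
#' @param type `"embedding"` (the pooled d-dimensional feature vector),
#'   `"prob"` (auxiliary-head class probabilities) or `"class"`.
#' @param ... unused.
#' @export
predict.fitrx_extractor <- function(object, x,
                                    type = c("embedding", "prob", "class"), ...) {
  type <- match.arg(type)
  fw <- extractor_forward(object$params, x, object$config, training = FALSE)
  switch(type,
    embedding = fw$z,
    prob = {
      colnames(fw$prob) <- c(object$levels, rep(NA, object$config$n_class - length(object$levels)))[seq_len(ncol(fw$prob))]
      fw$prob
    },
    class = factor(object$levels[max.col(fw$prob[, seq_along(object$levels), drop = FALSE])],
      levels = object$levels
    )
  )
}
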