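# Small, fast fixtures shared across tests; everything is generated in code.

# a compact cohort for pipeline-level tests
small_cohort <- function(n = 240, seed = 11) {
  generate_cohort(cohort_spec(n, seed = seed))
}

# a narrow extractor configuration that keeps training tests fast while
# exercising every architectural component (conv stack, multi-head
# attention, pooling, auxiliary head)
tiny_extractor_config <- function(...) {
  args <- utils::modifyList(
    list(
      conv_filters = c(8L, 12L, 16L), heads = 4L,
      batch_size = 32L, max_epochs = 5L
    ),
    list(...)
  )
  do.call(extractor_config, args)
}

# brute-force direct strided cross-correlation with explicit zero padding;
# the independent oracle for the vectorized conv layer
direct_conv1d <- function(x, w_arr, b, stride) {
  # x: L x Cin; w_arr: k x Cin x Cout
  k <- dim(w_arr)[1]
  cin <- dim(w_arr)[2]
  cout <- dim(w_arr)[3]
  len <- nrow(x)
  lout <- ceiling(len / stride)
  total_pad <- max((lout - 1) * stride + k - len, 0)
  pl <- total_pad %/% 2
  xp <- rbind(
    matrix(0, pl, cin), x,
    matrix(0, total_pad - pl, cin)
  )
  out <- matrix(0, lout, cout)
  for (t in seq_len(lout)) {
    for (co in seq_len(cout)) {
      acc <- b[co]
      for (dt in seq_len(k)) {
        for (ci in seq_len(cin)) {
          acc <- acc + xp[(t - 1) * stride + dt, ci] * w_arr[dt, ci, co]
        }
      }
      out[t, co] <- acc
    }
  }
  pmax(out, 0)
}

# reshape a flat (k*Cin) x Cout kernel matrix into the k x Cin x Cout array
# layout used by direct_conv1d (time index fastest, matching the package's
# window flattening)
kernel_as_array <- function(w, k, cin) {
  array(w, c(k, cin, ncol(w)))
}

# one conv layer through the package's internal kernel (post-ReLU activations)
conv1d_layer_for_test <- function(x, w, b, cfg) {
  fitrx:::conv1d_layer(x, w, b, cfg$kernel, cfg$stride)$a
}

# accumulate the analytic training gradients exactly as fit_extractor does
# (per-metric masked passes + entropy penalty), in evaluation mode
extractor_loss_gradients_for_test <- function(params, x, y, cfg) {
  grads <- NULL
  n <- dim(x)[1]
  for (m in 1:4) {
    fw <- extractor_forward(params, x, cfg, mask = m, keep_cache = TRUE)
    ce <- fitrx:::softmax_ce(fw$logits, y, cfg$n_class)
    a <- fw$attention
    n_rows <- length(a) / dim(a)[4]
    coef <- cfg$lambda_attn / (4 * n_rows)
    dattn <- -coef * (log(pmax(a, 1e-12)) + 1)
    gb <- fitrx:::extractor_backward(params, fw, cfg,
      dlogits = cfg$metric_weights[m] * ce$dlogits, dattn = dattn
    )
    grads <- if (is.null(grads)) gb else mapply(`+`, grads, gb, SIMPLIFY = FALSE)
  }
  grads
}

# drive the package's early-stopping state machine with a fixed loss sequence
simulate_early_stop <- function(val_losses, patience) {
  es <- fitrx:::early_stop_init()
  stopped <- length(val_losses)
  for (epoch in seq_along(val_losses)) {
    es <- fitrx:::early_stop_update(es, val_losses[epoch], epoch, patience)
    stopped <- epoch
    if (es$stop) break
  }
  list(stopped = stopped, best = es$best_epoch)
}
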