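test_that("conv stack follows the ceil length chain with the stated depths", {
  cfg <- extractor_config()
  params <- init_extractor_params(cfg, seed = 1)
  x <- array(rnorm(3 * 15 * 4), c(3, 15, 4))
  cb <- conv_block_forward(x, params, cfg)
  expect_equal(cb$lengths, c(8L, 4L, 2L))
  expect_equal(dim(cb$h), c(3, 2, 256))
  expect_true(all(cb$h >= 0)) # ReLU output
  # all-zero input with zero bias stays zero through the linear + ReLU stack
  p0 <- params
  for (l in 1:3) p0[[paste0("conv", l, "_b")]][] <- 0
  cb0 <- conv_block_forward(array(0, c(2, 15, 4)), p0, cfg)
  expect_true(all(cb0$h == 0))
})

test_that("conv layer matches a brute-force direct convolution oracle", {
  cfg <- extractor_config(conv_filters = c(3L, 4L, 6L), heads = 2L)
  params <- init_extractor_params(cfg, seed = 2)
  set.seed(5)
  x <- array(rnorm(15 * 4), c(1, 15, 4))
  cb <- conv_block_forward(x, params, cfg)
  # replicate layer 1 by hand
  oracle <- direct_conv1d(
    matrix(x[1, , ], 15, 4),
    kernel_as_array(params$conv1_W, cfg$kernel, 4L),
    params$conv1_b, cfg$stride
  )
  layer1 <- conv1d_layer_for_test(x, params$conv1_W, params$conv1_b, cfg)
  expect_equal(matrix(layer1[1, , ], dim(layer1)[2], dim(layer1)[3]), oracle,
    tolerance = 1e-12
  )
  # single-channel impulse against the hand-computed strided correlation
  xi <- array(0, c(1, 15, 4))
  xi[1, 7, 1] <- 1
  oracle_i <- direct_conv1d(
    matrix(xi[1, , ], 15, 4),
    kernel_as_array(params$conv1_W, cfg$kernel, 4L),
    params$conv1_b, cfg$stride
  )
  layer1_i <- conv1d_layer_for_test(xi, params$conv1_W, params$conv1_b, cfg)
  expect_equal(matrix(layer1_i[1, , ], 8, 3), oracle_i, tolerance = 1e-12)
})

test_that("attention is row-stochastic, residual-normalized, and degenerates correctly", {
  cfg <- extractor_config(conv_filters = c(4L, 6L, 8L), heads = 2L)
  params <- init_extractor_params(cfg, seed = 3)
  set.seed(6)
  h <- array(rnorm(5 * 3 * 8), c(5, 3, 8))
  att <- attention_forward(h, params, cfg)
  rows <- matrix(att$attention, ncol = 3)
  expect_true(all(abs(rowSums(matrix(aperm(att$attention, c(1, 2, 3, 4)),
    ncol = dim(att$attention)[4]
  )) - 1) < 1e-6))
  expect_true(all(att$attention >= 0))
  expect_equal(dim(att$h_attn), dim(h))

  # zero query/key projections -> uniform attention; each head output is the
  # time-mean of its values
  p0 <- params
  p0$Wq[] <- 0
  p0$Wk[] <- 0
  att0 <- attention_forward(h, p0, cfg)
  expect_true(all(abs(att0$attention - 1 / 3) < 1e-12))

  # single time position: attention weight is exactly 1
  h1 <- array(rnorm(4 * 1 * 8), c(4, 1, 8))
  att1 <- attention_forward(h1, params, cfg)
  expect_true(all(att1$attention == 1))
  expect_error(
    attention_forward(array(0, c(2, 3, 6)), params, cfg),
    "width"
  )
})

test_that("global average pooling is the exact time-mean", {
  set.seed(7)
  h <- array(rnorm(6 * 4 * 10), c(6, 4, 10))
  z <- pool_features(h)
  expect_equal(dim(z), c(6, 10))
  oracle <- apply(h, c(1, 3), mean)
  expect_equal(z, oracle, tolerance = 1e-12)
  # constant-in-time input passes through; two steps average exactly
  hc <- array(rep(matrix(1:60, 6, 10), times = 4), c(6, 10, 4))
  hc <- aperm(hc, c(1, 3, 2))
  expect_equal(pool_features(hc), matrix(1:60, 6, 10))
  h2 <- array(c(rep(1, 12), rep(3, 12)), c(12, 2, 1))
  expect_true(all(pool_features(h2) == 2))
  expect_error(pool_features(matrix(1, 2, 2)), "array")
})

test_that("the full forward pass yields a 256-dim embedding with head dim 32", {
  cfg <- extractor_config()
  expect_equal(cfg$d, 256L)
  expect_equal(cfg$head_dim, 32L)
  params <- init_extractor_params(cfg, seed = 4)
  x <- array(rnorm(2 * 15 * 4), c(2, 15, 4))
  fw <- extractor_forward(params, x, cfg)
  expect_equal(ncol(fw$z), 256)
  expect_equal(dim(fw$attention), c(2, 8, 2, 2))
  expect_equal(rowSums(fw$prob), c(1, 1), tolerance = 1e-9)
  # shape contract for N = 1
  fw1 <- extractor_forward(params, array(rnorm(15 * 4), c(1, 15, 4)), cfg)
  expect_equal(dim(fw1$z), c(1, 256))
  # eval-mode determinism: bitwise-equal repeat passes
  fw2 <- extractor_forward(params, x, cfg)
  expect_identical(fw$z, fw2$z)
  # embedding equals the time-mean of the post-attention features
  cb <- conv_block_forward(x, params, cfg)
  att <- attention_forward(cb$h, params, cfg)
  expect_equal(fw$z, pool_features(att$h_attn), tolerance = 1e-6)
})

test_that("attention entropy penalty matches closed forms", {
  # one-hot rows have zero entropy
  a <- array(0, c(1, 1, 2, 2))
  a[1, 1, 1, 1] <- 1
  a[1, 1, 2, 2] <- 1
  expect_equal(attention_entropy(a), 0)
  # uniform rows over two positions: ln 2
  u <- array(0.5, c(3, 2, 2, 2))
  expect_equal(attention_entropy(u), log(2), tolerance = 1e-12)
  # mixed map equals the hand-summed mean of per-row entropies
  p1 <- c(0.9, 0.1)
  p2 <- c(0.3, 0.7)
  m <- array(0, c(1, 1, 2, 2))
  m[1, 1, 1, ] <- p1
  m[1, 1, 2, ] <- p2
  by_hand <- mean(c(-sum(p1 * log(p1)), -sum(p2 * log(p2))))
  expect_equal(attention_entropy(m), by_hand, tolerance = 1e-12)
  bad <- array(0.4, c(1, 1, 2, 2))
  expect_error(attention_entropy(bad), "sum to 1")
})

test_that("the weighted loss combiner follows its identities", {
  cfg <- extractor_config()
  onehot <- array(0, c(2, 8, 2, 2))
  onehot[, , 1, 1] <- 1
  onehot[, , 2, 2] <- 1
  # equal components with one-hot attention collapse to the common value
  expect_equal(extractor_loss(rep(1.7, 4), onehot, cfg), 1.7, tolerance = 1e-12)
  # components (1,0,0,0) weight out to 0.4
  expect_equal(extractor_loss(c(1, 0, 0, 0), onehot, cfg), 0.4, tolerance = 1e-12)
  # uniform attention over two positions adds exactly 0.1 * ln 2
  u <- array(0.5, c(2, 8, 2, 2))
  expect_equal(extractor_loss(rep(0, 4), u, cfg), 0.1 * log(2), tolerance = 1e-12)
  expect_error(extractor_loss(c(1, NaN, 0, 0), onehot, cfg), "finite")
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- extractor_config(
    conv_filters = c(4L, 6L, 8L), heads = 2L,
    attn_dropout = 0, hidden_noise = 0, weight_decay = 0, seed = 7
  )
  set.seed(1)
  n <- 3
  x <- array(rnorm(n * 15 * 4), c(n, 15, 4))
  y <- sample(1:4, n, replace = TRUE)
  params <- init_extractor_params(cfg, seed = 7)
  loss_fn <- function(p) {
    comp <- numeric(4)
    ent <- numeric(4)
    for (m in 1:4) {
      fw <- extractor_forward(p, x, cfg, mask = m)
      comp[m] <- -mean(log(fw$prob[cbind(seq_len(n), y)]))
      ent[m] <- attention_entropy(fw$attention)
    }
    sum(cfg$metric_weights * comp) + cfg$lambda_attn * mean(ent)
  }
  grads <- extractor_loss_gradients_for_test(params, x, y, cfg)
  set.seed(42)
  for (nm in c("conv1_W", "conv3_b", "Wq", "Wo", "ln_gamma", "head_W")) {
    for (i in sample(length(params[[nm]]), 3)) {
      h <- 1e-5
      p1 <- params
      p1[[nm]][i] <- p1[[nm]][i] + h
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] - h
      num <- (loss_fn(p1) - loss_fn(p2)) / (2 * h)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training stops per patience semantics and is seed-deterministic", {
  set.seed(30)
  co <- small_cohort(200, seed = 30)
  x <- standardize(compact_features(co))$x
  y <- co$category
  # deterministic repeat runs with dropout and noise disabled
  cfg <- tiny_extractor_config(
    attn_dropout = 0, hidden_noise = 0, max_epochs = 3L, seed = 13
  )
  e1 <- fit_extractor(tensorize(x), y, config = cfg)
  e2 <- fit_extractor(tensorize(x), y, config = cfg)
  expect_identical(e1$params, e2$params)
  expect_identical(e1$history, e2$history)
  expect_error(
    fit_extractor(array(0, c(0, 15, 4)), factor(character(), levels = "a")),
    "empty"
  )
})

test_that("patience counter stops after the stated number of non-improving epochs", {
  # strictly worsening validation loss from epoch 1 stops at epoch 1 + patience
  history <- simulate_early_stop(
    val_losses = seq(1, 3, length.out = 50), patience = 10
  )
  expect_equal(history$stopped, 11)
  expect_equal(history$best, 1)
  # improvement resets the counter
  history <- simulate_early_stop(c(3, 2.5, 2.6, 2.7, 2.4, 2.9, 3, 3.1), patience = 3)
  expect_equal(history$stopped, 8)
  expect_equal(history$best, 5)
})

test_that("training loss falls substantially on a separable synthetic cohort", {
  spec <- cohort_spec(
    200,
    class_proportions = c(0, 0.5, 0.5, 0),
    fatigue_slope = c(0, 0, 1.4, 0),
    seed = 17
  )
  co <- generate_cohort(spec)
  x <- standardize(compact_features(co))$x
  cfg <- tiny_extractor_config(max_epochs = 25L, patience = 25L, seed = 3)
  ext <- fit_extractor(tensorize(x), droplevels(co$category), config = cfg)
  tl <- ext$history$train_loss
  expect_lt(min(tl) / tl[1], 0.5)
  # dropping the attention penalty never increases the epoch-1 loss
  cfg0 <- tiny_extractor_config(max_epochs = 1L, lambda_attn = 0, seed = 3)
  cfg1 <- tiny_extractor_config(max_epochs = 1L, lambda_attn = 0.1, seed = 3)
  e0 <- fit_extractor(tensorize(x), droplevels(co$category), config = cfg0)
  e1 <- fit_extractor(tensorize(x), droplevels(co$category), config = cfg1)
  expect_lte(e0$history$train_loss[1], e1$history$train_loss[1])
})
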