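test_that("within-group change reproduces the printed table arithmetic", {
  # constructed samples with the printed means: 10.2 -> 14.7 gives +4.5
  n <- 100
  set.seed(16)
  base <- rnorm(n, 0, 3.1)
  base <- base - mean(base) + 10.2
  post <- base + 4.5
  wg <- within_group_change(base, post)
  expect_equal(wg$delta, 4.5, tolerance = 1e-9)
  expect_equal(wg$ci, c(4.5, 4.5)) # zero-variance differences degenerate
  # with change noise the CI brackets the mean change
  post2 <- post + rnorm(n, 0, 2)
  wg2 <- within_group_change(base, post2)
  expect_true(wg2$ci[1] < wg2$delta && wg2$delta < wg2$ci[2])
  # identical samples: zero change, CI contains 0
  wg3 <- within_group_change(base, base)
  expect_equal(wg3$delta, 0)
  expect_true(wg3$ci[1] <= 0 && wg3$ci[2] >= 0)
  expect_error(within_group_change(1:3, 1:4), "mismatch")
})

test_that("ANCOVA recovers injected effects and reduces to change scores under balance", {
  set.seed(17)
  n <- 300
  base <- rnorm(2 * n, 30, 3)
  arm <- factor(rep(c("control", "intervention"), each = n))
  post <- 5 + 0.8 * base + ifelse(arm == "intervention", -2, 0) + rnorm(2 * n, 0, 1)
  res <- ancova_group_effect(base, post, arm)
  expect_true(res$ci[1] < -2 && -2 < res$ci[2])
  expect_lt(res$p_value, 1e-10)
  # identical arms: near-zero estimate, non-significant
  post0 <- 5 + 0.8 * base + rnorm(2 * n, 0, 1)
  res0 <- ancova_group_effect(base, post0, arm)
  expect_lt(abs(res0$estimate), 0.5)
  # balanced baselines: estimate ~ difference in raw change means
  raw_diff <- mean((post - base)[arm == "intervention"]) -
    mean((post - base)[arm == "control"])
  expect_equal(res$estimate, raw_diff, tolerance = 0.25)
  # affine rescaling of the covariate leaves the effect unchanged
  res_resc <- ancova_group_effect(10 * base - 7, post, arm)
  expect_equal(res_resc$estimate, res$estimate, tolerance = 1e-9)
  expect_error(ancova_group_effect(base, post, factor(rep("a", 2 * n))), "both arms")
})

test_that("Cohen's d on change scores matches the hand formula", {
  expect_equal(cohens_d_change(c(1, 2, 3), c(1, 2, 3)), 0)
  # means 1 apart with pooled SD ~1
  set.seed(18)
  a <- rnorm(5000, 1, 1)
  b <- rnorm(5000, 0, 1)
  expect_equal(cohens_d_change(a, b), 1, tolerance = 0.06)
  # exact agreement with the direct formula on arbitrary samples
  x <- rnorm(37, 2, 3)
  y <- rnorm(53, 1, 2)
  sp <- sqrt(((36) * var(x) + (52) * var(y)) / (37 + 53 - 2))
  expect_equal(cohens_d_change(x, y), (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  expect_error(cohens_d_change(c(1, 1), c(1, 1)), "zero")
})

test_that("McNemar on unhealthy-weight status uses exact and chi-squared forms", {
  lv <- bmi_levels()
  # b = c: statistic 0, p = 1 under either form
  pre <- c(rep("overweight", 10), rep("normal", 10))
  post <- c(rep("normal", 5), rep("overweight", 5), rep("overweight", 5), rep("normal", 5))
  r <- mcnemar_shift(pre, post)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # b = 10, c = 0: exact two-sided binomial p = 2 * 0.5^10
  pre2 <- rep("overweight", 10)
  post2 <- rep("normal", 10)
  r2 <- mcnemar_shift(pre2, post2)
  expect_equal(r2$method, "exact binomial")
  expect_equal(r2$p_value, 2 * 0.5^10, tolerance = 1e-12)
  # no change at all: p = 1 by convention
  r3 <- mcnemar_shift(pre, pre)
  expect_equal(r3$p_value, 1)
  # large discordant counts use the chi-squared form, close to the exact p
  make_pair <- function(b, cc) {
    pre <- c(rep("overweight", b), rep("normal", cc))
    post <- c(rep("normal", b), rep("overweight", cc))
    mcnemar_shift(pre, post)
  }
  for (b in c(35, 40, 30)) {
    cc <- 60 - b
    r4 <- make_pair(b, cc)
    expect_equal(r4$method, "chi-squared")
    p_exact <- min(1, 2 * pbinom(min(b, cc), 60, 0.5))
    expect_lt(abs(r4$p_value - p_exact) / p_exact, 0.35)
  }
})

test_that("transition rates are row-normalized with the constructed 68.3% case", {
  lv <- bmi_levels()
  pre <- rep("overweight", 1000)
  post <- c(rep("normal", 683), rep("overweight", 317))
  tr <- transition_rates(pre, post)
  expect_equal(tr["overweight", "normal"], 0.683)
  expect_equal(sum(tr["overweight", ]), 1)
  expect_true(all(is.nan(tr["obese", ]))) # empty origin rows
  # identity when nothing changes
  pre2 <- sample(lv, 50, TRUE)
  tr2 <- transition_rates(pre2, pre2)
  present <- lv %in% pre2
  expect_equal(diag(tr2)[present], rep(1, sum(present)), ignore_attr = TRUE)
})

test_that("percent change follows the table conventions", {
  expect_equal(percent_change(32.4, 29.1, "time"), 10.2)
  expect_equal(percent_change(5, 5, "time"), 0)
  # 14.2 -> 12.8 min computes 9.9% at one decimal
  expect_equal(percent_change(14.2, 12.8, "time"), 9.9)
  expect_equal(percent_change(10.2, 14.7, "count"), 44.1)
  expect_equal(percent_change(14.2, 12.8, "time", digits = NULL),
    100 * 1.4 / 14.2,
    tolerance = 1e-12
  )
  expect_error(percent_change(0, 5), "zero")
})

test_that("full trial analysis recovers the injected effects end to end", {
  tr <- generate_trial(300, seed = 23)
  out <- trial_outcome(tr)
  pm <- out$per_metric
  # pull-up adjusted effect near +3.0 (4.5 - 1.5), runs near -54 s, shuttle -2
  expect_equal(pm$pull_ups$ancova$estimate, 3.0, tolerance = 0.8)
  expect_equal(pm$run_s$ancova$estimate, -54, tolerance = 12)
  expect_equal(pm$shuttle_s$ancova$estimate, -2.0, tolerance = 0.7)
  expect_true(pm$pull_ups$cohens_d > 0.4 && pm$pull_ups$cohens_d < 1.3)
  # within-group delta equals post mean - baseline mean
  ia <- pm$pull_ups$by_arm[[1]]
  expect_equal(ia$delta, ia$post_mean - ia$baseline_mean, tolerance = 1e-9)
  # completer-only analysis drops non-completers
  expect_equal(out$n_analyzed, sum(tr$completed))
  # ITT keeps everyone with LOCF
  itt <- trial_outcome(tr, itt = TRUE)
  expect_equal(itt$n_analyzed, nrow(tr))
  md <- trial_outcome_markdown(out)
  expect_true(any(grepl("Reference", md)))
})

test_that("classification metrics behave at the chance level and at perfection", {
  lv <- c("a", "b", "c", "d")
  y <- factor(rep(lv, each = 500), levels = lv)
  # perfect classifier
  p_perf <- diag(4)[as.integer(y), ]
  m <- classification_metrics(y, p_perf, lv)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(unname(rowSums(m$confusion)), rep(500, 4))
  # uniform-random predictions on balanced data: accuracy ~ .25, AUC ~ .5
  set.seed(24)
  p_rand <- matrix(rexp(2000 * 4), 2000, 4)
  p_rand <- p_rand / rowSums(p_rand)
  m2 <- classification_metrics(y, p_rand, lv)
  expect_equal(m2$accuracy, 0.25, tolerance = 0.03)
  expect_equal(m2$macro_auc, 0.5, tolerance = 0.03)
  # adjacent-class confuser concentrates off-diagonal mass next to the diagonal
  y_ord <- factor(rep(bmi_levels(), each = 200), levels = bmi_levels())
  idx <- as.integer(y_ord)
  shift <- ifelse(seq_along(idx) %% 4 == 0, 1, 0)
  pred_idx <- pmin(pmax(idx + shift, 1), 4)
  p_adj <- diag(4)[pred_idx, ]
  m3 <- classification_metrics(y_ord, p_adj, bmi_levels())
  cm <- m3$confusion
  off <- cm
  diag(off) <- 0
  adjacent <- sum(off[cbind(1:3, 2:4)]) + sum(off[cbind(2:4, 1:3)])
  expect_equal(sum(off), adjacent) # all confusion is between adjacent categories
})
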