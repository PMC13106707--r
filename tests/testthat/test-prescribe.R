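test_that("exact Shapley attribution satisfies additivity and closed forms", {
  set.seed(14)
  bg <- matrix(rnorm(80, 10, 3), 20, 4)
  # a pipeline that ignores all features attributes nothing
  sh0 <- metric_shap(function(m) rep(2.5, nrow(m)), c(1, 2, 3, 4), bg)
  expect_equal(unname(sh0$contributions), rep(0, 4))
  expect_equal(sh0$base, 2.5)
  # additive model: contribution_m = g_m(x_m) - g_m(background mean)
  g <- list(function(v) 2 * v, function(v) -v, function(v) v^2, function(v) sin(v))
  f <- function(m) g[[1]](m[, 1]) + g[[2]](m[, 2]) + g[[3]](m[, 3]) + g[[4]](m[, 4])
  x <- c(9, 12, 8, 11)
  sh <- metric_shap(f, x, bg)
  mu <- colMeans(bg)
  for (j in 1:4) {
    expect_equal(unname(sh$contributions[j]), g[[j]](x[j]) - g[[j]](mu[j]),
      tolerance = 1e-9
    )
  }
  expect_equal(sh$base + sum(sh$contributions), sh$prediction, tolerance = 1e-9)
  # non-additive model still reconstructs the margin exactly
  f2 <- function(m) m[, 1] * m[, 2] - exp(m[, 4] / 20)
  sh2 <- metric_shap(f2, x, bg)
  expect_equal(sh2$base + sum(sh2$contributions), sh2$prediction, tolerance = 1e-9)
  # non-deterministic pipelines are rejected
  f3 <- function(m) rnorm(nrow(m))
  expect_error(metric_shap(f3, x, bg), "deterministic")
})

test_that("the worked overweight pattern ranks pull-ups first", {
  # a constructed margin in which weak pull-ups push toward 'overweight'
  # and a fast shuttle pulls away, echoing the reported +0.21 / -0.08 case
  f <- function(m) 0.21 * (12 - m[, 2]) / 2 - 0.08 * (33 - m[, 4]) / 2 + 0.05 * (m[, 1] - 850) / 50
  bg <- cbind(rnorm(50, 850, 40), rnorm(50, 12, 2), rnorm(50, 38, 5), rnorm(50, 33, 2))
  set.seed(15)
  sh <- metric_shap(f, c(880, 7, 38, 30), bg)
  expect_gt(sh$contributions[["pull_ups"]], 0)
  expect_lt(sh$contributions[["shuttle"]], 0)
  expect_equal(names(which.max(sh$contributions)), "pull_ups")
  expect_equal(rank_deficiencies(sh), "pull_ups")
})

test_that("deficiency ranking applies the 50%-of-leader rule and fixed tie order", {
  expect_equal(
    rank_deficiencies(c(run_3000m = 0.05, pull_ups = 0.21, sit_ups = 0.02, shuttle = -0.08)),
    "pull_ups"
  )
  expect_equal(
    rank_deficiencies(c(run_3000m = 0.20, pull_ups = 0.15, sit_ups = 0.01, shuttle = -0.1)),
    c("run_3000m", "pull_ups")
  )
  expect_equal(
    rank_deficiencies(c(run_3000m = -0.1, pull_ups = -0.2, sit_ups = 0, shuttle = -0.01)),
    character(0)
  )
  # exact tie: fixed metric order decides
  expect_equal(
    rank_deficiencies(c(run_3000m = 0.1, pull_ups = 0.1, sit_ups = 0, shuttle = 0)),
    c("run_3000m", "pull_ups")
  )
})

test_that("the baseline template holds 10 sessions and 300 weekly minutes", {
  plan <- base_plan()
  expect_equal(sum(plan$freq), 10)
  expect_equal(plan_minutes(plan), 300)
  expect_equal(plan$load, rep(1, 3))
  expect_match(attr(plan, "hiit_protocol"), "20 s")
  # empty deficiency list leaves the template untouched
  expect_equal(as.data.frame(map_prescription(character(0))), as.data.frame(plan))
})

test_that("deficiencies map to the right modality emphases", {
  p <- map_prescription("pull_ups")
  expect_equal(p$freq[p$modality == "strength"], 3)
  expect_equal(p$load[p$modality == "strength"], 1.2)
  expect_equal(plan_minutes(p), 330)
  expect_true("strength" %in% attr(p, "emphasis"))
  # aerobic + HIIT emphasis leaves strength untouched
  p2 <- map_prescription(c("run_3000m", "shuttle"))
  expect_equal(p2$freq[p2$modality == "aerobic"], 4)
  expect_equal(p2$freq[p2$modality == "HIIT"], 6)
  expect_equal(p2$freq[p2$modality == "strength"], 2)
  expect_equal(p2$load[p2$modality == "strength"], 1)
  # sit-ups route to the strength slot with a core tag
  p3 <- map_prescription("sit_ups")
  expect_equal(p3$freq[p3$modality == "strength"], 3)
  expect_true("core" %in% attr(p3, "emphasis"))
  expect_error(map_prescription("flexibility"), "unknown deficiency")
  # JSON round-trip keeps the session table
  js <- jsonlite::fromJSON(plan_to_json(p))
  expect_equal(js$total_weekly_minutes, 330)
  expect_equal(js$schema_version, "1.0")
})

test_that("FRBI is the acute:chronic mean daily load ratio", {
  dates <- Sys.Date() - 27:0
  expect_equal(compute_frbi(data.frame(date = dates, load = 100)), 1.0)
  # acute week at 1.3x the chronic mean
  load <- rep(100, 28)
  load[22:28] <- 130
  frbi <- compute_frbi(data.frame(date = dates, load = load))
  expect_equal(frbi, (130 / 1) / ((21 * 100 + 7 * 130) / 28), tolerance = 1e-12)
  expect_error(compute_frbi(data.frame(date = dates[1:10], load = 100)), "chronic window")
  # padding a 9-day history: acute = 700/7, chronic = 900/28
  expect_equal(
    compute_frbi(data.frame(date = dates[20:28], load = 100), pad = TRUE),
    (700 / 7) / (900 / 28),
    tolerance = 1e-12
  )
  expect_error(compute_frbi(data.frame(date = dates, load = 0)), "zero")
  expect_error(compute_frbi(data.frame(date = dates, load = 100)[0, ]), "empty")
  expect_error(compute_frbi(data.frame(date = rev(dates), load = 100)), "non-decreasing")
})

test_that("prescription adjustment: deload dominance, overload midpoint, idempotence", {
  plan <- map_prescription("pull_ups")
  # FRBI above 1.2 deloads every modality by 17.5% for 4 days and nothing grows
  del <- adjust_prescription(plan, c(run_3000m = -0.1), frbi = 1.3)
  expect_equal(del$load, plan$load * 0.825, tolerance = 1e-12)
  expect_equal(attr(del, "deload_days"), 4)
  expect_true(all(del$minutes <= plan$minutes))
  # all metrics improving at frbi <= 1.2 is the identity
  prog_ok <- c(run_3000m = 0.05, pull_ups = 0.03, sit_ups = 0.04, shuttle = 0.02)
  same <- adjust_prescription(plan, prog_ok, frbi = 1.0)
  expect_equal(as.data.frame(same), as.data.frame(plan))
  # stagnation adds the 7.5% volume midpoint to the mapped modality
  adj <- adjust_prescription(plan, c(run_3000m = 0.0, pull_ups = 0.05), frbi = 1.0)
  expect_equal(
    adj$minutes[adj$modality == "aerobic"],
    plan$minutes[plan$modality == "aerobic"] * 1.075
  )
  expect_equal(
    adj$minutes[adj$modality == "strength"],
    plan$minutes[plan$modality == "strength"]
  )
  # boundary: exactly 2% improvement counts as progress
  adj2 <- adjust_prescription(plan, c(shuttle = 0.02), frbi = 1.0)
  expect_equal(as.data.frame(adj2), as.data.frame(plan))
})
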