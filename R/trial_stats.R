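#' Within-group change with 95% confidence interval
#'
#' Paired pre/post change: `delta = mean(post - baseline)` with a
#' t-distribution CI on the paired differences. Zero-variance differences
#' give a degenerate CI at the common change.
#'
#' @param baseline,post paired numeric samples of equal length (n >= 2).
#' @param conf confidence level (default 0.95).
#' @return list with `delta`, `ci` (length 2), `n`.
#' @export
within_group_change <- function(baseline, post, conf = 0.95) {
  if (length(baseline) != length(post)) stop("length mismatch", call. = FALSE)
  n <- length(baseline)
  if (n < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- post - baseline
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    ci <- c(m, m)
  } else {
    half <- stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
    ci <- c(m - half, m + half)
  }
  list(delta = m, ci = ci, n = n)
}

#' Baseline-adjusted between-group effect (ANCOVA)
#'
#' Fits `post = alpha + tau * arm + beta * baseline + error` and reports the
#' adjusted intervention-vs-control effect `tau` with its Wald confidence
#' interval and p-value.
#'
#' @param baseline,post numeric outcome vectors.
#' @param arm factor (or coercible) with levels `control` (reference) and
#'   `intervention`; both must be present.
#' @param conf confidence level.
#' @return list with `estimate`, `ci`, `p_value`, `model` (the `lm` fit).
#' @export
ancova_group_effect <- function(baseline, post, arm, conf = 0.95) {
  arm <- as.factor(arm)
  if (nlevels(droplevels(arm)) < 2) stop("both arms must be represented", call. = FALSE)
  if ("control" %in% levels(arm)) arm <- stats::relevel(arm, "control")
  fit <- stats::lm(post ~ arm + baseline)
  co <- summary(fit)$coefficients
  row <- grep("^arm", rownames(co))[1]
  ci <- stats::confint(fit, level = conf)[row, ]
  list(
    estimate = unname(co[row, "Estimate"]),
    ci = unname(ci),
    p_value = unname(co[row, "Pr(>|t|)"]),
    model = fit
  )
}

#' Cohen's d on change scores
#'
#' Standardized between-group difference of change scores: difference of
#' mean changes divided by their pooled standard deviation.
#'
#' @param change_intervention,change_control change-score samples (n >= 2
#'   each).
#' @return scalar d.
#' @export
cohens_d_change <- function(change_intervention, change_control) {
  n1 <- length(change_intervention)
  n2 <- length(change_control)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  s1 <- stats::var(change_intervention)
  s2 <- stats::var(change_control)
  sp <- sqrt(((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled SD of change scores is zero", call. = FALSE)
  (mean(change_intervention) - mean(change_control)) / sp
}

#' McNemar's test on unhealthy-weight status
#'
#' Dichotomizes BMI categories at the overweight boundary (unhealthy =
#' overweight or obese) and tests the marginal pre/post change with
#' `chi^2 = (b - c)^2 / (b + c)` on the discordant counts, falling back to
#' the exact binomial test when `b + c < 25`. `b + c = 0` gives p = 1 by
#' convention.
#'
#' @param pre_category,post_category paired category vectors (values among
#'   [bmi_levels()]).
#' @return list with `statistic`, `p_value`, `b` (unhealthy -> healthy),
#'   `c` (healthy -> unhealthy), `method`.
#' @export
mcnemar_shift <- function(pre_category, post_category) {
  if (length(pre_category) != length(post_category)) stop("length mismatch", call. = FALSE)
  unhealthy <- function(x) as.character(x) %in% c("overweight", "obese")
  pre_u <- unhealthy(pre_category)
  post_u <- unhealthy(post_category)
  b <- sum(pre_u & !post_u)
  cc <- sum(!pre_u & post_u)
  if (b + cc == 0) {
    return(list(statistic = 0, p_value = 1, b = b, c = cc, method = "none discordant"))
  }
  stat <- (b - cc)^2 / (b + cc)
  if (b + cc < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    method <- "exact binomial"
  } else {
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-squared"
  }
  list(statistic = stat, p_value = p, b = b, c = cc, method = method)
}

#' BMI-category transition matrix
#'
#' Row-normalized 4x4 matrix of pre -> post category transitions; rows of
#' categories absent at baseline are `NaN`.
#'
#' @param pre_category,post_category paired category vectors.
#' @return 4x4 matrix with dimnames over [bmi_levels()].
#' @export
transition_rates <- function(pre_category, post_category) {
  lv <- bmi_levels()
  pre <- factor(as.character(pre_category), levels = lv)
  post <- factor(as.character(post_category), levels = lv)
  tab <- table(pre, post)
  out <- sweep(tab, 1, rowSums(tab), "/")
  matrix(out, 4, 4, dimnames = list(pre = lv, post = lv))
}

#' Percent change between assessments
#'
#' For time metrics (where lower is better) a decrease is reported as a
#' positive percentage: `100 * (baseline - post) / baseline`. For count
#' metrics an increase is positive: `100 * (post - baseline) / baseline`.
#' Reported values are rounded to one decimal; pass `digits = NULL` for the
#' full-precision value.
#'
#' @param baseline,post metric means (baseline non-zero).
#' @param type `"time"` or `"count"`.
#' @param digits reporting precision (default 1).
#' @return percent change.
#' @export
percent_change <- function(baseline, post, type = c("time", "count"), digits = 1) {
  type <- match.arg(type)
  if (any(baseline == 0)) stop("zero baseline", call. = FALSE)
  pc <- if (type == "time") {
    100 * (baseline - post) / baseline
  } else {
    100 * (post - baseline) / baseline
  }
  if (is.null(digits)) pc else round(pc, digits)
}

#' Full trial outcome analysis
#'
#' Completer-only (per-protocol) analysis of a two-arm trial table: per
#' metric, baseline/post means and SDs by arm, within-group change with CI,
#' the baseline-adjusted ANCOVA between-group effect, and Cohen's d on
#' change scores; plus the BMI category transition matrix and McNemar's
#' test on unhealthy-weight status. Set `itt = TRUE` for intention-to-treat
#' with last observation carried forward (post = baseline for
#' non-completers).
#'
#' @param trial data.frame from [generate_trial()] (or the same layout).
#' @param metrics named list mapping metric labels to the column stems to
#'   analyse.
#' @param itt intention-to-treat flag (default `FALSE`, completer-only).
#' @return object of class `fitrx_trial_outcome`.
#' @export
trial_outcome <- function(trial,
                          metrics = c(
                            pull_ups = "pull_ups", run_s = "run_s",
                            sit_ups = "sit_ups", shuttle_s = "shuttle_s",
                            bmi = "bmi"
                          ),
                          itt = FALSE) {
  if (itt) {
    d <- trial
    locf <- !d$completed
    for (stem in metrics) {
      d[[paste0("post_", stem)]][locf] <- d[[paste0("baseline_", stem)]][locf]
    }
    if ("post_category" %in% names(d)) {
      d$post_category[locf] <- d$baseline_category[locf]
    }
  } else {
    d <- trial[trial$completed, , drop = FALSE]
  }
  arms <- c("intervention", "control")
  per_metric <- lapply(names(metrics), function(lbl) {
    stem <- metrics[[lbl]]
    b <- d[[paste0("baseline_", stem)]]
    p <- d[[paste0("post_", stem)]]
    rows <- lapply(arms, function(a) {
      sel <- d$arm == a
      wg <- within_group_change(b[sel], p[sel])
      list(
        arm = a, n = sum(sel),
        baseline_mean = mean(b[sel]), baseline_sd = stats::sd(b[sel]),
        post_mean = mean(p[sel]), post_sd = stats::sd(p[sel]),
        delta = wg$delta, ci = wg$ci
      )
    })
    anc <- ancova_group_effect(b, p, d$arm)
    dd <- cohens_d_change(
      (p - b)[d$arm == "intervention"],
      (p - b)[d$arm == "control"]
    )
    list(metric = lbl, by_arm = rows, ancova = anc[c("estimate", "ci", "p_value")], cohens_d = dd)
  })
  names(per_metric) <- names(metrics)
  out <- list(
    per_metric = per_metric,
    transitions = transition_rates(d$baseline_category, d$post_category),
    mcnemar = mcnemar_shift(d$baseline_category, d$post_category),
    n_analyzed = nrow(d),
    analysis = if (itt) "intention-to-treat (LOCF)" else "per-protocol (completers)"
  )
  class(out) <- "fitrx_trial_outcome"
  out
}

#' @export
print.fitrx_trial_outcome <- function(x, ...) {
  cat(sprintf("Trial outcome (%s, n = %d)\n", x$analysis, x$n_analyzed))
  for (m in x$per_metric) {
    anc <- m$ancova
    cat(sprintf(
      "  %-10s adjusted between-group delta %+0.2f (%0.2f to %0.2f), p = %.3g, d = %.2f\n",
      m$metric, anc$estimate, anc$ci[1], anc$ci[2], anc$p_value, m$cohens_d
    ))
  }
  mc <- x$mcnemar
  cat(sprintf(
    "  unhealthy-weight shift: b = %d, c = %d, %s p = %.3g\n",
    mc$b, mc$c, mc$method, mc$p_value
  ))
  invisible(x)
}

#' Markdown rendering of a trial outcome
#'
#' @param x a `fitrx_trial_outcome`.
#' @return character vector of markdown lines.
#' @export
trial_outcome_markdown <- function(x) {
  stopifnot(inherits(x, "fitrx_trial_outcome"))
  lines <- c(
    "| Metric | Group | Baseline (mean +/- SD) | Post (mean +/- SD) | Within-group delta (95% CI) | Between-group delta (95% CI) | p | Cohen's d |",
    "|---|---|---|---|---|---|---|---|"
  )
  for (m in x$per_metric) {
    anc <- m$ancova
    for (i in seq_along(m$by_arm)) {
      r <- m$by_arm[[i]]
      bet <- if (i == 1) {
        sprintf(
          "%+.1f (%+.1f to %+.1f) | %.3g | %.2f",
          anc$estimate, anc$ci[1], anc$ci[2], anc$p_value, m$cohens_d
        )
      } else {
        "(Reference) |  | "
      }
      lines <- c(lines, sprintf(
        "| %s | %s | %.1f +/- %.1f | %.1f +/- %.1f | %+.1f (%+.1f to %+.1f) | %s |",
        m$metric, r$arm, r$baseline_mean, r$baseline_sd, r$post_mean, r$post_sd,
        r$delta, r$ci[1], r$ci[2], bet
      ))
    }
  }
  lines
}
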