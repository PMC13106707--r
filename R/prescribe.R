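#' Names of the four fitness metrics
#'
#' Fixed order used for loss weights, attribution and tie-breaking:
#' 3,000 m run, pull-ups, sit-ups, 30x2 shuttle.
#'
#' @export
fitness_metrics <- function() c("run_3000m", "pull_ups", "sit_ups", "shuttle")

#' Exact Shapley attribution over the four fitness metrics
#'
#' Computes exact Shapley values on the 4-feature coalition lattice
#' (2^4 = 16 model evaluations, no sampling). Features absent from a
#' coalition are imputed with the background mean. Additivity holds by
#' construction: `base + sum(contributions) = f(x)` up to floating point.
#'
#' @param f deterministic model function taking an `N x 4` matrix (columns
#'   in [fitness_metrics()] order) and returning one numeric margin per row
#'   (e.g. the log-odds of the predicted class).
#' @param x numeric vector of the subject's 4 metric summaries.
#' @param background non-empty reference matrix (N x 4) defining the
#'   imputation means and the base value.
#' @return object of class `fitrx_shap`: list with `contributions` (named,
#'   signed, in the units of `f`), `base` (value with all features
#'   imputed), and `prediction` (`f(x)`).
#' @export
metric_shap <- function(f, x, background) {
  background <- as.matrix(background)
  if (nrow(background) < 1) stop("`background` must be non-empty", call. = FALSE)
  if (length(x) != 4L || ncol(background) != 4L) {
    stop("attribution is defined over exactly 4 metrics", call. = FALSE)
  }
  x <- as.numeric(x)
  bg <- colMeans(background)
  n_feat <- 4L
  # all 16 coalitions as a logical matrix; row i = members of coalition i
  coalitions <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n_feat)))
  inputs <- matrix(bg, nrow(coalitions), n_feat, byrow = TRUE)
  for (j in seq_len(n_feat)) inputs[coalitions[, j], j] <- x[j]
  colnames(inputs) <- fitness_metrics()
  v <- as.numeric(f(inputs))
  if (length(v) != nrow(coalitions)) {
    stop("`f` must return one value per input row", call. = FALSE)
  }
  # determinism guard: re-evaluate the full coalition
  v_full_again <- as.numeric(f(inputs[nrow(inputs), , drop = FALSE]))
  if (!isTRUE(all.equal(v_full_again, v[nrow(inputs)], tolerance = 1e-9))) {
    stop("model function is not deterministic; attribution is undefined", call. = FALSE)
  }
  sizes <- rowSums(coalitions)
  key <- coalitions %*% 2^(seq_len(n_feat) - 1)
  contrib <- numeric(n_feat)
  for (j in seq_len(n_feat)) {
    without <- which(!coalitions[, j])
    s <- sizes[without]
    w <- factorial(s) * factorial(n_feat - s - 1) / factorial(n_feat)
    with_j <- match(key[without] + 2^(j - 1), key)
    contrib[j] <- sum(w * (v[with_j] - v[without]))
  }
  structure(
    list(
      contributions = stats::setNames(contrib, fitness_metrics()),
      base = v[1], prediction = v[length(v)]
    ),
    class = "fitrx_shap"
  )
}

#' @export
print.fitrx_shap <- function(x, ...) {
  cat("Shapley attribution (log-odds units)\n")
  cat(sprintf("  base %.4f -> prediction %.4f\n", x$base, x$prediction))
  for (m in names(x$contributions)) {
    cat(sprintf("  %-10s %+.4f\n", m, x$contributions[[m]]))
  }
  invisible(x)
}

#' Rank fitness deficiencies from an attribution
#'
#' Selects the 1-2 metrics with the largest positive contributions toward
#' the (less healthy) predicted class: the top metric always, plus the
#' runner-up iff its contribution is at least `ratio` (default 50%) of the
#' top one. Ties break by the fixed metric order. All-non-positive
#' contributions yield an empty list.
#'
#' @param attribution a `fitrx_shap` or a named contribution vector.
#' @param ratio runner-up inclusion threshold as a fraction of the leader.
#' @return character vector of 0-2 metric names.
#' @export
rank_deficiencies <- function(attribution, ratio = 0.5) {
  contrib <- if (inherits(attribution, "fitrx_shap")) {
    attribution$contributions
  } else {
    attribution
  }
  contrib <- contrib[fitness_metrics()]
  pos <- contrib[contrib > 0]
  if (!length(pos)) {
    return(character(0))
  }
  ord <- order(-pos, match(names(pos), fitness_metrics()))
  pos <- pos[ord]
  out <- names(pos)[1]
  if (length(pos) >= 2 && pos[2] >= ratio * pos[1]) out <- c(out, names(pos)[2])
  out
}

#' Baseline weekly training template
#'
#' The generic weekly protocol: HIIT 5 sessions/week (5 cycles of 20 s
#' maximal sprint + 40 s rest per session), aerobic exercise 3 sessions/week,
#' strength training 2 sessions/week, 30 minutes each -- 10 sessions and
#' 300 cumulative minutes, meeting the >= 300 min/week target.
#'
#' @return object of class `fitrx_plan`: a data.frame with columns
#'   `modality`, `freq` (sessions/week), `minutes` (per session), `load`
#'   (multiplier), with attributes `emphasis` (character) and
#'   `hiit_protocol`.
#' @export
base_plan <- function() {
  plan <- data.frame(
    modality = c("HIIT", "aerobic", "strength"),
    freq = c(5L, 3L, 2L),
    minutes = c(30, 30, 30),
    load = c(1, 1, 1),
    stringsAsFactors = FALSE
  )
  structure(plan,
    class = c("fitrx_plan", "data.frame"),
    emphasis = character(0),
    hiit_protocol = "5 cycles x (20 s maximal sprint + 40 s rest)"
  )
}

#' Total weekly minutes of a plan
#' @param plan a `fitrx_plan`.
#' @export
plan_minutes <- function(plan) sum(plan$freq * plan$minutes)

deficiency_modality <- function(metric) {
  switch(metric,
    run_3000m = "aerobic",
    pull_ups = "strength",
    sit_ups = "strength", # core work lives in the strength slot
    shuttle = "HIIT",
    stop("unknown deficiency tag: ", metric, call. = FALSE)
  )
}

deficiency_emphasis <- function(metric) {
  switch(metric,
    run_3000m = "aerobic",
    pull_ups = "strength",
    sit_ups = "core",
    shuttle = "HIIT",
    stop("unknown deficiency tag: ", metric, call. = FALSE)
  )
}

#' Map deficiencies to a weekly prescription
#'
#' Starts from the [base_plan()] template and, for each prioritized
#' deficiency, adds one weekly session of the mapped modality and raises its
#' load multiplier by `load_factor` (default 1.2): 3,000 m -> aerobic
#' emphasis, pull-ups -> (upper-body) strength, sit-ups -> core strength,
#' shuttle -> HIIT. Total weekly minutes never drop below 300.
#'
#' @param deficiencies character vector from [rank_deficiencies()].
#' @param plan starting plan (default the template).
#' @param load_factor multiplicative load emphasis per deficiency.
#' @return adjusted `fitrx_plan`.
#' @export
map_prescription <- function(deficiencies, plan = base_plan(), load_factor = 1.2) {
  stopifnot(inherits(plan, "fitrx_plan"))
  emphasis <- attr(plan, "emphasis")
  for (m in deficiencies) {
    mod <- deficiency_modality(m)
    i <- which(plan$modality == mod)
    plan$freq[i] <- plan$freq[i] + 1L
    plan$load[i] <- plan$load[i] * load_factor
    emphasis <- union(emphasis, deficiency_emphasis(m))
  }
  if (plan_minutes(plan) < 300) {
    stop("internal error: plan fell below the 300-minute floor", call. = FALSE)
  }
  attr(plan, "emphasis") <- emphasis
  plan
}

#' @export
print.fitrx_plan <- function(x, ...) {
  cat("Weekly exercise plan (", plan_minutes(x), " min total)\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %-9s %d x %g min, load x%.3f\n",
      x$modality[i], x$freq[i], x$minutes[i], x$load[i]
    ))
  }
  emph <- attr(x, "emphasis")
  if (length(emph)) cat("  emphasis:", paste(emph, collapse = ", "), "\n")
  dl <- attr(x, "deload_days")
  if (!is.null(dl)) cat("  deload window:", dl, "days\n")
  invisible(x)
}

#' Serialize a weekly plan to JSON
#'
#' Schema-versioned JSON with the session table, emphasis tags, the HIIT
#' protocol and the static dietary/mental-health guidance text.
#'
#' @param plan a `fitrx_plan`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @export
plan_to_json <- function(plan, path = NULL) {
  obj <- list(
    schema_version = "1.0",
    sessions = as.data.frame(plan),
    emphasis = as.list(attr(plan, "emphasis")),
    total_weekly_minutes = plan_minutes(plan),
    hiit_protocol = attr(plan, "hiit_protocol"),
    deload_days = attr(plan, "deload_days"),
    static_guidance = static_guidance_text()
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
  }
}

# carried as static plan text only; not computed on
static_guidance_text <- function() {
  c(
    "Diet: 2,500-3,000 kcal/day adjusted to BMI; protein >= 84 g/day;",
    "carbohydrate 300-400 g/day (whole grains); healthy fats 50-70 g/day;",
    "fiber >= 25 g/day; minimize high-sugar foods, prefer low-fat dairy and lean meat.",
    "Mental health: stress-management activity >= 1x/week; >= 30 min daily outdoor activity."
  )
}

#' Fatigue-recovery balance index (FRBI)
#'
#' The acute:chronic workload ratio: mean daily training load over the
#' trailing `acute_days` window divided by the mean daily load over the
#' trailing `chronic_days` window (both ending on the last recorded day;
#' days without sessions count as zero load). Steady daily load gives 1.0;
#' values above 1.2 flag overtraining risk and trigger a deload.
#'
#' @param history data.frame with `date` (Date, non-decreasing) and `load`
#'   (non-negative session load, e.g. RPE x minutes).
#' @param acute_days,chronic_days window lengths in days (defaults 7 / 28).
#' @param pad if `TRUE`, a history shorter than the chronic window is
#'   explicitly padded with zero-load days at the start; otherwise it is an
#'   error.
#' @return scalar FRBI.
#' @export
compute_frbi <- function(history, acute_days = 7, chronic_days = 28, pad = FALSE) {
  if (is.null(history) || nrow(history) == 0) {
    stop("empty load history", call. = FALSE)
  }
  if (!all(c("date", "load") %in% names(history))) {
    stop("`history` needs `date` and `load` columns", call. = FALSE)
  }
  if (any(history$load < 0)) stop("loads must be non-negative", call. = FALSE)
  dates <- as.Date(history$date)
  if (is.unsorted(dates)) stop("dates must be non-decreasing", call. = FALSE)
  span <- as.numeric(max(dates) - min(dates)) + 1
  if (span < chronic_days && !pad) {
    stop(
      "history spans ", span, " day(s) < chronic window (", chronic_days,
      "); record more days or set pad = TRUE",
      call. = FALSE
    )
  }
  end <- max(dates)
  daily <- function(win) {
    sum(history$load[dates > end - win]) / win
  }
  chronic <- daily(chronic_days)
  if (chronic == 0) stop("chronic load is zero; FRBI undefined", call. = FALSE)
  daily(acute_days) / chronic
}

#' Adjust a prescription from progress and fatigue state
#'
#' The deload guard dominates: if `frbi > frbi_threshold` (1.2), every
#' modality's load multiplier is reduced by `deload_fraction` (default
#' 17.5%, the midpoint of the 15-20% band) for `deload_days` (default 4,
#' midpoint of 3-5 days) and nothing is intensified. Otherwise, each metric
#' whose relative improvement since the last assessment falls below
#' `improve_threshold` (2%) has its mapped modality's session minutes
#' increased by `increment` (7.5%, midpoint of the 5-10% weekly
#' progressive-overload band); improving metrics leave the plan unchanged.
#'
#' @param plan a `fitrx_plan`.
#' @param progress named numeric vector over [fitness_metrics()]: fractional
#'   improvement since the last assessment (positive = better).
#' @param frbi current fatigue-recovery balance index.
#' @param improve_threshold,increment,deload_fraction,deload_days,frbi_threshold
#'   tunable rule parameters (defaults as above).
#' @return adjusted `fitrx_plan`; after a deload the `deload_days` attribute
#'   records the reduced-load window.
#' @export
adjust_prescription <- function(plan, progress, frbi,
                                improve_threshold = 0.02, increment = 0.075,
                                deload_fraction = 0.175, deload_days = 4,
                                frbi_threshold = 1.2) {
  stopifnot(inherits(plan, "fitrx_plan"))
  if (frbi > frbi_threshold) {
    plan$load <- plan$load * (1 - deload_fraction)
    attr(plan, "deload_days") <- deload_days
    return(plan)
  }
  progress <- progress[intersect(names(progress), fitness_metrics())]
  for (m in names(progress)) {
    if (is.na(progress[[m]]) || progress[[m]] >= improve_threshold) next
    mod <- deficiency_modality(m)
    i <- which(plan$modality == mod)
    plan$minutes[i] <- plan$minutes[i] * (1 + increment)
  }
  bad <- plan$minutes < 0 | plan$load < 0
  if (any(bad)) {
    warning("negative durations/loads clamped to zero", call. = FALSE)
    plan$minutes <- pmax(plan$minutes, 0)
    plan$load <- pmax(plan$load, 0)
  }
  plan
}
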