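#' Largest-remainder apportionment of counts
#'
#' Splits `n` into integer counts proportional to `proportions`, rounding by
#' the largest-remainder (Hamilton) rule so the counts always sum to `n`.
#' Remainder ties are broken by position (earlier category wins), which makes
#' the allocation deterministic.
#'
#' @param n total count.
#' @param proportions non-negative fractions summing to 1 (tolerance 1e-9).
#' @return integer vector of counts, same length and names as `proportions`.
#' @examples
#' largest_remainder(6698, c(0.053, 0.745, 0.190, 0.012))
#' @export
largest_remainder <- function(n, proportions) {
  if (n < 0 || n != round(n)) stop("`n` must be a non-negative integer", call. = FALSE)
  if (any(proportions < 0)) stop("proportions must be non-negative", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  quota <- n * proportions
  counts <- floor(quota)
  short <- as.integer(round(n - sum(counts)))
  if (short > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

#' Specify a synthetic fitness cohort
#'
#' Bundles the parameters of the synthetic-cohort generator: the number of
#' subjects, the BMI-category mix, the per-category fatigue slope of the
#' 3,000 m lap-time series, and per-metric mean shifts between categories.
#'
#' Defaults emulate a homogeneous male undergraduate population: category
#' proportions 5.3 / 74.5 / 19.0 / 1.2 percent
#' (underweight/normal/overweight/obese), a mean 200 m lap pace near 57 s
#' (about a 14.2 min 3,000 m), pull-ups near 10 +/- 3, sit-ups near 38 +/- 6,
#' and a 30x2 shuttle near 32.5 +/- 2.3 s. Less healthy categories run and
#' shuttle slower, manage fewer pull-ups/sit-ups, and slow down more over the
#' final laps (the fatigue signal the sequence model is meant to pick up).
#'
#' @param n number of subjects (>= number of categories with positive share).
#' @param class_proportions four non-negative fractions summing to 1, ordered
#'   underweight, normal, overweight, obese.
#' @param fatigue_slope per-category late-lap slowdown in seconds per lap
#'   index (lap times increase linearly at this rate around mid-race).
#' @param metric_effects 4x4 matrix of standardized mean shifts by category
#'   (rows: categories; columns: `run_pace`, `pull_ups`, `sit_ups`,
#'   `shuttle`), relative to the normal-weight baseline.
#' @param noise_sd per-metric noise SDs, names `lap`, `pull_ups`, `sit_ups`,
#'   `shuttle` (metric units).
#' @param base_pace mean 200 m lap pace, seconds.
#' @param pace_sdlog log-scale SD of the per-subject lognormal base pace.
#' @param pace_sd between-subject pace SD used to scale standardized pace
#'   shifts into seconds.
#' @param metric_base,metric_sd baseline means and SDs for `pull_ups`,
#'   `sit_ups`, `shuttle`.
#' @param seed integer seed; every draw of the generator derives from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n,
                        class_proportions = c(
                          underweight = 0.053, normal = 0.745,
                          overweight = 0.190, obese = 0.012
                        ),
                        fatigue_slope = c(
                          underweight = 0.10, normal = 0.25,
                          overweight = 0.60, obese = 1.00
                        ),
                        metric_effects = default_metric_effects(),
                        noise_sd = c(
                          lap = 1.5, pull_ups = 3.0,
                          sit_ups = 6.0, shuttle = 2.3
                        ),
                        base_pace = 56.8,
                        pace_sdlog = 0.07,
                        pace_sd = 4.0,
                        metric_base = c(pull_ups = 10, sit_ups = 38, shuttle = 32.5),
                        metric_sd = c(pull_ups = 3, sit_ups = 6, shuttle = 2.3),
                        seed = 42) {
  if (length(class_proportions) != 4L) {
    stop("`class_proportions` must have 4 entries", call. = FALSE)
  }
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-9) {
    stop("`class_proportions` must be non-negative and sum to 1", call. = FALSE)
  }
  n_pos <- sum(class_proportions > 0)
  if (n < n_pos) {
    stop("`n` too small to place every positive-proportion category", call. = FALSE)
  }
  if (any(noise_sd < 0)) stop("`noise_sd` must be non-negative", call. = FALSE)
  stopifnot(
    is.matrix(metric_effects), all(dim(metric_effects) == c(4L, 4L)),
    length(fatigue_slope) == 4L
  )
  dimnames(metric_effects) <- list(
    bmi_levels(), c("run_pace", "pull_ups", "sit_ups", "shuttle")
  )
  structure(
    list(
      n = as.integer(n),
      class_proportions = stats::setNames(as.numeric(class_proportions), bmi_levels()),
      fatigue_slope = stats::setNames(as.numeric(fatigue_slope), bmi_levels()),
      metric_effects = metric_effects,
      noise_sd = noise_sd,
      base_pace = base_pace,
      pace_sdlog = pace_sdlog,
      pace_sd = pace_sd,
      metric_base = metric_base,
      metric_sd = metric_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Default per-category standardized metric shifts
#'
#' Rows are BMI categories, columns the four generator channels
#' (`run_pace`, `pull_ups`, `sit_ups`, `shuttle`); entries are mean shifts in
#' SD units relative to normal weight. Counts fall and times rise
#' monotonically from normal through overweight to obese.
#'
#' @export
default_metric_effects <- function() {
  m <- rbind(
    underweight = c(run_pace = 0.3, pull_ups = -0.5, sit_ups = -0.3, shuttle = 0.3),
    normal      = c(run_pace = 0.0, pull_ups =  0.0, sit_ups =  0.0, shuttle = 0.0),
    overweight  = c(run_pace = 0.8, pull_ups = -1.0, sit_ups = -0.8, shuttle = 0.8),
    obese       = c(run_pace = 1.6, pull_ups = -2.0, sit_ups = -1.5, shuttle = 1.6)
  )
  m
}

bmi_ranges <- function() {
  rbind(
    underweight = c(16.0, 18.5),
    normal      = c(18.5, 25.0),
    overweight  = c(25.0, 30.0),
    obese       = c(30.0, 36.0)
  )
}

#' Generate a synthetic fitness cohort
#'
#' Draws one subject per row with 15 lap times of a 3,000 m run (200 m
#' splits), pull-up and 60 s sit-up counts, a 30x2 shuttle-run time, BMI and
#' its WHO category. Category counts follow the spec proportions exactly via
#' [largest_remainder()]. Lap times are a per-subject lognormal base pace
#' plus a category-specific linear fatigue slope (centred mid-race) plus
#' i.i.d. Gaussian split noise; scalar metrics are Gaussian around
#' category-shifted means, counts rounded and truncated at zero. The output
#' is fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return a data.frame with columns `subject_id`, `lap_01` ... `lap_15`,
#'   `pull_ups`, `sit_ups`, `shuttle_s`, `bmi`, `category`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- largest_remainder(spec$n, spec$class_proportions)
  cats <- rep(bmi_levels(), times = counts)
  n <- spec$n
  out <- with_seed(spec$seed, {
    ranges <- bmi_ranges()
    bmi <- numeric(n)
    for (g in seq_along(bmi_levels())) {
      idx <- which(cats == bmi_levels()[g])
      if (length(idx)) {
        bmi[idx] <- stats::runif(length(idx), ranges[g, 1], ranges[g, 2] - 1e-6)
      }
    }
    eff <- spec$metric_effects[cats, , drop = FALSE]
    base_pace_i <- (spec$base_pace + eff[, "run_pace"] * spec$pace_sd) *
      exp(stats::rnorm(n, 0, spec$pace_sdlog))
    slope <- spec$fatigue_slope[cats]
    lap_idx <- seq_len(15) - 8 # centred so the slope leaves total time balanced
    laps <- matrix(0, n, 15)
    for (t in seq_len(15)) {
      laps[, t] <- base_pace_i + slope * lap_idx[t] +
        stats::rnorm(n, 0, spec$noise_sd[["lap"]])
    }
    laps <- pmax(laps, 1)
    pull <- pmax(0, round(stats::rnorm(
      n, spec$metric_base[["pull_ups"]] + eff[, "pull_ups"] * spec$metric_sd[["pull_ups"]],
      spec$noise_sd[["pull_ups"]]
    )))
    sit <- pmax(0, round(stats::rnorm(
      n, spec$metric_base[["sit_ups"]] + eff[, "sit_ups"] * spec$metric_sd[["sit_ups"]],
      spec$noise_sd[["sit_ups"]]
    )))
    shuttle <- pmax(1, stats::rnorm(
      n, spec$metric_base[["shuttle"]] + eff[, "shuttle"] * spec$metric_sd[["shuttle"]],
      spec$noise_sd[["shuttle"]]
    ))
    d <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      laps,
      pull_ups = as.integer(pull),
      sit_ups = as.integer(sit),
      shuttle_s = shuttle,
      bmi = bmi,
      stringsAsFactors = FALSE
    )
    names(d)[2:16] <- sprintf("lap_%02d", 1:15)
    d$category <- assign_bmi_category(d$bmi)
    # shuffle so category blocks are not contiguous
    d[sample.int(n), , drop = FALSE]
  })
  rownames(out) <- NULL
  out
}

# Run expr under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so generators compose without interfering.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Extract the 18-column compact feature matrix
#'
#' @param cohort a cohort data.frame from [generate_cohort()] or [read_cohort()].
#' @return numeric matrix with columns `lap_01` ... `lap_15`, `pull_ups`,
#'   `sit_ups`, `shuttle_s`.
#' @export
compact_features <- function(cohort) {
  cols <- c(sprintf("lap_%02d", 1:15), "pull_ups", "sit_ups", "shuttle_s")
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    stop("cohort is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  as.matrix(cohort[, cols])
}

#' Per-subject summaries of the four fitness metrics
#'
#' Collapses a cohort to the four metric summaries used for attribution and
#' prescription: total 3,000 m time (seconds), pull-ups, sit-ups, shuttle
#' time (seconds).
#'
#' @param cohort a cohort data.frame.
#' @return numeric matrix with columns `run_3000m`, `pull_ups`, `sit_ups`,
#'   `shuttle`.
#' @export
metric_summaries <- function(cohort) {
  x <- compact_features(cohort)
  cbind(
    run_3000m = rowSums(x[, 1:15, drop = FALSE]),
    pull_ups = x[, "pull_ups"],
    sit_ups = x[, "sit_ups"],
    shuttle = x[, "shuttle_s"]
  )
}

#' Write / read a cohort as CSV with a JSON provenance sidecar
#'
#' The CSV holds one row per subject (`subject_id,lap_01..lap_15,pull_ups,
#' sit_ups,shuttle_s,bmi,category`), UTF-8, dot decimal. `write_cohort` also
#' writes `<path>.json` recording the generating [cohort_spec()] when one is
#' supplied.
#'
#' @param cohort cohort data.frame.
#' @param path CSV file path.
#' @param spec optional [cohort_spec()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, spec = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(spec)) {
    side <- unclass(spec)
    side$metric_effects <- as.data.frame(side$metric_effects)
    jsonlite::write_json(side, paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  d$category <- factor(d$category, levels = bmi_levels(), ordered = TRUE)
  d
}
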