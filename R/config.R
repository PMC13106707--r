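default_run_config <- function() {
  list(
    cohort = list(
      n = 500L,
      proportions = c(0.053, 0.745, 0.190, 0.012),
      seed = 42L
    ),
    smote = list(k = 5L),
    noise = list(sigma = 0.1),
    cv = list(folds = 5L, seed = 42L),
    extractor = list(
      conv_filters = c(64L, 128L, 256L), kernel = 5L, stride = 2L, heads = 8L,
      attn_dropout = 0.3, lambda_attn = 0.1,
      metric_weights = c(0.4, 0.2, 0.2, 0.2),
      lr = 0.001, beta1 = 0.9, beta2 = 0.999, weight_decay = 1e-4,
      hidden_noise = 0.05, patience = 10L, max_epochs = 30L,
      batch_size = 64L, loss_mode = "per_metric"
    ),
    gbm = list(
      nrounds = 200L, learning_rate = 0.1, max_leaves = 31L,
      min_child_weight = 1, lambda1 = 1.2, lambda2 = 0.8,
      multiclass = "softmax"
    ),
    prescription = list(
      load_factor = 1.2, improve_threshold = 0.02, increment = 0.075,
      deload_fraction = 0.175, deload_days = 4, frbi_threshold = 1.2,
      reassess_weeks = 2
    ),
    run = list(seed = 42L, out_dir = "fitrx_run", verbosity = 1L)
  )
}

merge_config <- function(defaults, raw, path = character(0)) {
  if (!is.list(raw)) {
    stop("config section '", paste(path, collapse = "."), "' must be a mapping",
      call. = FALSE
    )
  }
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop(
      "unknown config key(s): ",
      paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "),
      call. = FALSE
    )
  }
  for (nm in names(raw)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], raw[[nm]], c(path, nm))
    } else {
      v <- raw[[nm]]
      if (length(v) == length(defaults[[nm]]) || length(defaults[[nm]]) == 0) {
        defaults[[nm]] <- v
      } else if (length(defaults[[nm]]) == 1L && length(v) == 1L) {
        defaults[[nm]] <- v
      } else {
        stop("config key '", paste(c(path, nm), collapse = "."), "' has length ",
          length(v), ", expected ", length(defaults[[nm]]),
          call. = FALSE
        )
      }
    }
  }
  defaults
}

#' Validate a run configuration
#'
#' Merges a (possibly partial) raw mapping into the full default
#' configuration -- whose values are the framework's stated
#' hyperparameters (Adam lr 0.001 with beta 0.9/0.999, patience 10, SMOTE
#' k = 5, noise sigma = 0.1, attention-penalty lambda 0.1, metric weights
#' 0.4/0.2/0.2/0.2, boosting lambda1 = 1.2 / lambda2 = 0.8) -- rejecting
#' unknown keys and out-of-range values with path-qualified messages.
#'
#' @param raw named list (e.g. parsed from JSON/YAML); empty gives the full
#'   default configuration.
#' @return object of class `fitrx_config`.
#' @export
validate_config <- function(raw = list()) {
  cfg <- merge_config(default_run_config(), raw)
  fail <- function(key, msg) {
    stop("config `", key, "`: ", msg, call. = FALSE)
  }
  if (cfg$smote$k < 1) fail("smote.k", "must be >= 1")
  if (cfg$noise$sigma < 0) fail("noise.sigma", "must be >= 0")
  if (cfg$cv$folds < 2) fail("cv.folds", "must be >= 2")
  if (abs(sum(cfg$extractor$metric_weights) - 1) > 1e-9) {
    fail("extractor.metric_weights", "must sum to 1")
  }
  if (cfg$extractor$lr <= 0) fail("extractor.lr", "must be > 0")
  for (k in c("attn_dropout", "beta1", "beta2")) {
    if (cfg$extractor[[k]] < 0 || cfg$extractor[[k]] > 1) {
      fail(paste0("extractor.", k), "must lie in [0, 1]")
    }
  }
  if (cfg$extractor$lambda_attn < 0) fail("extractor.lambda_attn", "must be >= 0")
  if (cfg$gbm$lambda1 < 0 || cfg$gbm$lambda2 < 0) {
    fail("gbm.lambda1/lambda2", "must be >= 0")
  }
  if (any(cfg$cohort$proportions < 0) ||
    abs(sum(cfg$cohort$proportions) - 1) > 1e-9) {
    fail("cohort.proportions", "must be non-negative and sum to 1")
  }
  if (cfg$prescription$frbi_threshold <= 0) fail("prescription.frbi_threshold", "must be > 0")
  structure(cfg, class = "fitrx_config")
}

#' Serialize a configuration to JSON
#'
#' Round-trip stable: `validate_config(parse(serialize(cfg)))` serializes
#' identically.
#'
#' @param config a `fitrx_config`.
#' @param path optional file path.
#' @export
config_to_json <- function(config, path = NULL) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    invisible(path)
  } else {
    txt
  }
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline end to end
#'
#' Executes simulate -> fold planning -> augmentation -> extractor training
#' -> boosted classification -> cross-validated evaluation -> prescription
#' for every subject the model flags as overweight/obese, writing all
#' artifacts and a run manifest (config hash, seeds, input hashes, stage
#' timings) to the output directory. Each stage is also individually
#' invokable through the exported functions it wraps.
#'
#' @param config a [validate_config()] result (or raw list passed through
#'   it).
#' @param out_dir output directory (default from the config).
#' @return the run manifest, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = validate_config(), out_dir = NULL) {
  if (!inherits(config, "fitrx_config")) config <- validate_config(config)
  if (is.null(out_dir)) {
    out_dir <- file.path(config$run$out_dir, substr(config_hash(config), 1, 8))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("fitrx")),
    config_hash = config_hash(config),
    seed = config$run$seed,
    stages = list()
  )
  say <- function(...) if (config$run$verbosity > 0) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(proc.time()[["elapsed"]] - t0, 3)
    )
    say("stage %-12s done (%.1fs)", name, manifest$stages[[name]]$seconds)
    res
  }

  cohort <- stage("simulate", {
    spec <- cohort_spec(config$cohort$n,
      class_proportions = config$cohort$proportions,
      seed = config$cohort$seed
    )
    co <- generate_cohort(spec)
    write_cohort(co, file.path(out_dir, "cohort.csv"), spec)
    co
  })
  manifest$input_hashes <- list(
    cohort_csv = unname(tools::md5sum(file.path(out_dir, "cohort.csv")))
  )
  folds <- stage("folds", make_folds(cohort$category, config$cv$folds, config$cv$seed))
  ec <- config$extractor
  extractor_cfg <- extractor_config(
    conv_filters = ec$conv_filters, kernel = ec$kernel, stride = ec$stride,
    heads = ec$heads, attn_dropout = ec$attn_dropout,
    lambda_attn = ec$lambda_attn, metric_weights = ec$metric_weights,
    lr = ec$lr, beta1 = ec$beta1, beta2 = ec$beta2,
    weight_decay = ec$weight_decay, hidden_noise = ec$hidden_noise,
    patience = ec$patience, max_epochs = ec$max_epochs,
    batch_size = ec$batch_size, loss_mode = ec$loss_mode,
    seed = config$run$seed
  )
  gc_cfg <- config$gbm
  gbm_cfg <- gbm_config(
    nrounds = gc_cfg$nrounds, learning_rate = gc_cfg$learning_rate,
    max_leaves = gc_cfg$max_leaves, min_child_weight = gc_cfg$min_child_weight,
    lambda1 = gc_cfg$lambda1, lambda2 = gc_cfg$lambda2,
    multiclass = gc_cfg$multiclass, seed = config$run$seed
  )
  metrics <- stage("evaluate", {
    m <- evaluate_cv(cohort, folds, extractor_cfg, gbm_cfg,
      smote_k = config$smote$k, noise_sigma = config$noise$sigma,
      seed = config$run$seed
    )
    write_metrics_report(m,
      json_path = file.path(out_dir, "report.json"),
      confusion_csv_path = file.path(out_dir, "confusion.csv")
    )
    m
  })
  stage("prescribe", {
    # final model on the full cohort for prescription generation
    x <- compact_features(cohort)
    std <- standardize(x)
    ext <- fit_extractor(tensorize(std$x), cohort$category, config = extractor_cfg)
    gbm <- fit_gbm(predict(ext, tensorize(std$x)), cohort$category, gbm_cfg)
    ms <- metric_summaries(cohort)
    f <- metric_margin_fn(ext, gbm, std$stats, ms)
    pred <- predict(gbm, predict(ext, tensorize(std$x)), type = "class")
    flagged <- which(as.character(pred) %in% c("overweight", "obese"))
    flagged <- utils::head(flagged, 5L) # a handful of worked examples
    plans <- lapply(flagged, function(i) {
      sh <- f(ms[i, ])
      plan <- map_prescription(rank_deficiencies(sh),
        load_factor = config$prescription$load_factor
      )
      plan_to_json(plan, file.path(out_dir, sprintf("plan_%s.json", cohort$subject_id[i])))
      plan
    })
    plans
  })
  manifest$pooled_metrics <- metrics$pooled[c("accuracy", "macro_f1", "macro_auc")]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}

#' Build a metric-level attribution function for a fitted pipeline
#'
#' Returns a closure suitable for [metric_shap()]: it maps the four metric
#' summaries of one subject to the model's log-odds margin of that
#' subject's predicted class, by reconstructing a flat-pace lap profile
#' consistent with the 3,000 m total, standardizing with the training
#' statistics, and running the extractor + boosted classifier.
#'
#' @param extractor a fitted `fitrx_extractor`.
#' @param gbm a fitted `fitrx_gbm` (softmax objective).
#' @param stats standardization statistics of the training data.
#' @param background_metrics metric-summary matrix used to fix the
#'   predicted class of the explained subject.
#' @return function: given a 4-vector (or N x 4 matrix) of metric
#'   summaries, applied to one explained subject, returns a `fitrx_shap`
#'   (for a vector) or the margin values (for a matrix, used internally).
#' @export
metric_margin_fn <- function(extractor, gbm, stats, background_metrics) {
  margins <- function(m4) {
    m4 <- matrix(m4, ncol = 4)
    compact <- cbind(
      matrix(m4[, 1] / 15, nrow(m4), 15), # flat-pace laps from the total
      m4[, 2], m4[, 3], m4[, 4]
    )
    z <- predict(extractor, tensorize(standardize(compact, stats)$x))
    predict(gbm, z, type = "margin")
  }
  function(x) {
    x <- as.numeric(x)
    # fix the explained class from the subject's own prediction
    ci <- which.max(margins(x)[1, ])
    sh <- metric_shap(function(m) margins(m)[, ci], x, background_metrics)
    sh$predicted_class <- gbm$levels[ci]
    sh
  }
}
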