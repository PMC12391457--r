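#' Default run configuration
#'
#' Materializes every pipeline default: cohort structure, effect sizes,
#' preprocessing, the model registry, and audit settings. One global seed
#' governs the run; each stage derives its own stream via
#' [derive_seed()] so inserting a stage never shifts the randomness of
#' the stages downstream.
#'
#' @return A named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    cohort = list(n_total = 251L, n_pd = 99L),
    effects = list(),
    split = list(train_fraction = 0.7),
    smote = list(k = 5L, enabled = TRUE),
    race_upsample = list(ratio = 1.0, enabled = TRUE),
    resample_scope = "train",
    include_demographics = TRUE,
    include_memory = TRUE,
    band_halfwidth = 15,
    models = model_registry(),
    top_k = 3L,
    threshold = 0.5,
    audit = list(B = 100L, alpha = 0.05, eodds_convention = "absolute"),
    write_sessions = TRUE
  )
}

#' Validate a run configuration file
#'
#' Reads a YAML configuration, rejects unknown keys (no silent typos),
#' range-checks the values and fills in every default; an empty file
#' yields the all-defaults configuration. The materialized configuration
#' re-validates to itself.
#'
#' @param path YAML file path, or `NULL`/a list for in-memory use.
#' @return The validated configuration list.
#' @export
validate_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
          else if (is.list(path)) path
          else {
            if (!file.exists(path)) stop("config file not found: ", path,
                                         call. = FALSE)
            yaml::read_yaml(path) %||% list()
          }
  def <- default_run_config()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(def, user)
  for (nested in c("cohort", "split", "smote", "race_upsample", "audit"))
    if (!is.list(cfg[[nested]]))
      stop(nested, " must be a mapping", call. = FALSE)
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    stop("config requires an integer seed", call. = FALSE)
  if (cfg$split$train_fraction <= 0 || cfg$split$train_fraction >= 1)
    stop("split.train_fraction must lie in (0, 1)", call. = FALSE)
  if (cfg$smote$k < 1) stop("smote.k must be >= 1", call. = FALSE)
  if (cfg$race_upsample$ratio < 0)
    stop("race_upsample.ratio must be >= 0", call. = FALSE)
  if (!cfg$resample_scope %in% c("train", "all"))
    stop("resample_scope must be 'train' or 'all'", call. = FALSE)
  bad <- setdiff(cfg$models, model_registry())
  if (length(bad))
    stop("unknown models: ", paste(bad, collapse = ", "), call. = FALSE)
  if (cfg$audit$B < 1) stop("audit.B must be >= 1", call. = FALSE)
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full simulate-extract-resample-train-audit pipeline
#'
#' Executes every stage under one global seed, writes the stage outputs
#' (`cohort.csv`, `sessions.jsonl`, `features.csv`, per-model
#' `preds_*.csv` and `report_*.json`/`.md`) into `out_dir`, and returns a
#' manifest with the configuration snapshot and an MD5 digest of every
#' output file. Any stage failure aborts with the stage named.
#'
#' @param config A configuration list (see [validate_run_config()]), a
#'   YAML path, or `NULL` for all defaults.
#' @param out_dir Output directory, created if needed.
#' @return The run manifest (also written as `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("motorfair_run_")) {
  cfg <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  outputs <- character(0)
  log_line <- function(stage, ...)
    message(sprintf("[%s] %s", stage, paste0(...)))

  cohort <- run_stage("cohort", {
    cc <- do.call(cohort_config, c(cfg$cohort, list(seed = seed)))
    generate_cohort(cc)
  })
  p <- file.path(out_dir, "cohort.csv"); write_cohort(cohort, p)
  outputs <- c(outputs, p)
  log_line("cohort", nrow(cohort), " participants, ",
           sum(cohort$label == "PD"), " PD")

  effects <- run_stage("effects", do.call(effect_config, cfg$effects))
  sessions <- run_stage("simulate",
    simulate_cohort_sessions(cohort, effects,
                             seed = derive_seed(seed, "simulate")))
  if (isTRUE(cfg$write_sessions)) {
    p <- file.path(out_dir, "sessions.jsonl"); write_sessions(sessions, p)
    outputs <- c(outputs, p)
  }
  log_line("simulate", length(sessions), " sessions")

  features <- run_stage("extract", {
    fm <- extract_feature_matrix(sessions, cohort,
                                 include_demographics = cfg$include_demographics,
                                 include_memory = cfg$include_memory,
                                 band_halfwidth = cfg$band_halfwidth)
    fm$label <- cohort$label[match(fm$participant_id, cohort$id)]
    fm
  })
  p <- file.path(out_dir, "features.csv"); write_feature_matrix(features, p)
  outputs <- c(outputs, p)
  log_line("extract", ncol(features) - 2L, " features x ", nrow(features),
           " rows")

  prep <- run_stage("resample", {
    if (cfg$resample_scope == "all") {
      full <- features
      if (cfg$race_upsample$enabled)
        full <- race_upsample(full, cfg$race_upsample$ratio,
                              seed = derive_seed(seed, "race"))
      sp <- split_train_test(full, cfg$split$train_fraction, seed = seed)
      sc <- fit_transform(sp$train, sp$test)
      tr <- sc$train
      if (cfg$smote$enabled)
        tr <- smote_upsample(tr, cfg$smote$k,
                             seed = derive_seed(seed, "smote"))
      list(train = tr, test = sc$test)
    } else {
      sp <- split_train_test(features, cfg$split$train_fraction, seed = seed)
      tr <- sp$train
      if (cfg$race_upsample$enabled)
        tr <- race_upsample(tr, cfg$race_upsample$ratio,
                            seed = derive_seed(seed, "race"))
      sc <- fit_transform(tr, sp$test)
      tr <- sc$train
      if (cfg$smote$enabled)
        tr <- smote_upsample(tr, cfg$smote$k,
                             seed = derive_seed(seed, "smote"))
      imp <- impute_features(tr, sc$test)
      list(train = imp$train, test = imp$test)
    }
  })
  log_line("resample", nrow(prep$train), " train rows (",
           sum(prep$train$label == "PD"), " PD) / ", nrow(prep$test),
           " test rows")

  specs <- lapply(cfg$models, model_spec, seed = derive_seed(seed, "fit"))
  cv <- run_stage("cross_validate",
    cross_validate(prep$train, specs, seed = seed,
                   threshold = cfg$threshold))
  top <- run_stage("select", select_top(cv, cfg$top_k))
  log_line("select", "top models: ",
           paste(vapply(top, `[[`, character(1), "model_id"),
                 collapse = ", "))

  reports <- list()
  for (spec in top) {
    preds <- run_stage(paste0("predict/", spec$model_id),
      fit_predict(spec, prep$train, prep$test, cohort,
                  threshold = cfg$threshold))
    p <- file.path(out_dir, paste0("preds_", spec$model_id, ".csv"))
    write_predictions(preds, p); outputs <- c(outputs, p)
    rep <- run_stage(paste0("audit/", spec$model_id),
      fairness_report(preds, B = cfg$audit$B,
                      seed = derive_seed(seed, "audit"),
                      alpha = cfg$audit$alpha,
                      eodds_convention = cfg$audit$eodds_convention))
    pj <- file.path(out_dir, paste0("report_", spec$model_id, ".json"))
    pm <- file.path(out_dir, paste0("report_", spec$model_id, ".md"))
    write_fairness_report(rep, pj, pm)
    outputs <- c(outputs, pj, pm)
    reports[[spec$model_id]] <- rep
  }

  manifest <- list(
    config = cfg,
    cv = lapply(cv, function(r) r[c("model_id", "mean_f1", "sd_f1",
                                    "mean_auroc", "sd_auroc")]),
    top_models = vapply(top, `[[`, character(1), "model_id"),
    digests = as.list(tools::md5sum(outputs)),
    versions = list(motorfair = as.character(utils::packageVersion("motorfair")),
                    r = as.character(getRversion())),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(c(manifest, list(reports = reports, out_dir = out_dir)))
}
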