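# Shared simulation-audit runs. Calibration experiments (null-configuration
# false-positive rates, bias injection/recovery) reuse out-of-fold
# random-forest prediction tables over the default 251-participant cohort;
# runs are memoized so several test files can share the same draws.

.run_cache <- new.env(parent = emptyenv())

audit_cohort <- function() generate_cohort(cohort_config())

# out-of-fold RF prediction table for one simulated cohort under `effects`;
# ntree trimmed for the calibration experiments (hundreds of runs)
audit_run <- function(seed, effects, tag) {
  key <- paste0(tag, "/", seed)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  cohort <- audit_cohort()
  sessions <- simulate_cohort_sessions(cohort, effects, seed = seed)
  features <- extract_feature_matrix(sessions, cohort)
  features$label <- cohort$label[match(features$participant_id, cohort$id)]
  spec <- model_spec("random_forest", list(ntree = 100),
                     seed = derive_seed(seed, "fit"))
  preds <- cv_predict(features, spec, cohort, seed = seed)
  .run_cache[[key]] <- preds
  preds
}

null_run <- function(seed) audit_run(seed, null_effects(), "null")

# device effect masking the PD motor signal on Windows; the PD effect is
# raised so the unsuppressed groups are classified cleanly and the audit
# measures the injected masking, not classifier weakness
suppressed_windows_effects <- function() {
  effect_config(pd_deviation_scale = 2.5, pd_time_scale = 1.5,
                pd_tremor_amp = 8,
                device_pd_attenuation = c(Windows = 0.05, Mac = 1, Linux = 1),
                device_latency_ms = c(Windows = 0, Mac = 0, Linux = 0))
}

injected_run <- function(seed) {
  audit_run(seed, suppressed_windows_effects(), "injected")
}

# one default-effects pipeline run shared by the performance sanity checks
default_run <- function() {
  if (is.null(.run_cache[["default"]])) {
    .run_cache[["default"]] <- audit_run(20260901, effect_config(), "default")
  }
  .run_cache[["default"]]
}

di_bootstrap_ci <- function(preds, B = 100, seed = 1) {
  boot <- bootstrap_group_metrics(preds, "device", B = B, seed = seed)
  di <- boot$replicates$di
  di <- di[!is.na(di)]
  stats::quantile(di, c(0.025, 0.975), names = FALSE)
}
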