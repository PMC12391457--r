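#!/usr/bin/env Rscript
# Stage 5: group-balanced bootstrap fairness audit (100 replicates) of each
# selected model across sex, race, device type and dominant hand, plus
# global and stratified (device, handedness) feature importance.
# The audit reads only prediction tables; feature files matter solely for
# the importance analysis, which by design runs without race upsampling.

suppressPackageStartupMessages(library(motorfair))
seed <- 1L

cohort <- read_cohort("results/cohort.csv")
pred_files <- list.files("results", "^preds_.*\\.csv$", full.names = TRUE)

for (pf in pred_files) {
  model <- sub("^preds_(.*)\\.csv$", "\\1", basename(pf))
  preds <- read_predictions(pf)
  rep <- fairness_report(preds, B = 100,
                         seed = derive_seed(seed, "audit"))
  write_fairness_report(rep, sprintf("results/report_%s.json", model),
                        sprintf("results/report_%s.md", model))
  cat("==", model, "==\n")
  for (a in names(rep$attributes)) {
    s <- rep$attributes[[a]]$summary
    g <- function(m) s$mean[s$metric == m]
    gs <- function(m) s$sd[s$metric == m]
    cat(sprintf("  %-6s DI %.2f (%.2f)  EO %.2f (%.2f)  EOdds %.2f (%.2f)\n",
                a, g("di"), gs("di"), g("eo"), gs("eo"),
                g("eodds"), gs("eodds")))
  }
}

# stratified importance: refit on subgroup rows, without race upsampling
features <- read_feature_matrix("results/features.csv")
strata <- list(global = rep(TRUE, nrow(features)),
               right_handed = features$hand == "right",
               left_handed = features$hand == "left",
               mac = features$device == "Mac",
               windows = features$device == "Windows")
imp <- do.call(rbind, lapply(names(strata), function(nm) {
  top <- stratified_importance(features, subset = strata[[nm]],
                               seed = seed, k = 10)
  data.frame(stratum = nm, rank = seq_len(nrow(top)), top)
}))
write.csv(imp, "results/stratified_importance.csv", row.names = FALSE)
cat("\ntop-5 global features by impurity importance:\n")
print(head(imp[imp$stratum == "global", c("rank", "feature", "importance")],
           5), row.names = FALSE, digits = 2)
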