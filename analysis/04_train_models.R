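#!/usr/bin/env Rscript
# Stage 4: 5-fold cross-validation of the six-classifier registry on the
# training partition, selection of the top three by mean F1, and held-out
# prediction tables for the selected models.

suppressPackageStartupMessages(library(motorfair))
seed <- 1L

train <- read_feature_matrix("results/train_preprocessed.csv")
test <- read_feature_matrix("results/test_preprocessed.csv")
cohort <- read_cohort("results/cohort.csv")

specs <- lapply(model_registry(), model_spec,
                seed = derive_seed(seed, "fit"))
cv <- suppressWarnings(cross_validate(train, specs, seed = seed))

cv_table <- do.call(rbind, lapply(cv, function(r)
  data.frame(model = r$model_id, mean_f1 = r$mean_f1, sd_f1 = r$sd_f1,
             mean_auroc = r$mean_auroc, sd_auroc = r$sd_auroc)))
cv_table <- cv_table[order(-cv_table$mean_f1), ]
write.csv(cv_table, "results/cv_results.csv", row.names = FALSE)
cat("cross-validation (train only):\n")
print(cv_table, row.names = FALSE, digits = 3)

top <- select_top(cv, 3)
cat("top 3 by mean F1:",
    paste(vapply(top, `[[`, character(1), "model_id"), collapse = ", "),
    "\n")

held <- lapply(top, function(spec) {
  preds <- suppressWarnings(fit_predict(spec, train, test, cohort))
  write_predictions(preds,
                    sprintf("results/preds_%s.csv", spec$model_id))
  m <- performance_metrics(confusion_counts(preds))
  data.frame(model = spec$model_id,
             accuracy = m$accuracy, f1 = m$f1, auroc = auroc(preds$score,
                                                             preds$label),
             sensitivity = m$recall, specificity = m$specificity)
})
held <- do.call(rbind, held)
write.csv(held, "results/heldout_metrics.csv", row.names = FALSE)
cat("held-out (30%) performance:\n")
print(held, row.names = FALSE, digits = 3)
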