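#!/usr/bin/env Rscript
# Stage 3: stratified 70/30 split, Non-White non-PD random upsampling,
# min-max scaling + one-hot encoding fitted on the training partition,
# and SMOTE class balancing of the training rows (Linux excluded).
# The before/after group counts logged here are the per-stage
# data-distribution snapshots of the run.

suppressPackageStartupMessages(library(motorfair))
seed <- 1L

features <- read_feature_matrix("results/features.csv")
sp <- split_train_test(features, 0.7, seed = seed)
cat("split:", nrow(sp$train), "train /", nrow(sp$test), "test\n")

count_block <- function(df, tag) {
  cat(sprintf("[%s] PD %d / non-PD %d | Non-White non-PD %d | Linux %d\n",
              tag, sum(df$label == "PD"), sum(df$label == "non-PD"),
              sum(df$race_binary == "Non-White" & df$label == "non-PD"),
              sum(df$device == "Linux")))
}
count_block(sp$train, "train before resampling")

train <- race_upsample(sp$train, ratio = 1.0,
                       seed = derive_seed(seed, "race"))
count_block(train, "after race upsampling")

sc <- fit_transform(train, sp$test)
train <- smote_upsample(sc$train, k = 5, seed = derive_seed(seed, "smote"))
cat(sprintf("[after SMOTE] PD %d / non-PD %d (classes balanced)\n",
            sum(train$label == "PD"), sum(train$label == "non-PD")))

write_feature_matrix(train, "results/train_preprocessed.csv")
write_feature_matrix(sc$test, "results/test_preprocessed.csv")
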