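#!/usr/bin/env Rscript
# Stage 2: extract the 79-feature matrix from the simulated sessions.
# Sessions are regenerated deterministically from the stage-1 seed.

suppressPackageStartupMessages(library(motorfair))
seed <- 1L

cohort <- read_cohort("results/cohort.csv")
sessions <- simulate_cohort_sessions(cohort, effect_config(),
                                     seed = derive_seed(seed, "simulate"))
features <- extract_feature_matrix(sessions, cohort)
features$label <- cohort$label[match(features$participant_id, cohort$id)]
write_feature_matrix(features, "results/features.csv")
write_feature_registry("results/feature_registry_v1.csv")

cat("feature matrix:", nrow(features), "rows x",
    ncol(features) - 2L, "features\n")
cat("missing values:", sum(is.na(features)), "\n")
cat("example row (motor deviation features, participant",
    features$participant_id[1], "):\n")
print(round(unlist(features[1, c("total_deviation_straight_line",
                                 "net_deviation_straight_line",
                                 "maximum_deviation_straight_line",
                                 "time_to_trace_a_spiral")]), 3))
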