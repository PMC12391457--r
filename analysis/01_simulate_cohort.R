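#!/usr/bin/env Rscript
# Stage 1: generate the demographically structured cohort and simulate one
# assessment session per participant.
#
# The cohort reproduces the study's margins exactly (251 participants,
# 99 PD / 152 controls, 212 M / 39 F, 202/41/8 Windows/Mac/Linux,
# 176 right / 75 left, race-by-status joint as published). Sessions are
# written as JSON-lines only when WRITE_SESSIONS=1 (the file is ~20 MB);
# downstream stages regenerate sessions deterministically from the seed,
# so the file is a convenience, not a dependency.

suppressPackageStartupMessages(library(motorfair))
seed <- 1L
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(cohort_config(seed = seed))
write_cohort(cohort, "results/cohort.csv")

cat("cohort: ", nrow(cohort), " participants; ",
    sum(cohort$label == "PD"), " PD (",
    round(100 * mean(cohort$label == "PD"), 1), "%), ",
    sum(cohort$label == "non-PD"), " controls\n", sep = "")
print(table(cohort$device, cohort$label))
print(table(cohort$race_binary, cohort$label))

sessions <- simulate_cohort_sessions(cohort, effect_config(),
                                     seed = derive_seed(seed, "simulate"))
cat("simulated", length(sessions), "sessions",
    "(9 traces + 9 key tasks + click + memory each)\n")
if (nzchar(Sys.getenv("WRITE_SESSIONS"))) {
  write_sessions(sessions, "results/sessions.jsonl")
  cat("wrote results/sessions.jsonl\n")
}
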