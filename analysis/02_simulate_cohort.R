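#!/usr/bin/env Rscript
# Generate the synthetic behavioural cohort used by the downstream
# analyses: observers drawn from the causal-inference model across the full
# session structure (28 conditions x 28 trials + catch trials).
#
# The cohort here is kept at 8 participants so the full workflow reruns in
# a few minutes; generate_cohort() scales to the study's 28.

library(avrabbit)

seed <- 20240917
n_participants <- 8

dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(n_participants = n_participants,
                    trials_per_condition = 28, variant = "BCI", seed = seed)
cohort <- generate_cohort(spec)

cat("Simulated", length(unique(cohort$trials$participant_id)),
    "participants,", nrow(cohort$trials), "trials (",
    sum(cohort$trials$is_catch), "catch )\n")

write_trials(cohort$trials, "results/synthetic_trials.tsv",
             header = paste0("synthetic cohort; master_seed=", seed))
write_ground_truth(cohort$ground_truth, "results/ground_truth.tsv",
                   seed = seed)
cat("Wrote results/synthetic_trials.tsv and results/ground_truth.tsv\n")
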