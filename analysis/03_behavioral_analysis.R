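#!/usr/bin/env Rscript
# Behavioural illusion-rate analysis: score trials, pool mirror directions
# into the ten analysis conditions, screen participants on control-condition
# rates, and run the paired condition contrasts (Shapiro-Wilk gate ->
# Wilcoxon signed-rank or paired t, Bonferroni-corrected).

library(avrabbit)

design <- build_design()
trials <- read_trials("results/synthetic_trials.tsv", design)

rates <- illusion_rates(trials, design)
pooled <- pool_directions(rates, design)
write.table(pooled, "results/illusion_rates_pooled.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Group mean illusion rates by analysis condition:\n")
print(round(tapply(pooled$rate, pooled$analysis_condition, mean), 3))

scr <- screen_participants(pooled)
cat("\nParticipant screening: kept", length(scr$kept), "excluded",
    length(scr$excluded),
    sprintf("(threshold %.3f)\n", scr$threshold))
pooled <- pooled[pooled$participant_id %in% scr$kept, ]

contrasts <- condition_contrasts(pooled)
write.table(contrasts, "results/condition_contrasts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nCondition contrasts (Bonferroni over",
    nrow(contrasts), "pairs):\n")
print(cbind(contrasts[, c("condition_a", "condition_b", "test_name")],
            round(contrasts[, c("statistic", "z", "p_raw",
                                "p_bonferroni")], 4)))
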