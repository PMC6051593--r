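#!/usr/bin/env Rscript

# Step 2 -- synthetic cohort.
# Simulates 21 synthetic observers through the training protocol on all
# three levels (3-5 sessions of five 56-trial blocks per level, i.e.
# 840-1400 trials per level), with per-observer matching-vs-maximization
# blends drawn uniformly. The presentation sets are regenerated
# deterministically from the same seeds as step 1. Writes:
#   results/logs/agent_NN.csv   one trial log per observer
#   results/manifest.csv        observer id, blend, seeds, session counts

library(seqstrat)

seed <- 2026L
dir.create("results/logs", showWarnings = FALSE, recursive = TRUE)

seqsets <- lapply(0:2, function(level) {
  model <- build_model(level)
  set.seed(seed + level)
  select_sequences(model)
})
names(seqsets) <- paste0("level", 0:2)

cohort <- simulate_cohort(seqsets, n_agents = 21L, master_seed = seed)
for (a in seq_along(cohort$logs)) {
  write_trial_log(cohort$logs[[a]], sprintf("results/logs/agent_%02d.csv", a))
}
write.csv(cohort$manifest, "results/manifest.csv", row.names = FALSE)

cat(sprintf("simulated %d observers; trials per observer per level: %d-%d\n",
            length(cohort$logs), min(cohort$manifest$n_trials),
            max(cohort$manifest$n_trials)))
cat(sprintf("observer blends (lambda) span %.2f-%.2f\n",
            min(cohort$manifest$lambda), max(cohort$manifest$lambda)))
cat("wrote results/logs/ and results/manifest.csv\n")
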