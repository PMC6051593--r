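#!/usr/bin/env Rscript

# Step 3 -- performance scoring.
# Reads the cohort trial logs and scores each observer per 56-trial block:
# min-overlap performance index (PI), analytic chance baseline per level,
# and normalized PI = PI - PI_rand. Reports how many observers end training
# above the 0.70 criterion. Writes results/scores.csv.

library(seqstrat)

models <- lapply(0:2, build_model)
names(models) <- as.character(0:2)

log_files <- sort(Sys.glob("results/logs/agent_*.csv"))
stopifnot(length(log_files) > 0)

rows <- list()
for (f in log_files) {
  log <- read_trial_log(f)
  agent <- as.integer(sub(".*agent_(\\d+)\\.csv", "\\1", f))
  for (lv in unique(log$level)) {
    rep <- score_session(log[log$level == lv, ], models[[as.character(lv)]])
    blk <- rep$blocks
    blk$agent_id <- agent
    blk$level <- lv
    rows[[length(rows) + 1]] <- blk
  }
}
scores <- do.call(rbind, rows)
scores <- scores[, c("agent_id", "level", "session_id", "block_id",
                     "n_used", "n_null", "n_dropped", "pi", "pi_rand",
                     "pi_normalized")]
write.csv(scores, "results/scores.csv", row.names = FALSE)

final_session <- aggregate(pi ~ agent_id + level,
                           data = scores[ave(scores$session_id,
                                             scores$agent_id, scores$level,
                                             FUN = max) == scores$session_id, ],
                           FUN = mean)
cat("mean final-session PI by level:\n")
print(aggregate(pi ~ level, final_session, mean))
cat(sprintf("observers above the 0.70 training criterion at their final session: %d/%d (level-averaged)\n",
            sum(tapply(final_session$pi, final_session$agent_id, mean) > 0.70),
            length(unique(final_session$agent_id))))
cat("wrote results/scores.csv\n")
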