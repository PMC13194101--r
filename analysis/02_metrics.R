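#!/usr/bin/env Rscript
# Extract the six navigation metrics from the raw trajectories written by
# 01_simulate.R, aggregate to participant level, inject the single missing
# path-distance-ratio value, and tabulate group-by-stage summaries.
#
# Usage: Rscript analysis/02_metrics.R [seed]

library(vmnav)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

config <- read_arena_config("results/arena_config.yaml")
traj <- read_trajectories("results/trajectories.csv", config)
cohort <- read_cohort("results/cohort.csv")

metrics <- compute_metrics(traj, config)
summ <- summarize_participants(metrics, cohort, config)
summ <- inject_missingness(summ, seed = derive_seed(seed, 3L))

utils::write.csv(metrics, "results/trial_metrics.csv", row.names = FALSE)
utils::write.csv(summ, "results/participant_summaries.csv", row.names = FALSE)
gs <- group_summary(summ)
utils::write.csv(gs, "results/group_summary.csv", row.names = FALSE)

cat("global group means (mean +- SE):\n")
g <- gs[gs$level == "global", ]
for (v in unique(g$variable)) {
  hc <- g[g$variable == v & g$group == "HC", ]
  am <- g[g$variable == v & g$group == "aMCI", ]
  cat(sprintf("  %-24s HC %7.2f +- %5.2f   aMCI %7.2f +- %5.2f\n",
              v, hc$mean, hc$se, am$mean, am$se))
}
cat(sprintf("censored trials: %.1f%%\n", 100 * mean(metrics$latency_censored)))
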