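#!/usr/bin/env Rscript
# Simulate the study cohort: 20 healthy-control-like and 18 aMCI-like virtual
# participants, each completing 3 stages x 7 trials of the virtual water
# maze, using the shipped calibrated simulator parameters. Writes the raw
# trajectory log and the cohort metadata under results/.
#
# Usage: Rscript analysis/01_simulate.R [seed]

library(vmnav)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

params <- default_simulator_params()
config <- arena_config()
co <- simulate_cohort(params, config, n_hc = 20, n_amci = 18, seed = seed)

write_trajectories(co$trajectories, "results/trajectories.csv")
write_cohort(co$cohort, "results/cohort.csv")
utils::write.csv(co$truth, "results/latent_truth.csv", row.names = FALSE)
write_arena_config(config, "results/arena_config.yaml")
write_simulator_params(params, "results/simulator_params.yaml")

cat(sprintf("seed %d: %d participants, %d trajectory samples\n",
            seed, nrow(co$cohort), nrow(co$trajectories)))
cat(sprintf("group counts: HC = %d, aMCI = %d\n",
            sum(co$cohort$group == "HC"), sum(co$cohort$group == "aMCI")))
cat(sprintf("MoCA means: HC %.1f, aMCI %.1f\n",
            mean(co$cohort$moca[co$cohort$group == "HC"]),
            mean(co$cohort$moca[co$cohort$group == "aMCI"])))
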