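#!/usr/bin/env Rscript
# Step 1: simulate the synthetic bi-ethnic cohort and persist it, together
# with the generative ground truth, under results/.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(metsadd))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

cfg <- sim_config(seed = seed)
cohort <- simulate_cohort(cfg)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")
jsonlite::write_json(ground_truth(cfg), "results/ground_truth.json",
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d participants (%d visits), seed %d\n",
            nrow(cohort$participants), nrow(cohort$visits), seed))
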