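#!/usr/bin/env Rscript
# Stage 1 — simulate the study.
#
# Generates the default synthetic production study (9 signers x 10 sentences
# x 3 emotions x 3 sentence types = 810 videos, 90 frames each at 30 fps) as
# OpenPose-style keypoint series, and writes the video metadata and the
# generator's analytic ground truth. Keypoint JSON is not persisted here —
# stage 2 regenerates the study from the same seed, which is cheaper than
# 73k JSON files; set WRITE_FRAMES below if the raw per-frame files are
# wanted.

suppressMessages(library(browprosody))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
WRITE_FRAMES <- FALSE

cfg <- synthetic_config()
study <- generate_study(cfg, seed = seed, level = "keypoints",
                        dir = if (WRITE_FRAMES) "results/frames" else NULL)

cat(sprintf(
  "Simulated %d videos (%d voided on purpose), seed %d.\n",
  nrow(study$metadata), sum(study$ground_truth$voided), seed
))

write_table_atomic(study$metadata, "results/metadata.csv", seed = seed, config = cfg)
write_table_atomic(study$ground_truth, "results/ground_truth.csv", seed = seed, config = cfg)
cat("Wrote results/metadata.csv and results/ground_truth.csv\n")
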