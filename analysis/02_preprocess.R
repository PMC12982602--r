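#!/usr/bin/env Rscript
# Stage 2 — pre-process the LAI cube.
#
# Marks fill values invalid and applies the Savitzky-Golay filter to every
# pixel's yearly 46-composite series (default window 3 with clamped quadratic
# order — a deliberately light touch that preserves the series; widen the
# window in the config for stronger smoothing). Writes the smoothed cube next
# to the raw one so later stages can run stand-alone.

library(droughtlai)

seed <- as.integer(Sys.getenv("SEED", "1"))
out_dir <- "results/run_default"
cfg <- pipeline_config(list(scenario = "default", seed = seed))

run_pipeline(cfg, stages = "preprocess", out_dir = out_dir)
cat("Smoothed cube written to", file.path(out_dir, "cube_smoothed"), "\n")
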