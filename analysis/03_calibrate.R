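#!/usr/bin/env Rscript
# Stage 3 — calibrate relative thresholds and key phenological windows.
#
# For each region the baseline year is auto-selected as the weakest-impact
# year of the statistics; then the grid search scans every candidate window
# in each crop's growing season x thresholds 0..100% against the historical
# series, selecting one key window per crop (degree-pooled normalized RMSE)
# and one threshold per severity degree (min RMSE, ties by highest R). The
# two-crop region is solved by the exact joint pair search.

library(droughtlai)

seed <- as.integer(Sys.getenv("SEED", "1"))
out_dir <- "results/run_default"
cfg <- pipeline_config(list(scenario = "default", seed = seed))

res <- run_pipeline(cfg, stages = "calibrate", out_dir = out_dir)

calib <- as.data.frame(res$calib)
cat("\nCalibrated thresholds and key phenological periods:\n")
print(calib[c("region_id", "crop", "degree", "T_percent",
              "window_start_doy", "window_end_doy", "R", "RMSE",
              "baseline_year")], row.names = FALSE, digits = 4)
cat("\nThresholds decrease from drought-covered to crop-failure in every",
    "region/crop:",
    all(tapply(calib$T_percent,
               paste(calib$region_id, calib$crop),
               function(x) all(diff(x) <= 0))), "\n")
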