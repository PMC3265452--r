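#!/usr/bin/env Rscript
# Stage 1 — simulate the campaign's raw data with known ground truth.
#
# Generates (i) three checkerboard plate-uniformity plates, (ii) a
# 1280-compound antagonist screen in quadruplicate across plate pairs
# with planted true antagonists and off-target reporter inhibitors, and
# writes everything as the plate-CSV interchange format plus the truth
# table. Downstream stages read only these files.

suppressPackageStartupMessages(library(dopscreen))

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- run_config(rng_seed = 20120124)  # fixed campaign seed
noise <- assay_noise_model(well_noise_cv = cfg$noise_cv,
                           plate_effect_sd = cfg$plate_effect_sd)

cb <- make_checkerboard(noise, n_plates = 3, seed = cfg$rng_seed)
write_plate_csv(cb, file.path(out, "checkerboard_plates.csv"))
cat(sprintf("checkerboard: %d wells on %d plates\n",
            nrow(cb$wells), length(unique(cb$wells$plate_id))))

scr <- make_screen(n_compounds = 1280, noise = noise, seed = cfg$rng_seed + 1L)
write_plate_csv(scr$dataset, file.path(out, "screen_plates.csv"))
write_table(scr$truth, file.path(out, "truth.tsv"))
cat(sprintf("screen: %d wells on %d plates; planted %d antagonists, %d off-target inhibitors\n",
            nrow(scr$dataset$wells), length(unique(scr$dataset$wells$plate_id)),
            sum(scr$truth$mechanism == "true_antagonist"),
            sum(scr$truth$mechanism == "off_target_reporter_inhibitor")))
cat("wrote", out, "\n")
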