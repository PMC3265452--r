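#!/usr/bin/env Rscript
# Stage 2 — checkerboard analysis: is the assay good enough to screen?
#
# Reads the simulated checkerboard plates and computes, per plate, the
# standard Z-factor and the replicate-adjusted Z-factor assuming the
# screen's quadruplicate design. The campaign proceeded on a
# replicate-adjusted Z of about 0.5.

suppressPackageStartupMessages(library(dopscreen))

cb <- read_plate_csv(file.path("results", "data", "checkerboard_plates.csv"))
qc <- checkerboard_qc(cb, n_replicates_planned = 4)
write_table(qc$per_plate, file.path("results", "qc_per_plate.tsv"))

print(qc$per_plate)
cat(sprintf("mean replicate-adjusted Z over %d plates: %.2f (sd %.2f); mean standard Z: %.2f\n",
            nrow(qc$per_plate), qc$mean_z_replicate_adjusted,
            qc$sd_z_replicate_adjusted, qc$mean_z_standard))
if (qc$mean_z_replicate_adjusted >= 0.4) {
  cat("assay window is adequate for quadruplicate antagonist screening\n")
} else {
  cat("WARNING: assay window below the 0.4 comfort margin\n")
}
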