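#!/usr/bin/env Rscript
# Stage 3 — normalize the screen and call antagonist hits.
#
# Per plate: subtract mean background, scale to the 300 nM dopamine
# maximal-stimulation mean, express wells as percent inhibition. The hit
# threshold is the pooled antagonist-control mean minus 3 SD (the
# campaign criterion); a relaxed mean-minus-6-SD threshold is reported
# for comparison. Calls are scored against the planted truth.

suppressPackageStartupMessages(library(dopscreen))

scr <- read_plate_csv(file.path("results", "data", "screen_plates.csv"),
                      check_design = TRUE)
truth <- read_table(file.path("results", "data", "truth.tsv"))

nw <- normalize_wells(scr)
ctrl <- nw$pct_inhibition[nw$role == "antagonist_control"]
thr3 <- derive_threshold(ctrl, k_sd = 3)
thr6 <- derive_threshold(ctrl, k_sd = 6)
cat(sprintf("antagonist control: mean %.1f%%, SD %.1f%% over %d wells\n",
            thr3$control_mean, thr3$control_sd, thr3$n_control_wells))
cat(sprintf("thresholds: %.1f%% (mean-3SD), %.1f%% (mean-6SD)\n",
            thr3$threshold_pct_inhibition, thr6$threshold_pct_inhibition))

agg <- aggregate_replicates(nw)
calls3 <- call_hits(agg, thr3)
calls6 <- call_hits(agg, thr6)
write_table(calls3$hits, file.path("results", "hits_k3.tsv"))
write_table(calls6$hits, file.path("results", "hits_k6.tsv"))
cat(sprintf("hits: %d at 3 SD (%.1f%% hit rate); %d additional at 6 SD\n",
            calls3$n_hits, 100 * calls3$n_hits / nrow(calls3$hits),
            calls6$n_hits - calls3$n_hits))

sc <- score_against_truth(calls3, truth)
cat(sprintf("vs planted truth: sensitivity %.2f (%.2f on detectable positives, n=%d), specificity %.3f\n",
            sc$sensitivity, sc$sensitivity_detectable, sc$n_detectable,
            sc$specificity))
stopifnot(all(calls3$hits$compound_id[calls3$hits$is_hit] %in%
                calls6$hits$compound_id[calls6$hits$is_hit]))
cat("hit set at 3 SD is nested in the 6 SD set, as required\n")
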