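#!/usr/bin/env Rscript
# Stage 6 — in vivo larval toxicity of the lead chemistries.
#
# Single-dose significance: simulate 400 uM exposures with the reported
# mean mortalities as ground truth (amitriptyline 93%, doxepin 72%;
# water control 0%) and run the one-sample t-test per compound. Then the
# amitriptyline dose-mortality series at the campaign design (5 doses,
# 5 wells x 10 larvae, 3 assays) with ground truth LC50/LC90 = 78/185 uM,
# fit by binomial-logit regression with bootstrap CIs.

suppressPackageStartupMessages(library(dopscreen))

seed <- 20120124

# -- single-dose assays ------------------------------------------------------
single <- list(amitriptyline = 0.93, doxepin = 0.72)
for (cmp in names(single)) {
  p <- single[[cmp]]
  # three biological replicates of 60 larvae at 400 uM
  reps <- with_seed(seed + match(cmp, names(single)),
                    100 * rbinom(3, 60, p) / 60)
  t_res <- single_dose_test(reps, control_mean = 0)
  cat(sprintf("%s 400 uM: mean mortality %.0f%% (t=%.1f, df=%d, p=%.2g)%s\n",
              cmp, t_res$mean_mortality, t_res$t, t_res$df, t_res$p_value,
              if (t_res$p_value < 0.05) " *significant vs water control*" else ""))
}

# -- amitriptyline dose-response ---------------------------------------------
rec <- make_bioassay(truth_lc50 = 78, truth_lc90 = 185, seed = seed)
write_table(rec, file.path("results", "bioassay_records.tsv"))
fit <- fit_lc(rec, n_boot = 500, seed = seed)
print(fit)
cat(sprintf("recovery vs truth: LC50 %+.1f%%, LC90 %+.1f%%\n",
            100 * (fit$lc50 / 78 - 1), 100 * (fit$lc90 / 185 - 1)))
lc_tab <- tibble::tibble(
  compound_id = "amitriptyline", link = fit$link,
  lc50_uM = fit$lc50, lc50_lo = fit$lc50_ci[1], lc50_hi = fit$lc50_ci[2],
  lc90_uM = fit$lc90, lc90_lo = fit$lc90_ci[1], lc90_hi = fit$lc90_ci[2],
  slope = fit$slope, deviance = fit$deviance, df_residual = fit$df_residual)
write_table(lc_tab, file.path("results", "lc_fit.tsv"),
            report_signif = c(lc50_uM = "lc50_report", lc90_uM = "lc90_report"))
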