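# End-to-end campaign orchestration over synthetic data: QC -> screen ->
# confirmation -> selectivity -> in vivo, with stage artifacts and a
# Markdown report. Every stage output is a pure function of (config, seed).

#' Run a full synthetic screening campaign
#'
#' Executes the analysis chain in order: (1) checkerboard plate QC,
#' (2) library screen simulation, per-plate normalization,
#' antagonist-control threshold derivation at `k_sd` and `2 k_sd`,
#' hit calling, class partition, and planted-truth scoring;
#' (3) dose-response confirmation scenarios (dopamine EC50 recovery at
#' both receptors) plus selectivity analysis of the reported
#' confirmation IC50s; (4) larval bioassay simulation and LC50/LC90
#' fitting with a single-dose significance test. A stage failure stops
#' the run with a message naming the stage. Rerunning with the same
#' config and seed reproduces every artifact.
#'
#' @param config A [run_config()].
#' @param out_dir Directory for stage TSVs and the report (created if
#'   needed); `NULL` skips writing.
#' @param n_compounds Library size for the screen stage (default 1280).
#' @param n_boot Bootstrap resamples for the LC fit.
#' @return A list of class `campaign_report` with elements `qc`,
#'   `screen`, `confirmation`, `selectivity`, `in_vivo`, `provenance`.
#' @export
run_campaign <- function(config = run_config(), out_dir = NULL,
                         n_compounds = 1280, n_boot = 500) {
  seed <- config$rng_seed
  noise <- assay_noise_model(well_noise_cv = config$noise_cv,
                             plate_effect_sd = config$plate_effect_sd)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("campaign stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  qc <- stage("plate_qc", {
    cb <- make_checkerboard(noise, n_plates = 3, seed = seed)
    checkerboard_qc(cb, n_replicates_planned = 4)
  })

  screen <- stage("screen", {
    scr <- make_screen(n_compounds = n_compounds, noise = noise, seed = seed + 1L)
    normalized <- normalize_wells(scr$dataset)
    ctrl <- normalized$pct_inhibition[normalized$role == "antagonist_control"]
    thr <- derive_threshold(ctrl, config$k_sd)
    thr_relaxed <- derive_threshold(ctrl, 2 * config$k_sd)
    agg <- aggregate_replicates(normalized)
    calls <- call_hits(agg, thr, annotations = scr$dataset$compounds)
    calls_relaxed <- call_hits(agg, thr_relaxed, annotations = scr$dataset$compounds)
    truth_score <- score_against_truth(calls, scr$truth)
    list(threshold = thr, threshold_relaxed = thr_relaxed,
         calls = calls, calls_relaxed = calls_relaxed,
         truth = scr$truth, truth_score = truth_score)
  })

  confirmation <- stage("dose_response", {
    scenarios <- list(
      AaDOP1 = list(ec50 = 3.1e-9,
                    conc = rep(10^seq(-12, -6, length.out = 10), each = 3)),
      AaDOP2 = list(ec50 = 2.4e-7,
                    conc = rep(10^seq(-11, -4, length.out = 10), each = 3)))
    ests <- lapply(names(scenarios), function(r) {
      sc <- scenarios[[r]]
      crv <- make_dose_response(sc$ec50, concentrations = sc$conc,
                                n_experiments = 3, noise_cv = 0.1,
                                seed = seed + 2L, compound_id = "dopamine",
                                receptor = r)
      est <- fit_dose_response(crv, config$censor_limit)
      est$true_ec50_M <- sc$ec50
      est
    })
    dplyr::bind_rows(ests)
  })

  selectivity <- stage("selectivity", {
    ref <- reference_confirmation_potencies()
    pairs <- tibble::tibble(
      compound_id = ref$compound,
      ic50_target_M = ref$ic50_aadop2_nM * 1e-9,
      ic50_reference_M = ref$ic50_hd1_nM * 1e-9,
      censored_target = ref$censored_aadop2,
      censored_reference = is.na(ref$ic50_hd1_nM))
    records <- compute_fold_selectivity(pairs)
    ok <- records$computable
    corr <- rank_order_correlation(records$ic50_target_M[ok],
                                   records$ic50_reference_M[ok])
    list(records = records, correlation = corr)
  })

  in_vivo <- stage("bioassay", {
    rec <- make_bioassay(truth_lc50 = 78, truth_lc90 = 185, seed = seed + 3L)
    lc <- fit_lc(rec, n_boot = n_boot, seed = seed + 4L)
    top <- rec[rec$dose_uM == max(rec$dose_uM), ]
    per_assay <- tapply(100 * top$n_dead / top$n_larvae, top$assay_replicate, mean)
    sd_test <- single_dose_test(as.numeric(per_assay), control_mean = 0)
    list(records = rec, lc_fit = lc, single_dose = sd_test)
  })

  report <- structure(
    list(qc = qc, screen = screen, confirmation = confirmation,
         selectivity = selectivity, in_vivo = in_vivo,
         provenance = list(seed = seed, k_sd = config$k_sd,
                           censor_limit = config$censor_limit,
                           noise_cv = config$noise_cv,
                           plate_effect_sd = config$plate_effect_sd,
                           n_compounds = n_compounds,
                           package_version = as.character(utils::packageVersion("dopscreen")))),
    class = "campaign_report")
  if (!is.null(out_dir)) write_campaign(report, out_dir)
  report
}

#' Write campaign artifacts
#'
#' Emits one TSV per stage table and a Markdown report whose body is a
#' deterministic function of the campaign results.
#'
#' @param report A `campaign_report` from [run_campaign()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_campaign <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(report$qc$per_plate, file.path(out_dir, "qc_per_plate.tsv"))
  write_table(report$screen$calls$hits, file.path(out_dir, "hits.tsv"))
  write_table(report$screen$calls$class_counts, file.path(out_dir, "hit_class_counts.tsv"))
  write_table(report$screen$truth, file.path(out_dir, "truth.tsv"))
  write_table(report$confirmation, file.path(out_dir, "potency_estimates.tsv"),
              report_signif = c(potency_M = "potency_report_M"))
  write_table(report$selectivity$records, file.path(out_dir, "selectivity.tsv"))
  write_table(report$in_vivo$records, file.path(out_dir, "bioassay_records.tsv"))
  s <- report$screen; iv <- report$in_vivo
  lines <- c(
    "# Screening campaign report", "",
    sprintf("seed: %d; k_sd: %g; censor limit: %g M",
            report$provenance$seed, report$provenance$k_sd,
            report$provenance$censor_limit), "",
    "## Plate QC",
    sprintf("- mean replicate-adjusted Z over %d checkerboard plates: %.3f (sd %.3f)",
            nrow(report$qc$per_plate), report$qc$mean_z_replicate_adjusted,
            report$qc$sd_z_replicate_adjusted), "",
    "## Screen",
    sprintf("- threshold (mean - %g SD of antagonist control): %.1f%% inhibition",
            s$threshold$k_sd, s$threshold$threshold_pct_inhibition),
    sprintf("- relaxed threshold (mean - %g SD): %.1f%% inhibition",
            s$threshold_relaxed$k_sd, s$threshold_relaxed$threshold_pct_inhibition),
    sprintf("- hits: %d of %d compounds (%.1f%% hit rate)",
            s$calls$n_hits, nrow(s$calls$hits),
            100 * s$calls$n_hits / nrow(s$calls$hits)),
    sprintf("- sensitivity on detectable planted positives: %.3f (n=%d); specificity: %.3f",
            s$truth_score$sensitivity_detectable, s$truth_score$n_detectable,
            s$truth_score$specificity), "",
    "## Confirmation potencies",
    sprintf("- %s %s dopamine EC50: %s (truth %.3g M)",
            report$confirmation$receptor, report$confirmation$compound_id,
            report$confirmation$display, report$confirmation$true_ec50_M), "",
    "## Selectivity",
    sprintf("- rank-order potency correlation (AaDOP2 vs hD1): R^2 = %.3f, p = %.3f (n=%d)",
            report$selectivity$correlation$r_squared,
            report$selectivity$correlation$p_value,
            report$selectivity$correlation$n), "",
    "## In vivo",
    sprintf("- LC50 = %.1f uM (95%% CI %.1f-%.1f); LC90 = %.1f uM (95%% CI %.1f-%.1f)",
            iv$lc_fit$lc50, iv$lc_fit$lc50_ci[1], iv$lc_fit$lc50_ci[2],
            iv$lc_fit$lc90, iv$lc_fit$lc90_ci[1], iv$lc_fit$lc90_ci[2]),
    sprintf("- single-dose mortality at 400 uM: %.1f%% (t = %.2f, p = %.2g)",
            iv$single_dose$mean_mortality, iv$single_dose$t, iv$single_dose$p_value))
  writeLines(lines, file.path(out_dir, "campaign_report.md"))
  invisible(out_dir)
}
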