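# dopscreen

Analysis chain for a cell-based antagonist screening campaign against
AaDOP2, a D1-like dopamine receptor of the yellow-fever mosquito
*Aedes aegypti*. The receptor is Gαs-coupled: agonist binding raises
intracellular cAMP, read out as luminescence through a CRE-luciferase
reporter in stably transfected HEK293 cells. An antagonist suppresses
the dopamine-stimulated signal, so a library screen for insecticide
leads reduces to a quantitative pipeline over 384-well luminescence
plates — and that pipeline is what this package implements, end to end,
over synthetic data with known ground truth plus the campaign's
published summary tables.

The package is aimed at screening scientists and computational
biologists who want each step of such a campaign as a tested, reusable
function rather than a spreadsheet: plate quality control, plate
normalization and hit calling, dose-response potency estimation,
cross-species selectivity, and larval dose-mortality analysis.

## The statistics at the core

**Plate QC (checkerboard analysis).** Alternating minimum
(300 nM dopamine + 10 µM SCH23390) and maximum (300 nM dopamine) wells
across full plates give the screening-window statistic

    Z = 1 − 3(σ₊ + σ₋) / |µ₊ − µ₋|

and, because every compound is screened in quadruplicate, a
replicate-adjusted form with each σ shrunk by √n (n = 4 planned
replicates). Both are reported (`compute_z()`, `checkerboard_qc()`).

**Normalization and hit calling.** Per plate: mean background
luminescence is subtracted, the 300 nM dopamine maximal-stimulation
mean defines 100 % stimulation, and every well becomes a percent
inhibition. Replicate wells (4 per compound, split over two plates in
different quadrants) are averaged. The hit threshold derives from the
SCH23390 antagonist-control wells pooled across plates:

    threshold = mean(control inhibition) − k·SD(control inhibition)

with k = 3 for the campaign criterion (mean 93 %, SD 4 % ⇒ 81 %
inhibition; k = 6 gives the relaxed 69 % cutoff). The comparison is
closed (≥). See `normalize_wells()`, `derive_threshold()`,
`call_hits()`.

**Potency.** Four-parameter logistic
`y = bottom + (top − bottom) / (1 + 10^{h(log₁₀EC₅₀ − log₁₀c)})`
fitted per experiment by bounded multi-start Levenberg–Marquardt, then
aggregated as a geometric mean with a log-scale SEM; estimates ≥ 10 µM
are censored as lacking intrinsic activity (`fit_4pl()`,
`summarize_experiments()`).

**Selectivity.** Fold selectivity = IC50(hD1) / IC50(AaDOP2), and the
tie-aware rank-order potency correlation (Spearman as Pearson on
mid-ranks, permutation p-value) across compounds tested at both
receptors (`compute_fold_selectivity()`, `rank_order_correlation()`).

**Larval toxicity.** One-sample t-tests for single-dose mortality, and
binomial-logit regression of deaths on log₁₀ dose for LC50/LC90 with
the closed-form identity `log₁₀(LC90/LC50) = log₁₀9 / slope` and
well-level bootstrap CIs (`single_dose_test()`, `fit_lc()`).

Every stage has a matching generator with planted ground truth
(`make_screen()`, `make_checkerboard()`, `make_dose_response()`,
`make_bioassay()`), so recovery of known truth is a testable property.

## Worked example

```r
library(dopscreen)

# simulate a 1280-compound screen with 4% planted antagonists
scr <- make_screen(n_compounds = 1280, seed = 1)
nw  <- normalize_wells(scr$dataset)
thr <- derive_threshold(nw$pct_inhibition[nw$role == "antagonist_control"], k_sd = 3)
calls <- call_hits(aggregate_replicates(nw), thr)
thr$control_mean; thr$threshold_pct_inhibition; calls$n_hits
#> [1] 92.69994
#> [1] 80.49587
#> [1] 62
score_against_truth(calls, scr$truth)$sensitivity_detectable
#> [1] 1

# larval dose-mortality fit at the campaign design
rec <- make_bioassay(truth_lc50 = 78, truth_lc90 = 185, seed = 20120124)
fit_lc(rec, n_boot = 500, seed = 20120124)
#> <lc_fit> logit link, 75 wells
#> LC50 = 79.7 uM (95% CI 73.4-85.9)
#> LC90 = 190 uM (95% CI 166-215)
#> slope = 5.81 per log10 dose; residual deviance 70.17 on 73 df
```

The antagonist-control wells average ~93 % inhibition with ~4 % SD, so
the mean − 3 SD criterion lands at ~81 % inhibition; 62 of 1280
compounds clear it (the 51 planted antagonists and 13 off-target
reporter inhibitors straddle the cutoff, and every planted positive
that is detectably above threshold is recovered). The larval fit
recovers the generating LC50/LC90 of 78/185 µM within a few percent.

## Analysis workflow

The `analysis/` directory holds the campaign as numbered drivers, each
a thin narrative script over the package that writes its tables under
`results/`:

1. `01_simulate_campaign.R` — checkerboard + screen plates with truth
2. `02_plate_qc.R` — per-plate Z-factors
3. `03_hit_calling.R` — normalization, thresholds, hits, truth scoring
4. `04_dose_response.R` — EC50 recovery scenarios and censoring
5. `05_selectivity.R` — fold selectivity and rank correlation
6. `06_larval_bioassay.R` — single-dose tests and the LC50/LC90 fit

`run_campaign()` executes the same chain as one call. File formats
(plate CSV, compound CSV, result TSVs, YAML config) are documented in
the function reference (`?read_plate_csv`, `?run_config`); a minimal
plate row looks like

```
plate_id,well,role,compound_id,concentration_M,luminescence_cps
P1,A1,background,,,105.2
```

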