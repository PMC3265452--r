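---
title: "Models and methods behind the AaDOP2 screening analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the AaDOP2 screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistical content:
the models each stage fits, the assumptions they carry, what the
synthetic-data generators do and do not emulate, the numerical choices,
and the known limitations. It states no result that the test suite and
analysis scripts do not themselves compute.

## The screen and its readout

AaDOP2 is a Gαs-coupled, D1-like dopamine receptor of *Aedes aegypti*.
In the assay system it is stably co-expressed in HEK293 cells with a
CRE-luciferase reporter, so receptor activation by dopamine raises
cAMP, which drives luciferase expression, which is read as
luminescence (counts per second). An antagonist added before a fixed
300 nM dopamine challenge suppresses that signal. Three well roles
anchor the analysis on every plate: *background* wells (cells alone,
no dopamine, no compound), *maximal stimulation* wells (300 nM
dopamine, the top of the usable signal window), and *antagonist
control* wells (10 µM SCH23390 + 300 nM dopamine, a near-complete
block). Test compounds are screened at 10 µM in quadruplicate, with
duplicate wells on each of two plates placed in different quadrants of
the interleaved 16×24 grid, so that a plate- or dispenser-level
artifact cannot silently create or destroy a hit.

## Plate quality control

The screening-window statistic compares control separation to control
variability:

$$Z = 1 - \frac{3(\sigma_+ + \sigma_-)}{|\mu_+ - \mu_-|}.$$

A screen averaging $n$ replicate wells per compound effectively sees
replicate-mean noise, so the package also reports a replicate-adjusted
form with both condition SDs shrunk by $\sqrt{n}$. Two choices are worth
making explicit. First, the adjusted formula is the
plate-uniformity recommendation of the NIH assay-guidance style of
analysis (SD/√n shrinkage of both conditions); the classical form is
always reported alongside, so a reader who prefers either convention
has it. Second, sample SDs use the $n-1$ denominator because control
well counts per plate are small. When $\mu_+ = \mu_-$ both statistics
are undefined; the report flags this instead of throwing, because a
dead plate is a data-quality finding, not a programming error.

Both statistics are invariant under affine rescaling of the raw
signals (reader gain or offset changes), and monotone non-increasing
in either SD; the test suite checks both properties on randomized
inputs.

## Normalization and the hit criterion

Processing is strictly per-plate: the plate's mean background is
subtracted, and the plate's mean net maximal-stimulation signal
defines 100 % stimulation. Percent inhibition of a well is
$100(1 - \text{net}/\text{plate max net mean})$. Because plate effects
in this assay are well approximated as multiplicative on the net
signal, per-plate scaling cancels them exactly; the suite verifies
that hit scores are unchanged between a screen generated with no plate
effects and one regenerated with 20 % plate-effect SD.

The hit threshold derives from the antagonist control: *mean control
inhibition minus k·SD*, with k = 3 as the campaign criterion. Reading
"control + k standard deviations" as widening the acceptance band
*below* the control mean is the only reading consistent with both
published cutoffs — a control at 93 % ± 4 % gives 81 % at 3 SD and
69 % at 6 SD — and it makes the hit set monotone non-decreasing in k,
which the suite checks on simulated screens. Three further choices:
the control mean/SD are pooled across all plates (the campaign quotes
a single cutoff, and pooling stabilizes the SD), the threshold
comparison is closed (a compound exactly at the cutoff is a hit, "at
least"), and no outlier rejection is applied among quadruplicates (no
published rule exists; silent rejection would bias sensitivity
estimates against the planted truth).

Compounds are aggregated as unweighted means over their four wells.
Each compound's effect is also expressed as percent of the control
effect (100 × mean inhibition / control mean inhibition), the scale on
which the campaign reported its hit table. Hits are partitioned into
seven mechanism classes (dopamine-receptor antagonists, serotonin-,
histamine- and muscarinic-receptor ligands, uptake inhibitors, kinase
modulators, miscellaneous) supplied as annotations — the package
validates the closed vocabulary but does not re-derive mechanism.

## What the synthetic screen emulates — and what it does not

The generator reproduces the design quantities: 384-well plates with
fixed control columns, 320 test wells per plate, quadruplicates split
across plate pairs in distinct quadrants, a 10-fold signal window
(background 1000 cps, maximal net 9000 cps). Noise is multiplicative
lognormal on the net signal per well, plus a lognormal per-plate
effect — luminescence is positive and heteroscedastic, and no published
noise model exists for the instrument, so the well-noise CV (0.29) is
calibrated to a single figure of merit: it is the value at which three
checkerboard plates give a replicate-adjusted Z of about 0.5, the
published qualification value. Antagonist-control wells draw their
inhibition directly from a normal distribution (mean 0.93, SD 0.04),
the unique pair that places the derived thresholds at 81 % (3 SD) and
69 % (6 SD); parameterizing these wells on the inhibition scale keeps
the two printed cutoffs reachable independently of the well-noise CV.

Planted truth has three mechanisms: *true antagonists* (IC50s
log-uniform over 10 nM–3 µM, the span of the confirmed hits; their
10 µM screen effect follows single-site occupancy with Hill slope 1),
*off-target reporter inhibitors* (chemistries that suppress the
CRE-luciferase readout without touching the receptor — the screen
cannot distinguish these, which is exactly why the campaign ran cAMP
confirmation assays; planted at 1 % with 82–99 % signal suppression),
and inactive filler. Default composition is 4 % antagonists, matching
the campaign's hit rate.

What passing tests on these simulations show is that the analysis
chain recovers what it is supposed to recover *under this noise
model*: they cannot certify behavior under spatial plate gradients,
edge effects, carry-over, or compound fluorescence/quenching, none of
which are modeled (and none of which the original analysis corrected
for either — there is deliberately no B-score or spatial smoothing
stage).

## Dose-response potency

The four-parameter logistic is fitted in log10-concentration space:

$$y = \text{bottom} + \frac{\text{top} - \text{bottom}}
{1 + 10^{\,h(\log_{10}\text{EC}_{50} - \log_{10}c)}}$$

per experiment, by bounded Levenberg–Marquardt with multiple starts
(Hill seeded at ±1 and ±0.5; midpoint at the half-range crossing; the
log-potency box extends one decade beyond the tested range). The Hill
slope is free — variable-slope fitting is the default in the software
the original campaign used — and its sign carries curve orientation,
so an antagonist (descending) curve needs no special casing: mirroring
a curve vertically flips the sign of $h$ and nothing else, a property
the suite asserts. A fit that pins the potency at the search bound is
treated as failed for aggregation; flat curves therefore end as
censored rather than as spurious mid-range potencies.

Experiments are fitted separately and then aggregated — matching the
"three independent experiments" presentation of the source assays —
as a geometric mean, since potencies are log-normally distributed;
the SEM is computed on the log10 scale and mapped back by the delta
method. Whether published ± values are SEMs over experiments or fit
standard errors is not stated in the source; SEM over experiments is
implemented. Potencies at or above 10 µM are censored after
aggregation and rendered "≥ 10 µM" (lacking intrinsic activity).

The recovery scenarios used in the tests and the acceptance script
simulate 3 experiments × 10 concentrations × triplicate measurements
with 10 % lognormal response noise, the within- and between-experiment
replication of the source assays. At this size the geometric-mean EC50
has roughly 9–10 % sampling SD, consistent with the published
precision of the AaDOP2 dopamine EC50 (240 ± 16 nM); the tests check
recovery within ±20 %. The independent oracle for the optimizer is a
dense grid search over (log-potency, Hill) with the two linear
parameters profiled out in closed form.

## Selectivity

Fold selectivity is the plain potency ratio IC50(hD1)/IC50(AaDOP2);
values above 1 mean mosquito-selective. Ratios are only computed for
compounds uncensored at both receptors. The rank-order potency
comparison is Spearman's correlation computed explicitly as Pearson on
mid-ranks — two of the eight confirmation compounds tie at the printed
precision, so tie handling is not optional — squared to an R², with a
permutation p-value (exhaustive for ≤ 7 pairs, Monte-Carlo above). A
rank-based statistic is the right reading of "rank order potencies":
Pearson on log-potencies of the same printed values exceeds the
published R² bound, so a parametric correlation is exposed nowhere in
the main chain. Rank correlation is invariant to any strictly monotone
transform of either margin, which also makes the unit convention
(molar vs nM) irrelevant.

## Larval bioassays

Single-dose assays are one-sample t-tests of per-replicate percent
mortality against the observed control mean (0 % for water controls),
two-tailed, df = replicates − 1. Zero-variance replicates (e.g. all
wells at the same mortality) are flagged with a below-machine-floor
p-value rather than an error.

Dose-mortality estimation is binomial regression of deaths on log10
dose. The logit link is the default — the source does not name its
link, and the logit yields the exact closed-form identity
$\log_{10}(\text{LC}_{90}/\text{LC}_{50}) = \log_{10}9 / b$
(b in logits per log10 dose), which doubles as an internal consistency
test; probit is available by argument and agrees closely at the center
of the dose range. Control wells are excluded from the regression;
Abbott's correction for nonzero control mortality exists but is off by
default because the source design observed 0 % control mortality.
Complete separation (every dose all-or-nothing) is a named error: the
slope is unidentified and no number should be reported. Bootstrap 95 %
CIs resample wells, not larvae — technical replicates share a plate and
day, so wells are the conservative exchangeable unit; coverage is
checked by simulation in the suite (120 seeded replicates at the
design size, n_boot = 200, chosen to keep the default test run inside
a few minutes while still estimating coverage to ~3 %).

The simulated design matches the published one exactly: five doses
(400/200/100/50/25 µM), five wells of ten larvae per dose, three assay
repeats. At that size the LC50 is recovered within ±15 %, the check
the tests apply.

## Numerical and degenerate-input conventions

* Concentrations are molar everywhere internally; bioassay doses are
  µM at the interface (the source tables mix nM and µM).
* Potency report columns round to 2 significant figures; machine
  columns keep full precision; TSV/CSV round-trips are exact.
* Ties in ranks get mid-ranks; permutation p-values are add-one
  corrected in the Monte-Carlo branch so they are never exactly 0.
* Equal QC condition means, < 2 control wells, < 4 distinct
  concentrations, inconsistent LC pairs, and layout over-capacity all
  raise located, named errors; nothing silently coerces.
* All generators are seeded and restore the caller's RNG state; a
  fixed seed fixes every generated value.

## Limitations

The noise model is calibrated to one published figure of merit, not to
raw plate data (which is unpublished); conclusions about absolute
false-positive rates on real instruments should not be read off the
simulations. Mechanism classes are input annotations, not predictions.
The dose-mortality model is a 24 h endpoint analysis — no
time-to-death component. And the screen analysis deliberately contains
no spatial correction stage, so plates with strong row/column
gradients would need upstream handling this package does not provide.
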