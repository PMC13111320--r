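---
title: "Modeling grapevine phenology from biweekly satellite time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling grapevine phenology from biweekly satellite time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Grapevine management decisions — rain covers at flowering, scouting and
biopesticides before veraison, harvest scheduling — hinge on knowing the
current phenological stage of each block. Satellite vegetation indices
(NDVI, EVI) observed at a biweekly cadence carry enough signal to stage a
season remotely: canopy green-up follows budburst, the plateau spans
flowering through veraison, and senescence follows harvest. `vitiphen`
implements an end-to-end pipeline for this task: a seeded generator of
synthetic site-seasons with growing-degree-day (GDD) ground truth, quality
control and gap imputation for the index series, a compact
depthwise-separable convolutional classifier over "pseudo-images" of the
season, a hybrid dream-optimizer/particle-swarm hyperparameter search, and a
rule-based rain/pest alerting layer scored against documented events.

Everything runs on one CPU; the neural network (forward, backward, Adam) is
implemented in the package itself, with the memory-bound kernels in compiled
code under `src/`.

## The synthetic generator and what it emulates

Real inputs of this kind are per-pixel time series from global crop
datasets: 26 biweekly NDVI/EVI composites per season plus daily reanalysis
weather. The generator reproduces the documented statistical structure of
such data so every downstream stage is testable offline:

* **Zones.** Three agroecological zones in a 40/30/30 mix. Annual rainfall
  is drawn per site inside the documented ranges (Mediterranean 600–800 mm,
  subtropical 400–550 mm, temperate 700–900 mm; rain amounts are rescaled so
  the annual total lands exactly in range, preserving wet/dry-day
  intermittency). Temperature is a seasonal sinusoid plus Gaussian noise;
  zone means and amplitudes (13.5/8, 14.5/7, 13.0/8 °C) were chosen so that
  GDD onsets land at realistic intervals (budburst around interval 6–7,
  flowering 10–11, veraison 14–15, harvest 17–19) and total annual GDD stays
  in 1550–1900, enough to reach the harvest threshold in almost every
  season. A ±0.7 °C site-level mean shift emulates microclimate so stage
  timing varies across sites of one zone. Southern-hemisphere sites are
  handled by season-relative indexing: day 1 is the local season start, so
  hemisphere is transparent downstream.
* **Stage truth.** Cumulative GDD (base 10 °C) crosses published onset
  thresholds: budburst 50, flowering 400, veraison 1000, harvest 1400. The
  published bands have dead zones (e.g. 100–400); for per-interval labels the
  stages are made contiguous — a stage persists until the next one starts —
  and the band uppers are kept as metadata only. An interval is labeled with
  the stage active at its midpoint (day 8 of 14). A fifth internal label,
  `pre_season`, covers intervals before budburst; the classifier never
  trains on it.
* **Vegetation indices.** A shared double-logistic latent curve (rise
  centered between budburst and flowering onsets, τ = 12 days; decline
  starting ~40 days after harvest onset, τ = 28 days) with per-site affine
  maps: NDVI = base + gain·latent, EVI a proportional transform
  (gain ratio 0.82). Bases and gains are drawn so population means match the
  documented summary statistics (NDVI ≈ 0.45, EVI ≈ 0.38) with clipping to
  the documented ranges [0.10, 0.85] and [0.08, 0.75]. Observation noise is
  *uniform and bounded* (±0.03) rather than Gaussian, so clean consecutive
  changes can never exceed 0.28 — the documented maximum for clean
  trajectories — and the 0.3 spike filter provably never fires on clean
  data.
* **Contamination.** Cloud spikes depress NDVI by N(0.47, 0.12) (about 94%
  of draws exceed the 0.3 detection threshold, matching the documented
  detectability) and EVI proportionally. Missing runs hit 28.47% of series;
  affected series carry 1 + Poisson(0.84) gaps with length classes
  {1, 2, 3, 4–6, >6} drawn from the documented gap-count proportions. The
  documented ">6" class averages ~18 missing steps, which would always
  trip the 30% series-drop rule, so the generator draws that class as
  7 + Poisson(1.5) — long enough to exercise the LOESS branch, short enough
  to survive QC.

What the generator does **not** emulate: spatial correlation between sites,
multi-year carryover, cultivar differences, compositing artifacts other than
spikes/gaps, and any real geography beyond labeled bounding-box coordinates.
Passing tests therefore demonstrate that the pipeline recovers structure the
generator put in — not field performance on real imagery.

## Preprocessing

* **Spike filter.** A change between consecutive *observed* NDVI steps whose
  magnitude strictly exceeds 0.3 marks a spike. Because cloud contamination
  depresses the index, the endpoint with the lower NDVI is the one flagged;
  this catches a dip both through the drop into it and the recovery out of
  it, which matters when a dip coincides with steep green-up. Flagged steps
  censor NDVI *and* EVI (the contamination is atmospheric); rainfall is a
  ground/reanalysis variable and is untouched.
* **Series dropping.** A series with more than 30% bad steps
  (flagged + missing, strict inequality) is discarded whole.
* **Imputation dispatch by gap length.** L = 1: linear interpolation between
  anchors (exact on lines). L ∈ {2, 3}: cubic spline through the observed
  points (`stats::splinefun`, FMM end conditions — exact on cubic signals).
  L > 3: LOESS, degree-1 local regression with tricube weights
  (`stats::loess`, direct surface) fitted to observed points within ±6
  intervals of the gap; the span of 0.2 is expressed relative to the whole
  series, so each local fit uses about `ceil(0.2 · n_observed)` points
  regardless of how the window truncates the fitting set. Edge gaps with a
  missing anchor use nearest-value extension for L ≤ 3 and LOESS otherwise.
  Observed values are never altered, and imputing a complete series is a
  no-op.
* **Normalization.** Per-feature min–max to [0, 1]. Parameters are fitted on
  the *training* portion only and reused elsewhere; fitting on the entire
  dataset (train + test) is the leakier alternative and is available simply
  by fitting on the full collection, but the pipeline defaults to the
  fold-safe protocol.
* **Pseudo-images.** Each (site, interval *t*) sample is a 26 × 3 × 1 matrix
  — rows are biweekly steps, columns (NDVI, EVI, rainfall) — with rows
  beyond *t* zeroed. This causal mask makes each sample "the season as seen
  up to interval *t*", so one model serves both in-season staging and
  end-of-season reconstruction.

## The classifier

The trunk is a MobileNetV2-style stack: a 3 × 3 stride-1 same-padding stem,
inverted-residual bottleneck blocks (1 × 1 expansion, depthwise 3 × 3,
linear 1 × 1 projection, skip when shape-preserving), a 1 × 1 projection to
a 32- or 64-wide feature map, global average pooling, one hidden dense
layer, dropout, and a 4-way softmax. Depthwise separability cuts the
multiply-add cost of a convolution by exactly 1/N + 1/D_K² — the package's
`conv_cost()` computes both sides of that identity. Strides of 2 are applied
only along the temporal (26-row) axis so the 3-wide feature axis never
collapses.

The canonical configuration keeps 16 bottleneck blocks with widths scaled to
the tiny input (~429k parameters). Training-heavy paths (tests, the
evaluation harness, the acceptance run) use `compact_network_spec()` — six
blocks, expansion 2, ~13k parameters — which reaches the same accuracy on
the synthetic task in a fraction of the time; this is a problem-size choice
documented here once and used consistently.

Three losses are available: plain categorical cross-entropy; weighted
cross-entropy with a 4-vector of class weights (normalized to sum to 1 and
scaled by the class count, so uniform weights reproduce the plain loss
exactly); and focal loss with exponent α (default 2; α = 0 reduces to plain
CE). The default is *adaptive* weighted CE: after each epoch, per-class
error rates Mr_j = 1 − recall_j on the validation split are mapped through a
monotone function (e^y by default; identity, y³, 10^y, e^100y also
implemented) and renormalized into the next epoch's weights. A class absent
from an epoch keeps its previous recall. "Recall on the validation split" is
a definitional choice — the alternative readings (precision, training-split
recall) are not distinguishable from the description this work follows.

Training is minibatch Adam from scratch. Pre-training on natural-image
datasets is structurally impossible at a 26 × 3 × 1 input and is not
attempted. Dropout applies to the hidden dense layer only. Batch-norm
statistics use the conventional momentum-0.9 running averages for
inference.

Predicted per-interval stages are monotonized by a running maximum over the
stage order before onset extraction (phenology is sequential; isolated
backward flickers are noise). The onset of a stage is the midpoint day of
the first interval predicted as that stage; a stage that never appears gets
no onset.

## The hyperparameter search

The tuner is a population metaheuristic: each agent is a candidate
(learning rate, batch size, dropout, kernel size, epochs) drawn in the
documented ranges (learning rate on a log10 scale in [1e-5, 1e-2]; batch
snapped to {16, 32, 64, 128}; dropout [0.2, 0.7]; kernel {3, 5}; epochs
[50, 200]). For the first 90% of iterations (exploration) the population is
split into five static groups; each agent resets to its group's best, then
"forgets" k_q randomly chosen dimensions: with probability 0.9 a forgotten
coordinate is perturbed around the group best by a uniform draw over the box
scaled by a cosine factor that decays to zero at the phase end, otherwise it
is copied from a random other agent (dream sharing; copying from oneself is
disallowed). The final 10% (exploitation) works the same way from the global
best, without grouping or dream sharing, under its own cosine schedule.
Every proposal is blended with a PSO step — velocity
v ← 0.7·v + 2·r₁(p_best − x) + 2·r₂(g_best − x), position
0.6·proposal + 0.4·(x + v) — and repaired into bounds (uniform resampling
for ≤15 dimensions, coordinate copy from another agent above that).

Interpretation notes, decided once: the published perturbation term is read
as a uniform draw over the box (the symbols are defined as the box bounds);
the exploration cosine argument is read as π(t + Tmax − Td)/Tmax so the
factor reaches zero exactly at t = Td; the velocity update includes the
conventional uniform multipliers r₁, r₂ (a `paper_pso = TRUE` switch removes
them, reproducing the deterministic printed form); groups are static; an
agent's fitness is evaluated once per iteration after all coordinate
updates; no explicit rollback of worsened agents is added because the next
iteration's memory reset restores bests anyway. Non-finite objective values
are recorded as +∞ and the run continues.

The tuning objective is the validation loss of a short proxy run (3 epochs
on a ~40-site subsample); the decoded epochs dimension is honored only in
the final fit. Minimization is the convention throughout.

## Risk alerts and event matching

Rain-stress: an alert at every interval whose biweekly rainfall strictly
exceeds the collection-wide 75th percentile *and* whose predicted stage is
flowering (fruit set is folded into flowering — the 4-class model has no
separate fruit-set window). Pest risk: within the 30 days before the
predicted veraison onset, any day with temperature > 22 °C and relative
humidity > 70% (grapevine moth conditions); consecutive qualifying days
collapse to one alert dated at the run's first day. The percentile is
population-level across the evaluation collection; a per-site variant is a
one-line change but is not the default because site-level 26-point
percentiles are noisy.

Scoring follows the asymmetric ±5/±10 protocol: an event is a true positive
if a same-site same-type alert falls within ±5 days (greedy one-to-one
matching by smallest gap, ties to the earlier event); unmatched events are
false negatives; an alert is a false positive only if *no* same-site
same-type event lies within ±10 days. Alerts landing 5–10 days from an event
count neither way — a deliberate limbo band absorbing reporting lapses.
TP + FN always equals the number of events. Since no external incident
database ships with the package, the evaluation harness scores model alerts
against events derived by applying the same rules to the *ground-truth*
stage timeline — a synthetic stand-in that measures how much alert fidelity
is lost to stage-prediction error alone.

## Evaluation harness

Site-grouped, zone-stratified splitting: 70% of sites per zone to training,
the rest held out; five folds partition the training portion (the held-out
30% is never folded). Metrics: accuracy, per-class precision/recall/F1,
macro-F1, confusion matrices; onset mean/median absolute error in days over
matched (site, stage) pairs; percentile bootstrap CIs (B = 1000 by default);
classical paired two-tailed t-tests at α = 0.01 with explicit degenerate
handling (all-zero differences → p = 1; constant non-zero differences →
infinite statistic, p reported as 0 with a flag). Permutation importance
shuffles one feature's column block across test samples and reports the mean
accuracy drop. The ablation grid crosses {tuned vs default hyperparameters}
× {26 vs 13 rows} × {with vs without rainfall}; the 13-row variant pools
adjacent biweekly rows — means for the indices, sums for rainfall, which on
the normalized scale is the same pooling with a doubled range — and the
no-rainfall variant zeroes the third column. The expected ordering
(full ≥ no-rainfall ≥ monthly) is logged, not asserted.

## Numerical choices and degenerate inputs

* Backpropagation is verified against central-difference numerical gradients
  (worst relative error ~1e-5) across every layer type and all three losses.
* Log arguments are clamped at 1e-12; batch-norm variance at ε = 1e-5.
* `randi(lo, hi)` is inclusive; lo > hi resolves to hi; forget counts are
  clamped to [1, Dim].
* Kernel-size decoding at the exact midpoint (4) snaps down to 3.
* A GDD series that never crosses a threshold simply omits that stage; a
  constant-temperature season at exactly the base temperature stays
  `pre_season` throughout.
* Seeds: every stochastic component takes an explicit seed; derived streams
  use a fixed 32-bit linear congruential mix so independent components do
  not share streams.

## Problem sizes used in the shipped runs

The scaled-down end-to-end run (tests and the acceptance script) uses 400
sites (~280 training, ~120 held out), 8 labeled intervals per training site,
a population of 10 for 20 optimizer iterations with 3-epoch proxy fits, and
the compact 6-block network. The optimizer benchmark uses the 5-D sphere
with N = 30, Tmax = 300, 20 seeds. These sizes are the package's choices for
reproducible desk-scale runs; the same code paths accept larger values.

## Known limitations

* Synthetic realism is limited (see the generator section); accuracy
  numbers here do not transfer to real imagery.
* The pre-season portion of a causal pseudo-image is indistinguishable from
  an early-budburst sample, so predicted budburst onsets saturate at the
  first interval for sites whose true budburst is late; median onset error
  is the robust summary, and the mean is reported alongside.
* The event records used for alert scoring are rule-derived from ground
  truth, not independent field reports.
* Training determinism holds for a fixed BLAS; exotic threaded BLAS builds
  may reorder reductions.
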