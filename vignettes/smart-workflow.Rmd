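---
title: "Scanning matched repeated time points for pre-diagnostic marker patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning matched repeated time points for pre-diagnostic marker patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the design

Molecular changes that precede a clinical diagnosis are faint compared with
the variation between individuals and with drift over years of sample
storage. A design that samples each future case twice before diagnosis —
a baseline and a later, repeated sample — and pairs every case with a
tightly matched control sampled at the same times, allows both nuisance
sources to be subtracted rather than modeled. Two within-subject,
within-pair contrasts do this:

* progression, `X_progress = X_repeated − X_baseline`, removes stable
  individual differences;
* disease progress, `d = X_progress(case) − X_progress(control)`, removes
  the shared passage-of-time component, leaving case-specific change.

Each matched pair contributes one difference vector `d` over the measured
variables, plus two time coordinates: `ttd`, the years from the case's
repeated sample to diagnosis, and `tbs`, the years between the baseline
and repeated samples. `ttd` is anchored to the repeated (later) sample
because that is the sample whose distance to diagnosis the method
interrogates. The question the scan answers is *where in the `(ttd, tbs)`
plane does a reproducible multivariate pattern in `d` become detectable*
— in other words, how early the marker pattern appears, and how long a
follow-up interval still permits within-subject normalization.

For cohorts with a single pre-diagnostic sample per subject, the analogous
contrast is `d = X_case − X_control`, with `tbs` undefined.

## Effect-projection OPLS

The difference vectors are dependent observations of a hypothesized common
effect. Effect projections handle this by regressing a constant unit
response on the difference matrix: variables are scaled by their sample
standard deviation (`n − 1` denominator) *without centering*, because the
origin of difference data ("no change") is meaningful, and an orthogonal
projections to latent structures (OPLS) model is fitted with `y = 1`.
The predictive weight vector is `w ∝ X'y` (unit norm), scores `t = Xw`,
loadings `p = X't/t't`, and the inner coefficient `b = t'y/t't`. Variation
orthogonal to the response can be deflated as separate components before
the predictive fit; subset models default to zero orthogonal components
(a single predictive component) to limit overfitting on 20 observations,
and the component count is an explicit setting, never auto-tuned.

Two useful consequences anchor the implementation and its tests:

* on a single variable the model's t statistic equals the paired
  two-tailed Student t-test, `t = mean/(sd/√n)` with `n − 1` degrees of
  freedom — the primary oracle of the OPLS module;
* sd-scaling makes every statistic invariant to positive rescaling of any
  variable, so arbitrary intensity units are harmless.

Negating the difference data flips the sign of `w` but leaves scores and
predictive ability unchanged — with a constant response the score is a
projection onto a data-determined direction, so only the loading signs
carry the direction of change.

## Cross-validation, variable selection and CV-ANOVA

Predictive ability is estimated with k-fold cross-validation (default
`k = 7`, the convention of the chemometrics software family this model
class comes from; folds are a seeded, balanced partition recorded in
every result). Inside each round, the model may be restricted to the
variables that reach both loading-significance criteria *on the training
part only* (two-sided p < 0.05 on each):

* the "w" criterion — the paired t-test on the raw difference column;
* the "p" criterion — the cosine similarity `cs` between the sd-scaled,
  uncentered column and the model-estimated response, converted to
  `t = cs·√(n − 1)/√(1 − cs²)` with `n − 2` degrees of freedom. The
  cosine is uncentered (not a Pearson correlation) because the data are
  uncentered.

The refitted model predicts the held-out responses; pooled predictions
give `Q² = 1 − PRESS/SS(y)`, where `SS(y)` is the *uncorrected* sum of
squares of the unit response (an uncentered response has no meaningful
corrected total). A round in which no variable passes both criteria makes
the model non-computable; this is a recorded sentinel, not an error, and
a non-computable model is never significant.

Model significance is an analysis of variance of the cross-validated
residuals: with `A` components and `n` observations,
`F = ((SS(y) − PRESS)/A) / (PRESS/(n − A))` referred to `F(A, n − A)`
(for a centered response the totals carry `n − 1`). A PRESS of zero
returns `p = 0` with a perfect-fit flag; a PRESS above the total gives
`p = 1`.

Measured behaviour worth knowing: at the full-cohort size (`n = 64`,
`p = 142`) the test holds its nominal level under null data (rejection
rate ≈ 0.04–0.05 at α = 0.05 in the package's own calibration test), but
at the subset size `n = 20` it is anticonservative (≈ 0.12 at nominal
0.05). This is a small-sample property of the F approximation, and it is
precisely why the workflow includes the random-data simulation below: the
density of significant subsets is never interpreted against its nominal
level, only against the same quantity recomputed under the null.

## The subset scan

A lattice with 0.25-year steps covers the bounding box of the observed
`(ttd, tbs)` coordinates. At each anchor, the `k = 20` observations with
the smallest weighted distance `√((w·Δttd)² + Δtbs²)` are selected, once
for each of seven `ttd` weights `1/8, 1/4, 1/2, 1, 2, 4, 8` (a doubling
sequence is the only seven-element geometric ladder with those endpoints;
the weight set is configurable). Small weights make subsets long in
`ttd`, large weights long in `tbs`, so the same anchor is interrogated at
seven aspect ratios. Distance ties are broken by pair id, making the scan
fully deterministic. Identical member sets arising from different anchors
or weights are deduplicated; each unique subset is fitted and
cross-validated as above and recorded with:

* its position — the unweighted mean `(ttd, tbs)` of its members;
* its Hotelling T² 95% ellipse — center at the member mean, axes from the
  eigen-decomposition of the member covariance scaled by
  `2(n−1)/(n−2)·F₀.₉₅(2, n−2)` (collinear members give a degenerate,
  zero-area sentinel);
* per-variable w/p statistics from the full-subset fit, used by the
  variable-level maps.

Two displays summarize the scan. The *model plot* marks each subset
position, highlighting models with CV-ANOVA p < 0.05. The *observation
density map* rasterizes the plane (cell size defaults to the grid step)
and counts, per cell, the significant-subset ellipses covering the cell
center. Variable-level maps do the same for the subsets in which a chosen
variable passes one of three criteria — univariate t-test, t-test with
Benjamini–Hochberg FDR < 0.2 across the variables of each subset, or
multivariate (significant model *and* both loading criteria) — signed by
the direction of change. The multivariate map is by construction a
cellwise subset of the t-test map.

## One pattern or several: clustering the loadings

If the significant models reflect one underlying marker pattern, their
`w` vectors should point the same way. Average-linkage hierarchical
clustering under the `1 − cosine` distance makes this checkable. The
cluster count is decided against a simulated reference: loading sets of
matched size and dimension with independent standard-normal entries,
1000 replicates, recording each replicate's maximum merge height;
observed merges above the 95th percentile of those maxima split clusters.

A limitation to keep in mind: independent high-dimensional loadings are
themselves nearly pairwise orthogonal, so this reference cannot separate
two groups of loadings that are merely orthogonal — their merge height
(~1) sits below the null threshold. Groups pointing in clearly opposed
directions (distance near 2) are separated. The null generator is
pluggable; the default reproduces the behaviour described above, and in
the intended use (one planted pattern) it correctly reports a single
cluster.

## Calibrating the density map against chance

Fitting thousands of models on overlapping subsets guarantees
significant-looking models somewhere. The control is direct simulation:
keep every geometric ingredient fixed — coordinates, subset memberships,
ellipses, fold partitions — and replace the variable data with
independent standard-normal draws (EP sd-scaling makes any marginal
scale equivalent to N(0,1)), 10,000 times by default. Each replicate
yields a full significant-subset density map; the per-cell empirical
distribution calibrates the observed map through the add-one estimator
`p̂ = (1 + #{replicates ≥ observed})/(1 + n_reps)`, which never returns
zero and floors at `1/10001` ≈ "<0.001" at the default replicate count.
`p̂` is discretized to six display levels: ">0.20", "<0.20", "<0.10",
"<0.05", "<0.01", "<0.001".

The per-cell estimator is calibrated cellwise, not familywise: under a
global null about 4–5% of covered cells reach "<0.05" on average, but
the chance that *some* cell does is much larger (cells are only
partially correlated). The map is therefore read as a spatial pattern —
a contiguous low-probability region co-located with a cluster of
significant models — not as a per-cell hypothesis test. The package's
tests check the calibrated quantity: the expected fraction of covered
cells reaching "<0.05" under the null stays at or below 0.05 up to
Monte-Carlo error.

Replicates are seeded independently (`seed + replicate`), so results are
independent of execution order, and long runs checkpoint and resume.

## The region of interest and the latent biomarker

The region of interest — the rectangle `ttd < ttd_max`, `tbs < tbs_max`
where significant, mutually similar models concentrate — is declared by
the analyst after inspecting the maps; no automatic rectangle estimator
is provided, by design. A one-component effect-projection model on the
selected variable panel, restricted to the pairs inside the region,
quantifies the panel's predictive ability (`Q²`, CV-ANOVA p), with
per-round selection off because the panel is already fixed.

The same restricted model, trained on the discovery region, scores an
independent single-time-point cohort: each validation pair's
case-minus-control difference is projected onto the model (uncentered, so
identical case/control values score exactly zero and scores are linear
in the difference). Evaluation uses:

* a dependent t-test — a one-sample t on the scores of pairs within the
  positive window (default `ttd < 8` years), valid because each score is
  already a paired contrast;
* ROC analysis with the window as the positive condition; AUC by
  trapezoid/midrank, which equals the Mann–Whitney `U/(n₁n₂)` statistic
  exactly. Significance defaults to the rank-sum test, since the two
  windows are independent groups of pairs; a one-sample signed-rank test
  of the positive-window scores against zero is available as an
  alternative reading.

## The synthetic cohort generator

All tests and the acceptance run operate on generated cohorts, because
the generator makes the ground truth explicit. It emulates the discovery
design: 64 matched pairs, baseline + repeated samples, 142 variables
with heterogeneous means (uniform 50–150) and scales (uniform 0.5–2×),
a subject-level random effect (sd 1) and measurement noise (sd 1), and a
planted increase of 1.5 total-sd units on a 15-variable panel, applied
to the *case repeated sample only* — so the paired transforms concentrate
it — if and only if the pair lies in the 8 × 7-year rectangle, with a
1-year linear taper to zero at the boundary (margin 0 gives a hard
edge). Controls never receive the effect.

The `(ttd, tbs)` sampling ranges default to uniform over
(0.5, 12) × (0.5, 9) years. This puts roughly half of the 64 pairs
inside the 8 × 7 region, matching the reported region membership of the
discovery design this generator emulates (region statistics there are
quoted with 28 degrees of freedom, i.e. 29 of 64 pairs); a much sparser
region would misrepresent the design the method was built for. The
validation generator mirrors the single-time-point design (default 68
pairs) with the effect gated by `ttd` alone, and accepts an explicit
panel so discovery and validation can share the same planted variables.

What the generator does *not* emulate: correlated metabolite blocks,
batch and run-order structure, heavy-tailed intensity distributions,
missingness, and imperfect matching. Passing tests therefore demonstrate
the machinery — contrasts, models, calibration, recovery of a planted
rectangular signal — not performance on real acquisition artifacts.

## Numerical choices and degenerate inputs

* Sample standard deviations use the `n − 1` denominator everywhere,
  required for the paired-t equivalence.
* Zero-variance variables are an error at scaling time; inside the scan
  and cross-validation they are dropped from the affected fit and their
  statistics recorded as NA sentinels.
* Orthogonality of score vectors holds to 1e−8; the paired-t equivalence
  to 1e−10.
* Exactly collinear ellipse inputs give a degenerate zero-area sentinel;
  a response exactly orthogonal to the predictors is a rank error.
* Distance and merge ties break deterministically (pair id, leaf order);
  all randomness (folds, null draws, generator) flows from explicit
  seeds kept below 2³¹.
* Times are continuous years; ISO-8601 dates are converted with the mean
  Gregorian year length.

## Problem sizes used by the test suite

The package's own checks run at sizes chosen to exercise the full
machinery while keeping the suite brisk: full-resolution scans
(0.25-year grid) for the acceptance run; 0.5-year grids for the 50
planted-recovery replicates; ~120 random-data replicates for the
calibration checks (the defaults remain 0.25 years and 10,000
replicates); 2000 simulations for the CV-ANOVA level check at
`n = 64 × p = 142`. These are the package's desk-scale choices; all of
them are settings, not constants.

## Known limitations

* CV-ANOVA is anticonservative at subset size `n = 20`; subset-level
  significance is only meaningful relative to the random-data
  calibration.
* The loading-cluster reference cannot split orthogonal pattern groups
  (above).
* The region of interest is a user decision; two analysts may draw
  different rectangles from the same maps.
* The unique-subset count depends on the grid extent convention (this
  implementation uses the observed bounding box, inclusive, aligned to
  the step), so counts are comparable only under identical conventions.
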