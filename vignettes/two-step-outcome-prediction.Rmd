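---
title: "Two-step prediction of neurodevelopmental delay from MRS and DTI characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step prediction of neurodevelopmental delay from MRS and DTI characteristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoprog)
```

## The problem

Very preterm infants (born before 32 gestational weeks) are at elevated risk
of white-matter injury and consequent motor and cognitive delay. At
term-equivalent age, proton MR spectroscopy yields metabolite ratios
(NAA/Cho, NAA/Cr, Cho/Cr, mI/Cr, NAA/mI) and diffusion tensor imaging yields
mean diffusivity (MD, 10⁻³ mm²/s) and fractional anisotropy (FA, unitless in
[0, 1]) in six supraventricular white-matter regions (frontal, central,
parietal; right and left) — 42 candidate characteristics per infant. The
outcome is binary: a Bayley-III scale score below 85 at 12 months corrected
age defines delay.

Two features make this prediction problem awkward for off-the-shelf
classifiers: the outcome is rare (roughly 6–13% of infants), and the number
of candidate characteristics is large relative to the handful of delayed
infants. `neoprog` implements a two-step cascade designed around exactly
this imbalance, together with a synthetic-cohort generator so that every
stage can be exercised and tested without access to patient data.

## The localisation degree

The screening statistic is the *localisation degree* (LD) of a
characteristic. Take the pooled range of the characteristic over all
subjects and cut it into 8 equal-width octiles. The LD is the fraction of
octiles containing at least one *delayed* subject's value:

$$\mathrm{LD} = \frac{\#\{\text{octiles occupied by delayed values}\}}{8}
  \in \{0.125, 0.25, \dots, 1\}.$$

LD = 0.125 means every delayed infant's value falls inside one octile —
the delayed class is strongly localised on that characteristic, which makes
the characteristic a candidate marker. LD = 1 means the delayed values
spread over the whole observed range. Screening keeps characteristics with
LD at or below a threshold and ranks them ascending; the lowest-LD
(strongest-localisation) members form the *inner subset* that feeds the
second stage.

Numerical conventions (all covered by tests):

* Octiles are left-closed half-open eighths of the pooled all-subject
  range; the eighth octile is closed so the maximum belongs to it. A value
  exactly on an internal boundary belongs to the octile on its right.
* A characteristic whose pooled values are all identical has no octile
  grid; `compute_ld()` refuses it as degenerate rather than reporting a
  misleading value.
* LD ties are broken by the smaller relative span of the occupied octiles,
  then lexicographically — the ranking is deterministic.
* Missing values are handled by per-characteristic pairwise deletion, and a
  characteristic is only profiled when at least `min_delayed` (default 3)
  delayed values are observed.
* LD is invariant under strictly increasing affine transforms of a
  characteristic, since the octile grid transforms with the range. This is
  a property test in the suite.

## Step 1: the common relaxed zones

For each selected characteristic the *developmental-delay common relaxed
zone* is the interval

$$[\min(\text{delayed}) - r \cdot R,\; \max(\text{delayed}) + r \cdot R],$$

where $R$ is the characteristic's pooled range in the training data and
$r \ge 0$ is the relaxation (default 0.10). A subject is a zone *member*
when the fraction of zone characteristics whose value falls inside its
interval reaches `membership_fraction` (default 1, a full conjunction).
Non-members are classified as normally developing outright; subjects
missing any zone characteristic are excluded from the analysis set,
mirroring the missing-metabolite-peak exclusions that clinical MRS data
always carry.

The zone is an interval hull of the delayed values rather than the union of
occupied octiles: the screening statistic identifies *where* the delayed
class concentrates, and the dilated hull is the simplest zone consistent
with that, with `relaxation` controlling the safety margin. The occupied
octile mask is retained in every `localisation_profile` should an
octile-union zone be wanted.

Because zones are fitted to the delayed training values, a held-out delayed
subject can fall outside them and be missed at step 1 — a structural false
negative that no step-2 improvement can recover. The evaluation module
accounts for these separately (below).

## Step 2: the network ensemble

Zone members — now a far more balanced set — are classified by an ensemble
of single-hidden-layer feed-forward networks over the inner-subset
characteristics:

* Members are split into 4 stratified folds. For each fold $k$, a *type* of
  100 networks is trained on the other three folds; the 100 networks differ
  only in their random initialisation.
* Inputs are standardised with training-fold means and SDs only.
* Each network outputs two softmax probabilities (summing to 1 within
  1e-9, a tested invariant); a network votes "delayed" when that
  probability is at least 0.5.
* A type votes "delayed" by majority of its networks, with an exact 50/50
  split resolved toward "delayed" — with a rare outcome, a sensitivity-
  favouring tie-break is the clinically safer default.
* The final call is a *two-vote aggregation*: "delayed" when at least 2 of
  the 4 type votes are "delayed".

The networks are trained with `nnet` (logistic hidden units, softmax
outputs, cross-entropy-style fit by BFGS). Regularisation is by weight
decay (default 5e-4) rather than validation-based early stopping: decay
achieves the same capacity control deterministically, and the held-out fold
remains a clean out-of-fold evaluation set. The hidden-layer width defaults
to the number of inputs + 1 (5–6 units for the configurations here); with
4–5 inputs and a few dozen members, anything wider only adds variance.
Delayed members are re-weighted inversely to their prevalence among members
(default on), addressing whatever imbalance survives step 1. All of this is
configurable through `fnn_spec()`; any trainer honouring the determinism
and voting contracts would be interchangeable.

Determinism is end-to-end: the ensemble seed fixes the fold split and every
network initialisation, so identical seeds give identical vote records, and
the pipeline reproduces `metrics.json` byte for byte.

## Evaluation bookkeeping

Sensitivity, specificity, PPV and NPV are computed at two scopes:

* **in-zone** — restricted to DDCRZ members, the set the networks actually
  see;
* **whole data set** — step-1 non-members are counted as predicted-normal,
  so delayed subjects missed by the zones become false negatives and
  outside normals become true negatives.

`whole_from_zone()` performs the corresponding count correction
$(tp, fp, tn + \text{outside normals}, fn + \text{missed delayed})$, and a
property test verifies it agrees with scoring whole-dataset predictions
directly. A metric whose denominator is zero is reported as undefined
(`n/a`), never silently as 0% or 100%. Percentages are rounded half away
from zero to one decimal.

## The synthetic-cohort generator

No patient data ship with the package. `generate_cohort()` emulates the
statistical structure the analysis assumes:

* **Class-conditional normals.** Per-characteristic means and SDs for the
  delayed and non-delayed classes, for the motor and cognitive outcomes,
  ship as packaged CSV tables. Two entries were mechanically corrected (an
  FA mean printed greater than 1, which is impossible for a quantity
  defined on [0, 1], and one malformed SD); every correction — and every
  value kept despite looking suspect — is listed in
  `inst/extdata/table_corrections.csv`.
* **Physical ranges.** FA draws are clamped into [0, 1] and MD draws
  floored at a small positive value; with the packaged means and SDs the
  clamping is a > 4 SD event and does not measurably bias class means (a
  tested property).
* **Rare-outcome imbalance.** Labels are Bernoulli draws at the study
  prevalences: 12.6% (motor, n = 103) and 6.1% (cognitive, n = 115) by
  default.
* **Planted localisation.** A planted characteristic has the delayed
  values redrawn uniformly inside the middle half of a designated octile of
  the non-delayed pooled range. Drawing strictly inside leaves the pooled
  range — and hence the octile grid — unchanged, so the planted LD is
  exactly 0.125 by construction, which the binning oracle in the test suite
  verifies. Under dropout the observed range can shrink and shift the grid
  slightly, so the exactness guarantee is stated for complete data.
* **Missing-peak dropout.** Individual metabolite ratios (never DTI
  values) are erased independently at `dropout_rate`, default 0.007 per
  value. Over 30 metabolite columns this yields ≈ 19% of subjects with at
  least one missing ratio, matching the second-step exclusion rate such
  cohorts typically show.
* **Optional within-region correlation.** The class tables carry no
  covariance information, so characteristics are conditionally independent
  by default; `rho` adds an equicorrelated within-region factor for
  sensitivity analyses. It is a free parameter, not an estimate.
* **Severe-injury flag.** An independent Bernoulli flag (default rate 2/7)
  exists solely to exercise the `exclude_severe` subanalysis toggle.

What the generator does **not** emulate: measurement error correlated
across regions, non-Gaussian tails, any label noise in the Bayley-III
threshold, or a causal link between characteristic values and the label
beyond the class-conditional means. Tests passing on synthetic cohorts
demonstrate that the machinery is correct and recovers planted structure —
not that the clinical effect sizes are reproducible.

## Pipeline defaults and demonstration configurations

`run_config()` defaults: `ld_threshold` 0.375 (at most 3 octiles occupied),
`inner_size` 5 (motor) / 4 (cognitive), `relaxation` 0.10,
`membership_fraction` 1.0, `fit_zones "per_fold"`, 4 folds × 100 networks,
final vote threshold 2. The per-fold protocol rebuilds zones inside each
training split, so a fold-k subject is routed by zones that never saw it,
and network type k trains on the members of its own leak-free zone fit;
`fit_zones = "once"` reproduces the simpler fit-once protocol.

One practical note: with realistic class overlap and ~7–9 selected
characteristics, a full-conjunction membership rule (`membership_fraction
= 1`) can leave no non-delayed members at all — the zones are a product of
many intervals, each capturing 30–80% of normals. The package keeps the
strict default but the demonstration configurations in the README and the
pipeline tests use `membership_fraction = 0.75`, which yields a member set
(≈ 15 delayed + ≈ 12 normals at the motor conditions) comparable to what a
partial rule produces on real cohorts. The single global seed fans out to
per-stage seeds so stages can be re-run in isolation.

## Problem sizes used by the test suite

The suite regenerates everything in code: LD oracle equivalence on 1,000
random instances; planted-characteristic recovery on 100 cohorts of
n = 103 at 12.6% prevalence (all three planted characteristics rank in the
LD top 7 in ≥ 90% of cohorts); ensemble parameter recovery on 20 seeded
cohorts of n = 80 with a 2-SD class shift on the five inner characteristics
(mean out-of-fold sensitivity and specificity ≥ 0.9, 4 × 100 networks per
seed); and byte-identical reruns of the full pipeline. These sizes keep the
whole suite around a minute on a single core while leaving each claim
statistically meaningful.

## Known limitations

* The LD reading (octile occupancy over the pooled range) and the
  interval-hull zone construction are the package's own formalisation of a
  procedure usually described only qualitatively; the occupied-octile mask
  and the `fit_zones` / `membership_fraction` switches expose the main
  alternatives.
* The 100 networks of a type differ by initialisation only; a bagging
  variant would be a natural extension.
* No confidence intervals accompany the four metrics, and no ROC analysis
  is provided — with a handful of delayed subjects, interval estimates
  would be dominated by the prior, and the cascade has no single threshold
  to sweep.
* Characteristic independence within a class is an idealisation; `rho`
  provides a one-parameter robustness check, not a fitted covariance.
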