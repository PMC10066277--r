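---
title: "Testing neural compensation with a classifier-derived language phenotype"
author: "phenoconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing neural compensation with a classifier-derived language phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoconn)
```

## The scientific question

In two-group neuroimaging studies of spontaneous social behavior, an
atypical pattern of functional connectivity can mean two very different
things: it can reflect a core deficit, or it can *compensate* for one —
an alternative neural strategy that makes overt behavior look more
typical.  Distinguishing the two requires (a) a quantitative, observer-
independent measure of how typical a participant's spontaneous behavior
is, and (b) a test of whether connectivity tracks that measure
differently in the two groups.  The compensation signature is a positive
relationship between connectivity and behavioral typicality *in the case
group only*: participants whose overt behavior most resembles the
control group show the most elevated connectivity, while controls — who
have nothing to compensate for — show no such relationship.

phenoconn implements this two-sided inference as a reusable pipeline:

1. **Language phenotype.** Per-conversation linguistic feature vectors
   (e.g. the 81 word-category variables of a dictionary-based text
   analysis) are z-scored and classified by diagnosis with a linear
   support vector machine in a leave-one-out loop.  The cross-validated
   decision values are mapped to posterior probabilities with a Platt
   sigmoid, averaged within participant into a *composite classifier
   score* in [0, 1] (higher = more control-like language), validated by
   permutation testing, ROC analysis and rank correlation with a
   clinician-rated severity score, and protected by a negative control
   run on the conversation partner's speech.
2. **Connectedness mapping.** Each conversation scan's parcellated time
   series yields a *whole-brain connectedness map*: node i stores the
   mean correlation of node i with every other node.  Maps are
   contrasted between groups node-wise with a linear mixed-effects model
   (`connectedness ~ group + age + motion + (1 | participant)`), and a
   ladder of voxelwise thresholds with permutation-calibrated cluster
   extents is combined into a robustness map from which ROIs are
   selected (clusters that survive every threshold with at least 10
   nodes).
3. **Compensation test.** Per ROI, `connectivity ~ score * group` (plus
   covariates and a participant random intercept) tests the group-by-
   score interaction at a Bonferroni-corrected alpha, with per-group
   Pearson correlations reported for interpretation; a seed-based
   follow-up contrast maps which nodes drive an ROI's over-connectivity
   and counts them by hemisphere.

## The classifier score

Conversations — not participants — are the classification unit: each of
the ~115 usable conversations is scored by a model trained on all the
others, which maximizes training data at the cost of treating repeated
conversations from one participant as independent (a deliberate choice,
exposed by the `grouped = TRUE` option which holds out whole
participants instead).  Features are z-scored **once, on the full
table, before cross-validation**, mirroring the reference protocol's
order of operations; `per_fold_standardize = TRUE` provides the
leakage-free variant for comparison.  The SVM cost parameter defaults to
1, the reference implementation's default, and the solver is an exact
sequential-minimal-optimization dual solver on a precomputed linear
kernel (tolerance `1e-5` on the maximal Karush–Kuhn–Tucker violation),
cross-checked in the test suite against an independent SVM
implementation and a brute-force convex minimizer of the primal.

Posterior calibration fits one two-parameter sigmoid to the pooled
cross-validated decision values by maximum likelihood with the standard
smoothed targets, then applies it to each held-out decision value.  Two
consequences are worth knowing:

* Calibrating on cross-validated scores of the *same* data means the
  sigmoid can learn, and invert, the slight anti-predictive bias that
  leave-one-out decision values carry under the null (removing a
  conversation tilts its fold's training set toward the other group).
  On pure-noise features the composite accuracy therefore centers near
  60–65%, **not** 50%.  This is a property of the calibrated-composite
  statistic itself, not of our implementation; it is why the
  significance test is a label permutation test, whose null
  distribution carries exactly the same bias, and it is consistent with
  "chance-level" negative controls landing near 59% rather than 50%.
* A composite exactly at the cutoff (0.5) is classified as control: only
  composites *lower than* the cutoff predict the case group.

The permutation test relabels at the participant level (all of a
participant's conversations move together, so group sizes are exactly
preserved), reruns the entire classify-calibrate-composite chain
against the permuted labels, and reports the proportion of permutations
whose accuracy strictly exceeds the observed accuracy, alongside the
add-one smoothed estimator `(#\{null >= obs\} + 1) / (n + 1)` which can
never be zero.  Severity validation uses Spearman rank correlation with
average ranks for ties (exact p by enumeration for n <= 9 without ties,
t approximation otherwise); the ROC AUC is computed by the trapezoidal
rule and equals the case/control rank-sum probability.

## Connectedness and the robustness map

Connectedness averages raw correlations by default — Fisher-z averaging
is available as a flag and the two scales are never mixed within one
contrast (enforced by a scale tag on every map).  Constant nodes
receive `NA` and drop out of the other nodes' averages.  The voxel grid
of the original procedure is abstracted to parcels/nodes; adjacency for
clustering comes from an edge list or a coordinate radius rule.

The node-wise group model is fitted by REML.  Degrees of freedom for
the group effect use the Satterthwaite approximation by default: the
group effect is a between-participant quantity, and a scan-level
residual df (~3x larger) would overstate the evidence; the residual-df
convention remains available (`df_method = "residual"`).  Singular fits
(random-intercept variance indistinguishable from zero, common at null
nodes) fall back to ordinary regression on participant-averaged maps
and are flagged per node.

Cluster extents are calibrated by participant-level group-label
permutation rather than by smooth-noise simulation from an estimated
spatial autocorrelation function: we have no empirical ACF at desk
scale, and the permutation null targets the same familywise error while
being data-driven.  The permutation engine is the participant-averaged
ordinary regression — scans within participant are exchangeable
summaries, and one calibration runs ~1000 * |thresholds| model fits,
where the mixed model would add nothing but cost.  For each voxelwise
alpha the minimum extent k is the 95th percentile of the null
maximum-cluster-size distribution; because supra-threshold maps are
nested along the descending threshold ladder
(0.005, 0.001, 0.0005, 0.0001, 0.00005, 0.00001), k is automatically
non-increasing with stringency.  The extent table also accepts
externally supplied k values verbatim, so a published ladder (e.g.
k >= 51, 22, 15, 7, 5, 2) can be reproduced exactly.  Thresholding is
one-sided in the case > control direction — the direction of the
contrast under test — while two-sided p-values are reported per node
for transparency.

## The compensation test

The interaction model runs at scan level with a participant random
intercept by default; `level = "participant"` averages a participant's
scans first and fits ordinary least squares, reproducing the
participant-level degrees of freedom (n - 4 with no covariates, e.g.
t(35) at n = 39) that published analyses of this design report.  Age
and motion enter whenever a covariate table is supplied; passing
`covariates = NULL` preserves the minimal `score * group` reading.  The
Bonferroni threshold is alpha divided by the number of ROIs tested
(0.05 / 3 = 0.0167 at three ROIs), kept unrounded internally.

Under a fully exchangeable null (no planted slope anywhere) the
interaction test's empirical type-I error in our validation runs is
~0.06–0.07 at nominal 0.05 (400 null replicates at the study's sample
size): a small liberal bias attributable to the estimated composite
entering as a regressor with group-dependent distribution.  Practical
conclusions at the Bonferroni-corrected threshold are insensitive to an
inflation of this size, but exact calibration at small n should not be
assumed.

Seed-correlation values are Fisher-z transformed before the seed-map
group model (variance stabilization); hemisphere counts are taken on
the thresholded significant set, with unlabeled nodes excluded from the
counts (warned) but kept in the set, and the left/right ratio reported
as infinite-with-flag when no right-hemisphere node is significant.

## The synthetic-data generator

No transcript or imaging data are deposited for this design, so the
generator is a first-class module that plants every structure the
analysis is supposed to detect, with ground truth stored alongside (and
never consumed by pipeline stages).

* **Cohort.** 19 case / 20 control male-cohort analog, ages uniform on
  14.7–32.0 years, participant motion log-normal (median 0.1, sdlog
  0.4 — a typical framewise-displacement-like scale in mm).  Each
  participant carries a scalar latent trait theta ~ N(±delta, 1)
  (control +, case −): the one-dimensional "typicality of language
  behavior" that the classifier score estimates.
* **Features.** 81 columns, 20 informative: informative feature j of
  participant i has mean `0.5 * theta_i` plus a participant random
  effect (SD 0.5) shared across that participant's 3 conversations and
  conversation noise (SD 1).  `delta = 0.7` by default: a pilot
  calibration (15 cohorts per candidate delta) put the leave-one-out
  composite accuracy at 65/70/73/77% for delta = 0.4/0.5/0.6/0.7, so
  0.7 lands the defaults in the realistic 70–85% band for this kind of
  classifier.  No claim is made that this matches the real
  data-generating process; it only makes the pipeline's operating
  point realistic.
* **Severity.** Case group only (the ADOS-2-like instrument is
  administered only to case participants), ordinal 7–14 with 7 as the
  diagnostic floor, generated by ranking
  `-(lambda * theta_z + sqrt(1 - lambda^2) * noise)` onto the integer
  scale.  `lambda = 0.6` yields recovered rank correlations near the
  −0.5 scale reported for such validations; lambda = 1 with few enough
  participants to avoid binning ties gives exactly −1.
* **Time series.** A factor model guarantees a valid joint covariance
  by construction: every node loads `sqrt(0.1)` on a global factor
  (background correlation 0.10), and the compensation and partner node
  sets share a region factor with control loading 0.30 and case loading
  `0.30 + 0.30 + 0.10 * theta` (clipped so a² + c² < 1; residual
  variance tops marginals up to 1).  Planted pairwise correlations are
  therefore `0.1 + c_i * c_j` within the region set and 0.1 elsewhere,
  and the planted expected connectedness of a member node is available
  in closed form (`planted_expected_connectedness()`), which is the
  oracle for the parameter-recovery tests.  180 timepoints emulate
  6-minute conversation runs at a 2-s sampling interval.  Scans omit
  rest padding and hemodynamics: the generator validates the
  *statistics* of the pipeline, not fMRI physics, so passing tests
  demonstrate correct inference on data satisfying the model's
  assumptions — not robustness to realistic fMRI noise spectra or
  motion artifacts.

All randomness descends from one master seed through named substreams
(`substream_seed(seed, "cohort")`, "features", "severity",
"timeseries", "permutation", "extent_calibration"), so adding or
rerunning a stage never perturbs the others and every output is exactly
reproducible from its manifest.

## Numerical choices and edge cases

* Tables are UTF-8 TSV with reals printed to 17 significant digits;
  read-write-read round-trips are lossless to < 1e-9.
* Z-scoring uses the sample SD (n − 1); constant feature columns are
  dropped with a warning, constant nodes flagged.
* The SMO solver's bias term is the midpoint of the KKT interval; when
  a training fold leaves no free support vector the bias is genuinely
  non-unique (an interval), which the oracle tests acknowledge by
  comparing the unique weight vector and objective instead.
* Correlations of exactly ±1 are clamped inside (−1, 1) before the
  Fisher transform; posteriors are clamped to (1e-12, 1 − 1e-12).
* Group labels are arbitrary strings; the configuration names the case
  group, and every signed quantity (decision values, contrasts,
  interactions) is oriented case-vs-control explicitly rather than by
  factor-level accident.

## Problem sizes used in validation

The shipped validation suite exercises the pipeline at desk scale:
50-scan connectedness oracles (≤ 30 nodes × ≤ 200 timepoints), 200
null cohorts of 20 participants × 2 conversations × 10 features with
99 permutations each for permutation-test calibration, a 10,000-draw
Monte-Carlo check against the exhaustive 6-relabeling null of a
4-participant cohort, 200 replicates of the full compensation recovery
at the cohort's size (39 participants, 3 scans, 30 nodes) plus 200
equal-slope nulls, 50 replicates of the three-region ROI pipeline at 50
nodes (with 50 global-null replicates), and 100 replicates of the 2:1
hemisphere-asymmetry recovery at 40 nodes.  These sizes were chosen to
give stable Monte-Carlo estimates of each rate being checked while
keeping the whole suite runnable on a laptop in well under half an
hour.

## Known limitations

* The zero-signal composite accuracy sits above 50% by construction of
  the calibrated composite (see above); only the permutation p-value —
  not raw accuracy against a 50% baseline — should be used for
  inference, exactly as the pipeline does.
* The latent trait is scalar and features carry no group information
  beyond it, so the achievable composite accuracy is capped at
  `pnorm(delta)`; simulated "separable" cohorts must raise delta, not
  feature count.
* The group-by-score interaction test runs slightly liberal (~0.065 at
  nominal 0.05) with estimated composites at n = 39.
* Node-scale clustering with radius adjacency is a coarse abstraction
  of voxel-scale cluster-extent inference; anatomical claims about
  selected ROIs are out of scope.
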