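---
title: "Models and methods behind goalddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind goalddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(goalddm)
```

goalddm studies how regulatory goals ("focus on the food's healthiness",
"focus on your partner's feelings") reshape value-based choice, at two
levels: a behavioral accumulator model that measures how much weight each
choice attribute carries under each goal, and a multivoxel decoding stack
that asks where neural patterns carry attribute information and how that
information changes with the goal. This vignette documents the models,
their assumptions, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The multi-attribute accumulator

Each trial offers an on-screen option against a fixed default (a neutral
food; a $20/$20 split). A relative decision value (RDV) starts at 0 and
takes discrete steps of `dt` seconds once the non-decision time `ndt` has
elapsed:

RDV(t+dt) = RDV(t) + sum_a w_a * x_a + e,   e ~ Normal(0, noise_sd)

where `x_a` are the trial's attribute values and `w_a` the subject's
condition-specific weights. "Yes" is emitted when the RDV reaches the
upper bound, "no" at the lower bound. Both bounds sit at +/- `bound0`
initially and collapse exponentially toward zero at rate `decay` (per
second) as the 4-second response deadline approaches, reflecting the
growing urgency of late responses. Trials that never cross are missed
responses, retained in the likelihood as the probability mass of reaching
the deadline.

Parameters and conventions:

* `weights` — drift per attribute unit per step. Free; food task has two
  (tastiness, healthiness), altruism three ($self, $other, fairness), so
  the fitted models have 5 and 6 free parameters respectively.
* `ndt` — seconds, free, box [0.1, 1.5].
* `bound0` — free, box [0.2, 3]. `decay` — 1/s, free, box [0, 2]. The
  collapse form `bound0 * exp(-decay * (t - ndt))` is the simplest shape
  consistent with an exponential decay toward zero.
* `noise_sd = 0.1` per step and `dt = 0.008` s are fixed scaling
  conventions, not fitted: they set the unit in which weights are read.
  With these constants, weights of magnitude ~0.01 per step produce
  choices and 0.5–2.5 s response times inside the 4 s deadline at
  `bound0` near 1, matching the magnitudes the fitted weight tables are
  reported on. Both are config-exposed.

### Attribute coding

Food ratings enter as integers −2..+2 around the neutral default food
(recoded from 5-point scales). Because the choice is always
accept-the-proposal-versus-default, altruism payoffs enter the drift
relative to the default allocation: `self − 20` and `other − 20` dollars
(`recode_attributes()`, reference config-exposed). Fairness,
`-|self - other|`, is zero at the default and needs no shift. Raw-dollar
coding would add a constant acceptance bias of roughly 0.18 per step at
the default — an accumulator that accepts nearly every proposal and makes
the weights practically unidentifiable at the precision we target.
Dataset files always keep raw $0–40 payoffs; recoding happens at model
entry. Ratings are not mean-centered per subject: the −2..+2 coding is
already default-relative.

### The likelihood

The joint density of (choice, RT bin) is computed by deterministic
forward propagation of the discretized accumulator: the RDV is binned on
a 201-point grid spanning ±1.2 `bound0`, each step convolves the interior
mass with the per-step Gaussian kernel (drift-shifted, cell-integrated),
and mass at or beyond the current bound is absorbed into the RT bin (50
ms) of that step. Kernel tails beyond 5 SD are folded onto the nearest
grid edge, which lies beyond the bound, so probability is conserved
exactly; propagation stops early once interior mass falls below 1e−12.
This scheme is deterministic and testable: against 10^6-draw Monte-Carlo
histograms of the identical walk the maximum per-bin discrepancy is
about 0.0015 at the default resolution (tested at < 0.005). A grid too
coarse to resolve the bound (fewer than 3 grid steps) is rejected.

Absorption at the bound is fractional in the grid cell that straddles
it (cell mass is treated as uniformly spread), so the likelihood varies
continuously with the bound parameters rather than jumping as the bound
crosses grid points; this also halves the Monte-Carlo discrepancy.
Per-trial densities are cached per distinct drift value (at most 25 for
the food rating grid, at most 90 for altruism proposals), missed trials
contribute the deadline mass, and zero densities are floored at 1e−10
so the optimizer never sees −Inf. The fitted likelihood additionally
mixes in a small uniform contaminant over the outcome space (weight
0.005 by default, 0 for the pure density): a single fast response that
the current parameters deem impossible otherwise carves a −23-nat cliff
into the surface, and such cliffs trapped every optimizer variant we
tried. This is the standard robustness device for response-time model
fitting, and at 0.005 it produces no measurable shrinkage of recovered
weights. The fitting default uses a 121-point RDV grid (the density API
default is 201): in recovery pilots a 101-point grid visibly biased the
altruism weights downward while 121 left bias within sampling noise.

### Fitting

`fit_ddm()` maximizes this likelihood per subject × condition by staged
derivative-free search (BOBYQA, on rescaled coordinates so every
parameter moves on a comparable scale) inside box constraints. The
stages address two specific pathologies we observed: the likelihood
climbs steeply toward a cliff where the non-decision time meets the
fastest observed response, and the weight/bound ridge of the
6-parameter altruism model stalls a single full-space run started far
from the valley.

1. *Informed weight start.* A logistic regression of choice on
   attributes, rescaled by `noise_sd^2 / 2` (the random-walk absorption
   relation at unit bound); under separation the ratios are kept and
   the magnitude capped.
2. *Weights-only search* at candidate non-decision times anchored just
   below the fastest response (min RT − 0.03 and − 0.15 s), bound 1,
   decay 0.5 — a well-conditioned low-dimensional subproblem run from
   both the informed weights and zero.
3. *Full-vector refinement* from the winning seed.
4. *Screened safety net*: 10 Latin-hypercube starts get one evaluation
   each, and earn a full refinement only if they already beat the
   refined optimum.
5. *Coordinate cycles* (weights-only, then shape-only) when the
   refinement exhausted its evaluation budget, and a short final
   polish.

We moved from a Nelder-Mead simplex to BOBYQA after the simplex
reliably stalled on the altruism ridge, biasing recovered weights by
more than the 0.002 tolerance we hold ourselves to. The weight box is
[−0.05, 0.05] per step, an order of magnitude wider than the
cohort-mean magnitudes.

In simulation-recovery studies at the cohort-mean weights (20 subjects ×
90 trials per condition, the study's trial budget), the mean recovered
weight of every reported attribute lands within 0.002 of its generating
value; `scripts/acceptance.R` re-runs exactly this study.

### Behavioral scoring

A healthy choice accepts an on-screen food healthier than the default or
rejects a less healthy one; equal-health trials are undefined and
excluded from percentages (the definition is strict on "healthier").
An altruistic choice accepts a proposal favoring the partner or rejects
one favoring the self; every proposal trades off one party against the
other around the default, and violations of that structure are rejected
as invalid stimuli. Regulatory success is the condition difference of
percent goal-consistent choices (e.g. HC − NC), or of fitted weights.
Condition effects on weights use a one-way within-subject ANOVA
(F = MS_condition / MS_condition×subject) with pairwise paired t-tests,
Bonferroni-corrected by the number of pairs; cross-task consistency uses
Pearson or partial correlations (residualizing on the between-task
delay).

## The synthetic cohort

The generator emulates the study conditions the analyses assume: 36
subjects by default (config up to 49), two tasks, three conditions of 90
trials in 9 runs of 10, food items covering the 5 × 5 rating grid
roughly uniformly, altruism proposals on the trade-off-constrained
integer $0–40 grid around ($20, $20), and per-condition cohort-mean
weights (with between-subject SDs) at the magnitudes of the fitted
group tables. Proposal selection mimics the adaptive design: a
two-weight logistic fit to natural-condition choices picks the 30% of
candidates most likely to elicit generous responses and the 30% most
likely to elicit selfish ones (floored), the remainder drawn uniformly;
separation falls back to fully random selection with a warning.

Trial-wise voxel patterns are generated directly — no hemodynamic
convolution or GLM inversion, since the decoding stack consumes
trial-wise estimates and GLM estimation is out of scope. Each spherical
region carries one independent unit-norm code vector per attribute;
trial t in condition c contributes
`gain(region, attr, c) * code * x_attr(t)` plus isotropic Gaussian
noise. The planted signal-to-noise ratio is therefore
`gain * sd(attribute) / noise_sd`. A success-coding ROI plants
subject-level scores along a common direction with slope `beta`. Signal
regions in generalization analyses should hold on the order of a
hundred voxels or more, as the cortical clusters they emulate do: in
much smaller regions the chance overlap of independently drawn code
vectors (|cos| about 1/sqrt(n) voxels) itself produces cross-attribute
transfer and blurs the attribute-specificity the codes are meant to
carry. What the generator does *not* emulate — temporal autocorrelation, scanner
drift, motion, spatially correlated noise, hemodynamic blurring —
bounds what passing tests show: they validate the estimators and their
calibration under the assumed generative structure, not robustness to
real fMRI artifacts.

## Decoding

Searchlights collect all in-mask voxels within a Euclidean radius of 4
voxels of each center (257 in the interior); edge spheres are truncated
rather than dropped, with centers below 10 members marked missing.
Decoding is a linear nu-SVR with cost 0.01; nu is not part of the
decoding convention we inherit, so it stays at libsvm's 0.5 and is
config-exposed. Patterns enter unscaled (standardization is an option,
off by default). Accuracy is the run-wise leave-one-run-out (9-fold)
mean of Fisher-z-transformed correlations between predicted and actual
labels; undefined fold correlations count as 0 and |r| is clipped at
0.999 before `atanh` so maps stay finite. Accuracy maps — never trial
patterns — are smoothed with a 6 mm FWHM Gaussian, mask-renormalized so
constants are preserved at edges.

Cross-condition generalization trains on all trials of one
(attribute, condition) cell and tests on another, averaging the two
directions' Fisher-z values; cells sharing trials (the diagonal, and
same-condition attribute pairs) use odd/even-run split halves, averaged
across the two half assignments. Per-cell significance compares the
observed statistic with the 95th percentile of a label-permutation null
that re-runs the full cell computation (default 1000 permutations).

## Group inference and success decoding

Main effects average each subject's condition maps and test against
chance (0) with a voxelwise one-sample t; condition effects use the
voxelwise within-subject ANOVA, with directed contrasts (e.g.
HC − mean(NC, TC)) tested one-tailed because the hypotheses are
directional. Cluster-level family-wise error is controlled by
permutation of the maximum cluster size — sign-flipping of subject
values for t maps, within-subject condition-label permutation for F
maps — at a voxel height threshold of p < 0.001 and cluster alpha 0.05.
We use permutation rather than random-field theory deliberately: it is
assumption-light, exact under exchangeability, and self-contained.
Clusters use 26-neighborhood connectivity. Conjunctions intersect
independently corrected masks (minimum-statistic logic); they are
order-invariant and monotone.

Cross-subject success decoding represents each subject by the zero-sum
contrast combination of condition-mean patterns over an ROI (e.g.
+1, −0.5, −0.5), standardizes each voxel on training subjects only
(leakage-safe; the full-dataset alternative would leak the held-out
subject's mean), and predicts the held-out subject's success score with
the same linear nu-SVR in a leave-one-subject-out loop. Accuracy is the
plain Pearson correlation of predicted and observed scores; inference
permutes the pattern/score pairing and re-runs the entire
leave-one-subject-out loop per permutation (1000 by default), with the
add-one p-value and the 95th-percentile significance rule. Note that
leave-one-subject-out correlations are negatively biased under the
null (each held-out prediction is anticorrelated with the training
mean), which is exactly why inference runs through the permutation
null rather than a parametric test on r: the null distribution carries
the same bias and the 95th-percentile rule stays calibrated.

## Numerical choices and degenerate inputs

* RT bin assignment adds 1e−9 s before flooring so step times landing on
  bin edges bin identically in the density and in observed data.
* Ties: equal-health trials are undefined; undefined fold correlations
  score 0; weights exactly at a box edge are accepted but flagged by the
  convergence indicator.
* Missed-trial rates above 20% trigger a warning but the fit proceeds.
* Subjects with invariant choice behavior survive fitting (the logistic
  informed start falls back to zero weights); cohort-level exclusion is
  left to the analyst with `percent_goal_choices()` as the screen.
* All generators draw from R's RNG, so a single `set.seed()` makes every
  artifact bit-reproducible; `run_pipeline()` derives each stage's
  stream from the master seed.

## Problem sizes in the test-suite

The unit and acceptance tests run the full designs where they are cheap
(the density-versus-simulation comparison uses the full 10 parameter
sets × 10^6 draws; cluster-level calibration uses 200 replicates) and
reduced cohorts where fitting dominates (8 simulated subjects per
condition in the in-suite recovery check, against the same 0.002
tolerance; the full 20-subject recovery study is what
`scripts/acceptance.R` executes). Decoding calibration uses 400 noise
decodes against a 400-permutation cutoff; volumes in tests are 8–12
voxels per side with radius-2 searchlights, which preserves every
geometric property of the radius-4 production setting at a fraction of
the sphere volume.

## Known limitations

* The accumulator has no across-trial drift or starting-point
  variability and models the four-button response collapsed to yes/no.
* The likelihood's state discretization introduces bias well below the
  recovery tolerance at the default grid, but very small bounds
  (`bound0` < 3 grid steps) are rejected rather than approximated.
* Group inference assumes exchangeable subjects; the permutation
  schemes do not model session or order effects.
* The synthetic fMRI noise model is white; decoding accuracies on real
  data will be lower and spatially structured.
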