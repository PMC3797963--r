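---
title: "Time-resolved category discriminability and decoding for MEG epochs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved category discriminability and decoding for MEG epochs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catmeg)
```

## What the package computes

`catmeg` implements the statistical core of a feedback-driven visual
category-learning experiment recorded with MEG: two visually-similar "blob"
categories are learned over a 600-trial session, and the multichannel neural
response is asked, millisecond by millisecond, (i) *whether* it discriminates
the two categories (a time-resolved multivariate test), (ii) *when* that
discriminability is statistically credible (an excursion permutation test),
and (iii) *how well* held-out single trials can be classified per cortical
region and latency window, early versus late in learning (leave-one-trial-out
logistic decoding). Because no recordings are distributed with the package,
a synthetic MEG generator reproduces the statistical structure the analysis
assumes, so every stage is testable end to end.

## The stimulus model

Each blob is a 20-edge polygon: vertex $k$ sits at angle $2\pi k/20$ at a
distance $e_k \in (0,1)$ from the origin. A category is a multivariate
Gaussian over the edge vector $e \in \mathbb{R}^{20}$: mean = the category
prototype (each coordinate uniform on $[0.3, 0.7]$), covariance diagonal with

$$\sigma_k = 0.2 \, |a_k - b_k|,$$

where $a, b$ are the two prototypes. Jitter therefore scales per edge with
how far the categories are apart on that edge. The published description is
dimensionally ambiguous about whether the 20% proportionality applies to the
standard deviation or to the variance; we adopt the standard-deviation
reading because it reproduces the published stimulus-space geometry — a
pooled PCA of 600 exemplars then concentrates $\approx 90\%$ of the variance
in the first two components, with the first component essentially equal to
the normalized prototype difference (the package's tests verify cosine
similarity $> 0.95$). The variance reading produces a nearly isotropic cloud
with $\approx 20\%$ in two components and visually indistinct categories.
"The two exemplars" whose difference sets the covariance is read as the two
prototypes, the only distinguished pair. Out-of-range edges (outside
$(0.05, 0.95)$) are resampled per edge with a retry cap, preserving the
Gaussian bulk while guaranteeing renderable polygons.

The presentation order balances categories within each of 5 session blocks.
Because the learning-phase analyses require the first and last 100 trials to
contain equal numbers of A and B trials, balance is additionally enforced in
20-trial sub-blocks (10 A + 10 B) whenever block sizes divide evenly; any
100-trial prefix or suffix of the default design is then exactly balanced.
Trial indices are 1-based throughout.

## The synthetic MEG generator

Epochs span $-120$ to $400$ ms around stimulus onset, by default sampled at
5 ms (the analysis grid is 10 ms, so 5 ms sampling is lossless for the
binned statistics; 1 ms is supported). Sensor space has 102 magnetometer
channels; source space has 24 region-bounded dipole ensembles — 12 ventral
visual pathway (VVP) and 12 prefrontal (PFC) regions, 16 dipoles each by
default.

Noise is Gaussian, temporally smoothed by a 25 ms moving average (rescaled
to unit marginal variance), emulating the 0.1–50 Hz recording band at desk
scale; a per-trial, per-channel constant offset (sd 0.5) emulates slow
drift, so baseline removal is exercised — a constant offset is removed
*exactly* by subtracting the $[-120, 0)$ ms mean. This is the simplest noise
model under which the Hotelling null is exact, which is what the calibration
tests require.

A category effect is `sign(category) × amplitude × learning(trial) ×
pattern(channel) × bump(time)`: a unit-norm spatial loading, a raised-cosine
temporal envelope confined to a configurable latency window (smooth
onset/offset avoids edge artifacts in the 20 ms bins; the envelope is
identically zero outside its window), and a logistic learning curve
`floor + (ceiling − floor) / (1 + exp(−rate (t − midpoint)))` over the trial
index. `floor > ceiling` gives an effect that *decays* with learning.

The default scenario mirrors the experiment's headline finding: the left
inferior-temporal region carries a 150–250 ms effect ramping from 0.05 to
1.0 of its amplitude (midpoint trial 300, rate 0.02/trial), the left pars
orbitalis carries a 250–350 ms effect decaying from 1.0 to 0.2; all other
regions are pure noise. Effect amplitudes are free parameters of the
simulation — the experiment they emulate published no SNR — and were fixed
once from a pilot simulation at VVP 1.8 and PFC 1.5 (noise sd 1), putting
late-phase decoding in the target cell well above chance (≈ 0.85–1.0) while
early-phase decoding stays near chance. What passing tests show is that the
*pipeline recovers what was injected* under this noise model; they cannot
certify performance on real recordings, whose noise is neither Gaussian,
stationary, nor spatially white.

## The discriminability trace

Preprocessing: per-trial baseline removal over $[-120, 0)$ ms, then means
within half-open 20 ms windows stepped by 10 ms across $[0, 400)$ ms — 39
bins labeled by their centers 10, 20, …, 390 ms. (The published description
mentions both "10 ms windows" and a "20 ms window in steps of 10 ms"; we
follow the more specific parenthetical. Whether bins start at 0 or are
centered on it is not stated; the half-open left-edge grid is this package's
convention.)

Per bin, the pooled trials × channels matrix is centered and projected onto
the leading principal components holding at least 99% of the variance
(capped at $n_A + n_B - 2$ so the pooled covariance stays invertible; cap
events are recorded), and the two-sample Hotelling statistic is computed:

$$T^2 = \frac{n_A n_B}{n_A + n_B} \, \delta^\top S^{-1} \delta,$$

with $\delta$ the mean difference and $S$ the pooled covariance of the
projected vectors. $T^2$ is reported as a $\chi^2$ statistic against the
asymptotic $\chi^2_p$ reference; at the trial counts used here
($n \ge 200$) the exact-F correction changes the 95th percentile by under
10% and is available via `f_correct = TRUE` for sensitivity analysis. The
retained dimensionality is recorded per bin, so null comparisons are
dimension-matched by construction.

The chance reference is the same trace computed under label permutations
(100 by default, preserving the label multiset). The per-bin PCA is fit on
the *pooled* matrix, which permutation leaves unchanged, so refitting the
projection inside each permutation returns the identical projection; the
implementation computes it once per bin and reuses it — an exact
equivalence, not an approximation.

## Excursion inference and group combination

The trace is thresholded (default 20, the published source-space value) and
maximal runs of $\ge 2$ consecutive supra-threshold bins become candidate
regions; isolated single bins are pruned as likely chance events. Each
region's mass is the sum of the statistic over its run. The permutation
summary is the **maximum region mass** (the standard max-statistic
construction controlling family-wise error over time; a total-mass variant
is available), and

$$p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{N + 1},$$

so with $N = 100$ permutations the smallest attainable $p$ is $1/101$ and
$p$ is never 0. An empty observed region set yields $p = 1$. This convention
is corroborated by the group bound: Fisher's method,
$-2\sum_i \ln p_i \sim \chi^2_{2k}$, applied to seven subject minima of
$1/101$ gives $1.794\times 10^{-8}$ — the published group-level bound to
three digits.

## Decoding

Per region, latency window (baseline 0–50, M100 50–150, M200 150–250, M300
250–350 ms; half-open) and learning phase (first/last 100 trials): dipole
time courses are window-averaged to one feature per dipole, projected at 99%
variance, and category is predicted for each trial by a logistic model fit
on the remaining trials (leave-one-trial-out). The projection is fit once
per phase *before* cross-validation, replicating the published order of
operations; this leaks marginal (label-free) covariance information into the
folds, which is harmless at chance level but is documented, and a fold-wise
refit (`refit_pca = TRUE`) is provided. Fitting is maximum likelihood
(Newton/IRLS, warm-started); under complete separation the iteration cap
returns a finite fit whose class predictions are already exact, and on
breakdown a small ridge (10⁻³, intercept excluded) stabilizes the fit and
the event is counted. A predicted probability of exactly 0.5 deterministically
predicts category A.

Early-vs-late changes within one simulated subject use two-proportion tests
on the correct counts (the published cross-subject $t$-tests need multiple
subjects; the multi-seed drivers under `analysis/` aggregate across
simulated subjects with paired $t$-tests to mirror them). Pathway pooling is
the trial-weighted pooled accuracy (total correct / total trials) over the
12 VVP or 12 PFC regions. No multiple-testing correction is applied across
the 192-cell grid, matching the per-cell reporting convention; a Bonferroni
adjustment is one `p.adjust()` call away.

## Numerical and design choices

- **Dimensionality defaults.** 16 dipoles per region: a realistic
  downsampled ensemble for 5 mm dipole spacing, and large enough that the
  99%-variance projection of null data retains enough dimensions for the
  $\chi^2$ trace to cross the threshold of 20 regularly — this keeps the
  permutation distribution of the excursion summary continuous, which is
  what makes the test exactly calibrated (ties occur only at zero mass).
- **Seeds.** Every simulation function takes an explicit seed;
  `run_pipeline()` derives per-subject, per-stage streams from one master
  seed by a fixed affine rule, so runs are byte-identical.
- **Degenerate inputs.** Zero-variance matrices, single-label decoding
  inputs, missing baselines, infeasible prototype separations, and
  non-divisible block sizes all fail fast with the offending stage or cell
  named.
- **Problem sizes.** The package's own test suite runs the full study
  conditions where the science requires them (600-trial sessions, the
  24-region layout, 100 permutations, 20-seed recovery runs) and miniature
  versions (3 regions × 40 trials) where only the plumbing is under test.

## Known limitations

- The noise model is spatially white and stationary; real MEG noise is
  neither. Calibration results transfer only to the extent the Hotelling
  statistic is robust to those violations.
- The chance-level calibration of leave-one-out decoding uses labels
  shuffled within each decoded trial set (the phase), mirroring the
  permutation null of the trace analysis. Even so, LOO accuracy on null
  data is *overdispersed* relative to a binomial reference — held-out
  predictions share almost all their training data and are positively
  correlated — and slightly pessimistic (each held-out trial's class is the
  training minority). In 1000 Monte-Carlo replicates (100 trials × 16 noise
  features) the accuracy distribution has mean 0.488 and sd 0.067, against
  the binomial sd of 0.050; about 12% of null cells fall outside the central
  95% binomial band rather than 5%. Binomial bands around 0.5 are therefore
  a conservative *screen*, not an exact null, for LOO accuracies.
- Source localization is emulated, not performed: region ensembles stand in
  for minimum-norm dipole estimates, so anything concerning inverse-problem
  leakage between regions is out of scope.
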