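# catmeg

Time-resolved category discriminability and decoding for MEG epochs.

## The problem

When people learn to tell two visually-similar categories apart — two
families of jittered "blob" polygons whose members differ only in subtle
edge proportions — which cortical signals come to carry the category, and
when? Answering that from magnetoencephalography (MEG) takes three
statistical ingredients, all implemented here for anyone analyzing (or
simulating) multichannel epoch data around a learning task:

1. **A time-resolved multivariate discriminability trace.** At each time
   bin (20 ms windows, 10 ms steps across 0–400 ms post-stimulus), the
   trials × channels matrix is reduced to the principal components holding
   ≥ 99% of its variance and the two label groups are compared with the
   two-sample Hotelling statistic

   *T*² = (*n*<sub>A</sub>*n*<sub>B</sub>/(*n*<sub>A</sub>+*n*<sub>B</sub>)) δ′S⁻¹δ,

   reported as a χ² value against the asymptotic χ²<sub>p</sub> reference,
   with a 100-fold label-shuffled null trace alongside.
2. **Excursion (cluster) permutation inference.** Contiguous runs of ≥ 2
   bins above a threshold (default 20) are proposed as temporal regions of
   interest; the maximum region mass is compared against the same statistic
   in the label-shuffled data, giving *p* = (1 + #{null ≥ obs})/(*N* + 1),
   and subject-level *p*-values combine across subjects by Fisher's method
   (−2Σln *p*<sub>i</sub> ~ χ²<sub>2k</sub>).
3. **Window-averaged held-out decoding.** Per cortical region and latency
   window (baseline 0–50, M100 50–150, M200 150–250, M300 250–350 ms),
   leave-one-trial-out logistic regression predicts the category of each
   held-out trial, separately for the first and last 100 trials of the
   session — early versus late learning — with pathway-level pooling of
   ventral-visual (VVP) versus prefrontal (PFC) regions.

Since no recordings ship with the package, a synthetic generator produces
sensor-space (102 magnetometers) and source-space (24 region-bounded dipole
ensembles) epochs with band-limited noise and category effects confined to
configurable latency windows, whose amplitude follows a logistic learning
curve over trials. The parametric blob stimulus space itself (20-edge
polygons, Gaussian jitter proportional to the prototype difference) is also
implemented, including its PCA characterization.

## Worked example

```r
library(catmeg)

pair <- make_prototype_pair(seed = 11)
stim <- generate_stimulus_set(pair, seed = 12)
pca_summary(stim)$cumulative_variance[2]       # 0.907

regions <- simulate_region_ensembles(stim, seed = 13)  # default scenario
target <- remove_baseline(regions$lh_inferiortemporal)

# discriminability of the late-learning phase, with its permutation null
binned <- sliding_average(select_phase(target, "late", 100))
trace  <- discriminability_trace(binned)
nulls  <- shuffled_traces(binned, n_perm = 100, seed = 14)
exc    <- excursion_pvalue(find_excursions(trace, threshold = 20), nulls)

# held-out decoding of the M200 window, early vs late learning
for (ph in c("early", "late")) {
  sel <- select_phase(target, ph, 100)
  loo_logistic_accuracy(window_average(sel, c(150, 250)), sel$labels)
}
```

Output (printed by the snippet above, formatted):

```
stimulus space: 90.7% of variance in two principal components
late phase: peak chi2 = 419.3 at 200 ms; main excursion 120-240 ms, mass 1724, p = 0.0099
group bound for seven such subjects: p = 1.79e-08
early phase, M200 decoding: 0.49 (49/100 trials, 16 components)
 late phase, M200 decoding: 0.97 (97/100 trials, 16 components)
```

Read: the left inferior-temporal ensemble — the region carrying the
simulated learning effect at 150–250 ms — shows a strong late-phase
discriminability excursion around M200 (*p* = 1/101, the smallest value 100
permutations can give; seven such subjects combine to *p* ≈ 1.8 × 10⁻⁸),
and its M200 decoding accuracy rises from chance (0.49) early in learning
to 0.97 late, while noise-only regions stay at chance.

The numbered drivers under `analysis/` run the full study: `01_stimuli.R`
(stimulus space), `02_sensor_discriminability.R` (sensor traces, excursion
tests and the group Fisher bound for seven simulated subjects),
`03_source_excursion.R` (per-region, per-phase excursion tests), and
`04_decoding.R` (the 24 × 4 × 2 decoding grid with early/late comparisons
and pathway pooling). Their tables land under `results/`.

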