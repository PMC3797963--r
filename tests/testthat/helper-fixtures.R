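# Shared miniature fixtures, all generated in code at test time.

tiny_stimulus_set <- function(seed = 42, n_per_category = 20L) {
  pair <- make_prototype_pair(seed = seed)
  generate_stimulus_set(pair, n_per_category = n_per_category,
                        n_blocks = 5L, seed = seed + 1L)
}

# One noise-only region ensemble, baseline-removed, as an epoch_set.
noise_region_epochs <- function(seed, n_per_category = 50L,
                                dipole_count = 16L,
                                noise = noise_params()) {
  stim <- tiny_stimulus_set(seed = seed, n_per_category = n_per_category)
  layout <- default_region_layout(dipole_count)[1, ]
  regs <- simulate_region_ensembles(stim, layout, effects = list(),
                                    noise = noise, seed = seed + 2L)
  remove_baseline(regs[[1]])
}

# Deterministic quiet epochs: near-zero noise so injected structure is exact.
quiet_noise <- function() noise_params(sd = 1e-9, smooth_ms = 0,
                                       baseline_sd = 0)
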