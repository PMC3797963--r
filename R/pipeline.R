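#' Full analysis configuration
#'
#' Bundles and validates every parameter of the pipeline. The defaults are
#' the study conditions of the analysis: 300 exemplars per category in 5
#' balanced blocks, jitter scale 0.2, a 120 ms pre-stimulus baseline, the
#' 0--400 ms analysis window binned with a 20 ms moving window in 10 ms
#' steps, 99% PCA variance, excursion threshold 20, 100 label permutations,
#' 100-trial learning phases, the canonical latency windows, and 7 simulated
#' subjects.
#'
#' @param n_per_category Exemplars per category.
#' @param n_blocks Session blocks.
#' @param jitter_scale Stimulus jitter proportionality constant.
#' @param layout Region layout data frame.
#' @param region_effects List of [effect_spec()]s for the region simulation.
#' @param sensor_effects List of [effect_spec()]s for the sensor simulation.
#' @param noise [noise_params()].
#' @param dt_ms Sampling interval in ms.
#' @param n_channels Sensor channel count.
#' @param baseline_ms,epoch_ms Baseline and analysis intervals (half-open).
#' @param bin_window_ms,bin_step_ms Moving-average window and step.
#' @param variance_fraction PCA variance fraction.
#' @param excursion_threshold Excursion threshold on the chi-squared trace.
#' @param n_perm Label permutations for the null traces.
#' @param n_phase Trials per learning phase.
#' @param windows Decoding window data frame.
#' @param n_subjects Number of simulated subjects.
#' @param seed Master seed; per-subject and per-stage streams are derived
#'   from it.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(n_per_category = 300L, n_blocks = 5L,
                            jitter_scale = 0.2,
                            layout = default_region_layout(),
                            region_effects = default_scenario_effects(),
                            sensor_effects = default_sensor_effects(),
                            noise = noise_params(), dt_ms = 5,
                            n_channels = 102L,
                            baseline_ms = c(-120, 0), epoch_ms = c(0, 400),
                            bin_window_ms = 20, bin_step_ms = 10,
                            variance_fraction = 0.99,
                            excursion_threshold = 20, n_perm = 100L,
                            n_phase = 100L, windows = window_specs(),
                            n_subjects = 7L, seed = 1L) {
  stopifnot(n_per_category >= 1, n_per_category %% n_blocks == 0,
            jitter_scale > 0, dt_ms > 0, n_channels >= 2,
            baseline_ms[1] < baseline_ms[2], epoch_ms[1] < epoch_ms[2],
            bin_window_ms > 0, bin_step_ms > 0,
            variance_fraction > 0, variance_fraction <= 1,
            excursion_threshold > 0, n_perm >= 1, n_phase >= 6,
            n_subjects >= 1, is.numeric(seed), seed == round(seed))
  stopifnot(inherits(noise, "noise_params"),
            all(c("region", "pathway", "dipole_count") %in% names(layout)))
  if (2L * n_per_category < 2L * n_phase)
    stop("session too short: early and late phases of ", n_phase,
         " trials need at least ", 2L * n_phase, " trials")
  structure(as.list(environment()), class = "analysis_config")
}

#' Default sensor-space effect
#'
#' A single broad occipital-like sensor effect used by the sensor-space
#' stage of the pipeline: 100--300 ms window, loading on the first 30
#' channels, mild learning ramp. Amplitude is a free simulation parameter.
#'
#' @param n_channels Total sensor count the pattern is embedded in.
#' @param amplitude Peak amplitude.
#' @return A list with one [effect_spec()].
#' @export
default_sensor_effects <- function(n_channels = 102L, amplitude = 0.8) {
  k <- min(30L, n_channels)
  pattern <- c(rep(1, k), rep(0, n_channels - k))
  list(effect_spec("sensors", window_ms = c(100, 300),
                   amplitude = amplitude,
                   learning = learning_params(floor = 0.3, ceiling = 1,
                                              midpoint_trial = 300L,
                                              rate = 0.02),
                   spatial_pattern = pattern))
}

# Deterministic per-subject, per-stage seed derivation (kept < 2^31).
.derive_seed <- function(master, subject, stage) {
  (as.integer(master) + 7919L * as.integer(subject) +
     104729L * as.integer(stage)) %% 2000000000L
}

#' Run the full analysis pipeline
#'
#' For each simulated subject: generate a stimulus session, simulate the
#' sensor and region epochs, remove baselines, compute the sensor
#' discriminability trace with its label-shuffled null set, run the
#' excursion test, and decode the region x window x phase grid. Then
#' Fisher-combine the subject excursion p-values and write every result
#' table, plus a machine-readable manifest, under `out_dir`. Byte-identical
#' outputs for a fixed configuration.
#'
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created; subdirectories `stimuli/`,
#'   `traces/`, `excursion/`, `decoding/`).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `subject_p_values`, `group`,
#'   `decoding_tables`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("stimuli", "traces", "excursion", "decoding"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  subject_p <- numeric(config$n_subjects)
  tables <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    say("subject %d: stimuli (%d trials)", s, 2 * config$n_per_category)
    pair <- make_prototype_pair(seed = .derive_seed(config$seed, s, 1L),
                                jitter_scale = config$jitter_scale)
    stim <- generate_stimulus_set(pair, config$n_per_category,
                                  config$n_blocks,
                                  seed = .derive_seed(config$seed, s, 2L))
    if (s == 1L) write_stimulus_set(stim, file.path(out_dir, "stimuli"))
    say("subject %d: sensor epochs (%d channels)", s, config$n_channels)
    sensor <- simulate_sensor_epochs(stim, config$sensor_effects,
                                     config$noise, config$n_channels,
                                     config$dt_ms,
                                     seed = .derive_seed(config$seed, s, 3L))
    sensor <- remove_baseline(sensor, config$baseline_ms, config$epoch_ms)
    binned <- sliding_average(sensor, config$bin_window_ms,
                              config$bin_step_ms, config$epoch_ms)
    trace <- discriminability_trace(binned,
                                    variance_fraction =
                                      config$variance_fraction)
    nulls <- shuffled_traces(binned, n_perm = config$n_perm,
                             seed = .derive_seed(config$seed, s, 4L),
                             variance_fraction = config$variance_fraction)
    write_trace(trace, file.path(out_dir, "traces",
                                 sprintf("subject_%02d.csv", s)), nulls)
    exc <- excursion_pvalue(find_excursions(trace,
                                            config$excursion_threshold),
                            nulls, config$excursion_threshold)
    subject_p[s] <- exc$p_value
    write_excursion_test(exc, file.path(out_dir, "excursion",
                                        sprintf("subject_%02d", s)))
    rm(sensor, binned)
    say("subject %d: region ensembles + decoding grid", s)
    regions <- simulate_region_ensembles(stim, config$layout,
                                         config$region_effects,
                                         config$noise, config$dt_ms,
                                         seed = .derive_seed(config$seed, s,
                                                             5L))
    regions[] <- lapply(regions, remove_baseline, config$baseline_ms,
                        config$epoch_ms)
    tab <- decode_grid(regions, config$windows,
                       n_phase = config$n_phase,
                       variance_fraction = config$variance_fraction)
    tables[[s]] <- tab
    utils::write.csv(tab, file.path(out_dir, "decoding",
                                    sprintf("subject_%02d_table.csv", s)),
                     row.names = FALSE)
    utils::write.csv(compare_phases(tab),
                     file.path(out_dir, "decoding",
                               sprintf("subject_%02d_phase_comparison.csv",
                                       s)), row.names = FALSE)
    utils::write.csv(pool_pathways(tab),
                     file.path(out_dir, "decoding",
                               sprintf("subject_%02d_pathways.csv", s)),
                     row.names = FALSE)
    rm(regions)
  }
  group <- fisher_combine(subject_p)
  jsonlite::write_json(
    list(subject_p_values = subject_p,
         fisher_statistic = group$fisher_statistic, df = group$df,
         combined_p = group$combined_p),
    file.path(out_dir, "excursion", "group_combination.json"),
    auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("catmeg")),
    seed = config$seed, n_subjects = config$n_subjects,
    n_per_category = config$n_per_category, dt_ms = config$dt_ms,
    n_channels = config$n_channels, n_perm = config$n_perm,
    excursion_threshold = config$excursion_threshold,
    variance_fraction = config$variance_fraction,
    n_phase = config$n_phase,
    seed_rule = "seed + 7919*subject + 104729*stage mod 2e9")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(subject_p_values = subject_p, group = group,
                 decoding_tables = tables, manifest = manifest))
}

#' Write deterministic miniature fixture datasets
#'
#' Generates a tiny, fully deterministic dataset for smoke-testing every
#' pipeline stage without large inputs: a 20-per-category stimulus set and,
#' for `"tiny"`, 3 regions x 40 trials x 4 dipoles at 5 ms sampling written
#' as delimited text; `"default"` writes the full-size stimulus set only
#' (epoch tensors at full size are regenerated from seeds, not stored).
#'
#' @param dir Output directory.
#' @param size `"tiny"` or `"default"`.
#' @param seed Integer seed (fixtures regenerate identically from it).
#' @return `dir`, invisibly.
#' @export
generate_fixtures <- function(dir, size = c("tiny", "default"), seed = 1L) {
  size <- match.arg(size)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (size == "tiny") {
    pair <- make_prototype_pair(seed = seed)
    stim <- generate_stimulus_set(pair, n_per_category = 20L, n_blocks = 5L,
                                  seed = seed + 1L)
    write_stimulus_set(stim, file.path(dir, "stimuli"))
    layout <- default_region_layout(dipole_count = 4L)[c(1, 2, 13), ]
    effects <- list(effect_spec(layout$region[1], window_ms = c(150, 250),
                                amplitude = 2,
                                learning = learning_params(0.1, 1, 20L,
                                                           0.2)))
    regions <- simulate_region_ensembles(stim, layout, effects,
                                         seed = seed + 2L)
    for (r in names(regions))
      write_epochs(regions[[r]],
                   file.path(dir, sprintf("epochs_%s.csv", r)))
  } else {
    pair <- make_prototype_pair(seed = seed)
    stim <- generate_stimulus_set(pair, seed = seed + 1L)
    write_stimulus_set(stim, file.path(dir, "stimuli"))
  }
  invisible(dir)
}
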