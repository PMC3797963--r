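#' Learning-curve parameters
#'
#' Parameters of the logistic ramp that modulates effect amplitude over the
#' session: `floor` is the level early in the session, `ceiling` the level it
#' approaches late, `midpoint_trial` the trial at which the curve is halfway
#' between them, and `rate` the steepness (per trial). `floor > ceiling`
#' gives a decaying curve (an effect that weakens with learning).
#'
#' @param floor,ceiling Levels in \[0, 1\].
#' @param midpoint_trial Trial index of the half-way point.
#' @param rate Logistic steepness per trial; `rate > 0` makes the curve
#'   monotone from `floor` towards `ceiling`.
#' @return A list of class `learning_params`.
#' @export
learning_params <- function(floor = 1, ceiling = 1, midpoint_trial = 0L,
                            rate = 0) {
  stopifnot(floor >= 0, floor <= 1, ceiling >= 0, ceiling <= 1,
            is.finite(rate))
  structure(list(floor = floor, ceiling = ceiling,
                 midpoint_trial = midpoint_trial, rate = rate),
            class = "learning_params")
}

#' Evaluate the learning curve at given trial indices
#'
#' `floor + (ceiling - floor) / (1 + exp(-rate * (trial - midpoint)))`,
#' vectorized over `trial_index`. Monotone nondecreasing in `trial_index`
#' when `rate > 0` and `ceiling >= floor`.
#'
#' @param trial_index Nonnegative trial indices (vectorized).
#' @param learning A [learning_params()] object.
#' @return Values in \[0, 1\], same length as `trial_index`.
#' @export
learning_curve <- function(trial_index, learning) {
  stopifnot(inherits(learning, "learning_params"), all(trial_index >= 0))
  learning$floor + (learning$ceiling - learning$floor) *
    stats::plogis(learning$rate * (trial_index - learning$midpoint_trial))
}

#' Specification of one injected category effect
#'
#' Describes a category-signed signal component: where it lives (a region
#' name, or `"sensors"` for sensor space), its spatial loading pattern over
#' that target's channels, the post-onset latency window it occupies, its
#' amplitude, and its learning modulation. The injected signal for trial `t`
#' at channel `c` and time `s` is
#' `sign(category) * amplitude * learning_curve(t) * pattern[c] * bump(s)`
#' with `sign(A) = +1`, `sign(B) = -1` and `bump` a raised-cosine envelope
#' spanning `window_ms` (zero outside it).
#'
#' @param target Region name, or `"sensors"`.
#' @param window_ms Half-open latency window `c(start, end)` in ms
#'   post-onset, inside \[0, 400\].
#' @param amplitude Peak signal amplitude (same units as the noise sd).
#' @param learning A [learning_params()] object.
#' @param spatial_pattern Loading vector over the target's channels,
#'   normalized to unit norm; `NULL` (default) means uniform loading,
#'   resolved when the target's channel count is known.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(target, window_ms = c(150, 250), amplitude = 1,
                        learning = learning_params(),
                        spatial_pattern = NULL) {
  stopifnot(length(window_ms) == 2, window_ms[1] >= 0, window_ms[2] <= 400,
            window_ms[2] > window_ms[1], amplitude >= 0,
            inherits(learning, "learning_params"))
  if (!is.null(spatial_pattern)) {
    nrm <- sqrt(sum(spatial_pattern^2))
    if (nrm <= 0) stop("spatial_pattern must be a nonzero vector")
    spatial_pattern <- spatial_pattern / nrm
  }
  structure(list(target = target, window_ms = as.numeric(window_ms),
                 amplitude = amplitude, learning = learning,
                 spatial_pattern = spatial_pattern),
            class = "effect_spec")
}

#' Noise-model parameters for simulated epochs
#'
#' Epoch noise is Gaussian, temporally smoothed by a moving-average kernel of
#' length `smooth_ms` (rescaled to unit variance, approximating the
#' 0.1--50 Hz recording band at the configured sampling rate) and scaled by
#' `sd`; each trial additionally receives a per-trial, per-channel constant
#' baseline offset with standard deviation `baseline_sd` (slow drift), which
#' baseline removal must eliminate.
#'
#' @param sd Noise standard deviation per sample (signal units).
#' @param smooth_ms Moving-average kernel length in ms.
#' @param baseline_sd Standard deviation of the per-trial constant offset.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(sd = 1, smooth_ms = 25, baseline_sd = 0.5) {
  stopifnot(sd > 0, smooth_ms >= 0, baseline_sd >= 0)
  structure(list(sd = sd, smooth_ms = smooth_ms, baseline_sd = baseline_sd),
            class = "noise_params")
}

#' Construct an epoch set
#'
#' The universal container of the analysis: a trials x channels x time
#' tensor with per-trial category labels, per-trial presentation indices, a
#' time axis in ms, channel names and a kind tag (`"sensor"` or `"region"`).
#'
#' @param data Numeric array, trials x channels x time.
#' @param labels Per-trial category labels in `{"A","B"}`.
#' @param trial_index Per-trial presentation order (1-based).
#' @param time_ms Strictly increasing sample times in ms (0 = stimulus
#'   onset, which must be on the axis).
#' @param channel_names Channel identifiers.
#' @param kind `"sensor"` or `"region"`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, trial_index, time_ms,
                      channel_names = NULL, kind = c("sensor", "region")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == length(labels),
            dim(data)[1] == length(trial_index),
            dim(data)[3] == length(time_ms),
            all(diff(time_ms) > 0),
            any(time_ms == 0),
            all(labels %in% c("A", "B")))
  if (is.null(channel_names))
    channel_names <- sprintf("ch%03d", seq_len(dim(data)[2]))
  stopifnot(length(channel_names) == dim(data)[2])
  structure(list(data = data, labels = as.character(labels),
                 trial_index = as.integer(trial_index),
                 time_ms = as.numeric(time_ms),
                 channel_names = channel_names, kind = kind),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set (%s)> %d trials x %d channels x %d samples, %g..%g ms\n",
              x$kind, d[1], d[2], d[3], min(x$time_ms), max(x$time_ms)))
  cat(sprintf("  labels: %d A / %d B\n", sum(x$labels == "A"),
              sum(x$labels == "B")))
  invisible(x)
}

# Circulant moving-average smoothing matrix of kernel length len over nt
# samples, rescaled so smoothed white noise keeps unit marginal variance.
.smoothing_matrix <- function(nt, len) {
  offsets <- seq.int(-((len - 1L) %/% 2L), len - 1L - (len - 1L) %/% 2L)
  s <- matrix(0, nt, nt)
  for (o in offsets) {
    idx <- ((seq_len(nt) - 1L + o) %% nt) + 1L
    s[cbind(seq_len(nt), idx)] <- 1 / len
  }
  s * sqrt(len)
}

# Smoothed Gaussian noise plus per-trial constant baseline drift.
# Returns a trials x channels x time array. Consumes the current RNG stream.
.simulate_noise <- function(n_trials, n_channels, time_ms, noise) {
  nt <- length(time_ms)
  dt <- if (nt > 1) time_ms[2] - time_ms[1] else 1
  len <- max(1L, round(noise$smooth_ms / dt))
  m <- n_trials * n_channels
  x <- matrix(stats::rnorm(m * nt), nrow = m)
  if (len > 1L) x <- x %*% .smoothing_matrix(nt, len)
  arr <- array(x * noise$sd, dim = c(n_trials, n_channels, nt))
  if (noise$baseline_sd > 0) {
    drift <- stats::rnorm(m, 0, noise$baseline_sd)
    arr <- arr + array(drift, dim = c(n_trials, n_channels, nt))
  }
  arr
}

# Raised-cosine envelope over the half-open window [w0, w1): 0 at the edges,
# 1 at the center, identically 0 outside. Vectorized over time.
.raised_cosine_bump <- function(time_ms, window_ms) {
  u <- (time_ms - window_ms[1]) / (window_ms[2] - window_ms[1])
  ifelse(u >= 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

# Add one effect in place to a trials x channels x time array.
.inject_effect <- function(data, effect, labels, trial_index, time_ms,
                           channels = seq_len(dim(data)[2])) {
  pattern <- effect$spatial_pattern
  if (is.null(pattern)) pattern <- rep(1 / sqrt(length(channels)),
                                       length(channels))
  if (length(pattern) != length(channels))
    stop("spatial_pattern length (", length(pattern),
         ") does not match target channel count (", length(channels), ")")
  bump <- .raised_cosine_bump(time_ms, effect$window_ms)
  active <- which(bump > 0)
  if (length(active) == 0L)
    stop("effect window [", effect$window_ms[1], ", ", effect$window_ms[2],
         ") contains no samples of the epoch time axis")
  sgn <- ifelse(labels == "A", 1, -1)
  coef <- sgn * effect$amplitude * learning_curve(trial_index,
                                                  effect$learning)
  block <- outer(coef, pattern)              # trials x target channels
  for (s in active)
    data[, channels, s] <- data[, channels, s] + block * bump[s]
  data
}

#' Simulate sensor-space epochs for a stimulus session
#'
#' Generates a trials x channels x time tensor spanning -120..400 ms around
#' stimulus onset: band-limited Gaussian noise (see [noise_params()]) plus
#' the category-signed, latency-windowed, learning-modulated effects given in
#' `effects`. Trial order, labels and trial indices come from the stimulus
#' set's presentation order.
#'
#' @param stimulus_set A [generate_stimulus_set()] object.
#' @param effects List of [effect_spec()] objects with `target = "sensors"`.
#' @param noise A [noise_params()] object.
#' @param n_channels Number of magnetometer channels (default 102).
#' @param dt_ms Sampling interval in ms (default 5; 1 supported).
#' @param seed Optional integer seed.
#' @return An [epoch_set()] of kind `"sensor"`.
#' @export
simulate_sensor_epochs <- function(stimulus_set, effects = list(),
                                   noise = noise_params(),
                                   n_channels = 102L, dt_ms = 5,
                                   seed = NULL) {
  stopifnot(inherits(stimulus_set, "stimulus_set"))
  if (!is.null(seed)) set.seed(seed)
  pres <- stimulus_set$presentation
  time_ms <- seq(-120, 400 - dt_ms, by = dt_ms)
  data <- .simulate_noise(nrow(pres), n_channels, time_ms, noise)
  for (e in effects) {
    stopifnot(inherits(e, "effect_spec"))
    if (!identical(e$target, "sensors"))
      stop("sensor simulation received an effect targeting '", e$target, "'")
    data <- .inject_effect(data, e, pres$category, pres$trial_index, time_ms)
  }
  epoch_set(data, pres$category, pres$trial_index, time_ms,
            channel_names = sprintf("MEG%03d", seq_len(n_channels)),
            kind = "sensor")
}

#' Default cortical region layout
#'
#' 24 anatomically named regions: 12 in the ventral visual pathway (VVP) and
#' 12 in prefrontal cortex (PFC), 6 of each per hemisphere, each an ensemble
#' of `dipole_count` source dipoles.
#'
#' @param dipole_count Dipoles per region (default 16; must be >= 2).
#' @return A data frame with columns `region`, `pathway`, `hemisphere`,
#'   `dipole_count`, of class `region_layout`.
#' @export
default_region_layout <- function(dipole_count = 16L) {
  stopifnot(dipole_count >= 2)
  vvp <- c("lateraloccipital", "fusiform", "inferiortemporal", "lingual",
           "pericalcarine", "parahippocampal")
  pfc <- c("parsorbitalis", "parstriangularis", "parsopercularis",
           "rostralmiddlefrontal", "lateralorbitofrontal", "frontalpole")
  out <- expand.grid(hemisphere = c("lh", "rh"), base = c(vvp, pfc),
                     stringsAsFactors = FALSE)
  out$pathway <- ifelse(out$base %in% vvp, "VVP", "PFC")
  out$region <- paste(out$hemisphere, out$base, sep = "_")
  out$dipole_count <- as.integer(dipole_count)
  out <- out[order(out$pathway == "PFC", out$base, out$hemisphere),
             c("region", "pathway", "hemisphere", "dipole_count")]
  rownames(out) <- NULL
  class(out) <- c("region_layout", "data.frame")
  out
}

#' Default learning-effect scenario for region simulations
#'
#' The reference scenario used throughout the acceptance checks: one left
#' VVP region (inferior temporal) carries a 150--250 ms effect whose
#' amplitude ramps up with learning (floor 0.05, ceiling 1.0), one left PFC
#' region (pars orbitalis) carries a 250--350 ms effect that decays with
#' learning (floor 1.0, ceiling 0.2); all other regions are pure noise.
#' Amplitudes are free parameters of the simulation (the experiment they
#' emulate published no SNR); the defaults were fixed once from a pilot
#' simulation so that late-phase decoding in the target cell is well above
#' chance.
#'
#' @param vvp_amplitude,pfc_amplitude Peak effect amplitudes (signal units,
#'   relative to noise sd 1).
#' @param midpoint_trial,rate Shared learning-curve shape (default midpoint
#'   trial 300 of 600, rate 0.02 per trial).
#' @return A list of two [effect_spec()] objects named by their targets.
#' @export
default_scenario_effects <- function(vvp_amplitude = 1.8,
                                     pfc_amplitude = 1.5,
                                     midpoint_trial = 300L, rate = 0.02) {
  list(
    effect_spec("lh_inferiortemporal", window_ms = c(150, 250),
                amplitude = vvp_amplitude,
                learning = learning_params(floor = 0.05, ceiling = 1,
                                           midpoint_trial = midpoint_trial,
                                           rate = rate)),
    effect_spec("lh_parsorbitalis", window_ms = c(250, 350),
                amplitude = pfc_amplitude,
                learning = learning_params(floor = 1, ceiling = 0.2,
                                           midpoint_trial = midpoint_trial,
                                           rate = rate)))
}

#' Simulate per-region source-space epoch ensembles
#'
#' One [epoch_set()] of kind `"region"` per layout region, sharing the
#' session's labels and trial order; each effect is injected only into its
#' target region. Deterministic given `seed` (regions consume the seeded RNG
#' stream in layout order).
#'
#' @param stimulus_set A [generate_stimulus_set()] object.
#' @param layout A [default_region_layout()]-style data frame.
#' @param effects List of [effect_spec()] objects whose targets name layout
#'   regions (default: the reference learning scenario).
#' @param noise A [noise_params()] object.
#' @param dt_ms Sampling interval in ms.
#' @param seed Optional integer seed.
#' @return A named list of `epoch_set` objects with the layout attached as
#'   attribute `"layout"`, of class `region_ensembles`.
#' @export
simulate_region_ensembles <- function(stimulus_set,
                                      layout = default_region_layout(),
                                      effects = default_scenario_effects(),
                                      noise = noise_params(), dt_ms = 5,
                                      seed = NULL) {
  stopifnot(inherits(stimulus_set, "stimulus_set"))
  targets <- vapply(effects, `[[`, character(1), "target")
  missing <- setdiff(targets, layout$region)
  if (length(missing) > 0)
    stop("effect targets not present in layout: ",
         paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  pres <- stimulus_set$presentation
  time_ms <- seq(-120, 400 - dt_ms, by = dt_ms)
  out <- vector("list", nrow(layout))
  names(out) <- layout$region
  for (r in seq_len(nrow(layout))) {
    k <- layout$dipole_count[r]
    data <- .simulate_noise(nrow(pres), k, time_ms, noise)
    for (e in effects[targets == layout$region[r]])
      data <- .inject_effect(data, e, pres$category, pres$trial_index,
                             time_ms)
    out[[r]] <- epoch_set(data, pres$category, pres$trial_index, time_ms,
                          channel_names = sprintf("%s_dip%02d",
                                                  layout$region[r],
                                                  seq_len(k)),
                          kind = "region")
  }
  structure(out, layout = layout, class = "region_ensembles")
}

#' Write / read an epoch set as long-format delimited text
#'
#' Plain-text persistence for small epoch sets: one row per (trial, channel,
#' sample) with columns `trial`, `trial_index`, `label`, `channel`,
#' `time_ms`, `value`. Intended for miniature fixtures; full-size tensors
#' should be regenerated from seeds instead.
#'
#' @param epochs An [epoch_set()] object.
#' @param file Path of the CSV file to write / read.
#' @return `write_epochs` returns `file` invisibly; `read_epochs` an
#'   `epoch_set`.
#' @export
write_epochs <- function(epochs, file) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  long <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    trial_index = rep(epochs$trial_index, times = d[2] * d[3]),
    label = rep(epochs$labels, times = d[2] * d[3]),
    channel = rep(rep(epochs$channel_names, each = d[1]), times = d[3]),
    time_ms = rep(epochs$time_ms, each = d[1] * d[2]),
    value = as.numeric(epochs$data),
    stringsAsFactors = FALSE)
  attr_line <- sprintf("# kind=%s", epochs$kind)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(file) {
  first <- readLines(file, n = 1)
  kind <- sub("^# kind=", "", first)
  long <- utils::read.csv(file, skip = 1, stringsAsFactors = FALSE)
  trials <- sort(unique(long$trial))
  channels <- unique(long$channel[long$trial == trials[1] &
                                    long$time_ms == long$time_ms[1]])
  time_ms <- sort(unique(long$time_ms))
  d <- c(length(trials), length(channels), length(time_ms))
  data <- array(long$value, dim = d)
  first_block <- long[seq_len(d[1]), ]
  epoch_set(data, first_block$label, first_block$trial_index, time_ms,
            channel_names = channels, kind = kind)
}
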