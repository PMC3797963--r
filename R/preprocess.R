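#' Remove the pre-stimulus baseline from each trial
#'
#' For every trial and channel, subtracts the mean over the 120 ms
#' pre-stimulus interval \[-120, 0) and returns the post-onset samples on
#' \[0, 400). Removes slow per-trial drift (constant offsets exactly).
#'
#' @param epochs An [epoch_set()] whose time axis covers \[-120, 0).
#' @param baseline_ms Baseline interval `c(start, end)` in ms (half-open).
#' @param keep_ms Post-onset interval returned (half-open).
#' @return An `epoch_set` restricted to `keep_ms`.
#' @export
remove_baseline <- function(epochs, baseline_ms = c(-120, 0),
                            keep_ms = c(0, 400)) {
  stopifnot(inherits(epochs, "epoch_set"))
  bidx <- which(epochs$time_ms >= baseline_ms[1] &
                  epochs$time_ms < baseline_ms[2])
  if (length(bidx) == 0)
    stop("no pre-stimulus samples in [", baseline_ms[1], ", ",
         baseline_ms[2], ") ms: cannot remove baseline")
  pidx <- which(epochs$time_ms >= keep_ms[1] & epochs$time_ms < keep_ms[2])
  d <- dim(epochs$data)
  bmean <- rowMeans(matrix(epochs$data[, , bidx, drop = FALSE],
                           nrow = d[1] * d[2]))
  post <- epochs$data[, , pidx, drop = FALSE]
  post <- post - array(bmean, dim = dim(post))
  epoch_set(post, epochs$labels, epochs$trial_index, epochs$time_ms[pidx],
            channel_names = epochs$channel_names, kind = epochs$kind)
}

#' Moving-window time averaging of an epoch set
#'
#' Averages each trial and channel within half-open windows
#' `[k*step, k*step + window)` ms for `k = 0, 1, ...` over the post-onset
#' epoch; with the 20 ms window / 10 ms step defaults over \[0, 400) this
#' yields 39 bins labeled by their centers 10, 20, ..., 390 ms.
#'
#' @param epochs A baseline-removed [epoch_set()] covering \[0, 400).
#' @param window_ms Window length in ms (default 20).
#' @param step_ms Step between window onsets in ms (default 10).
#' @param epoch_ms Interval the bin grid tiles (half-open, default
#'   `c(0, 400)`).
#' @return An object of class `binned_epochs`: `data`
#'   (trials x channels x bins), `bin_centers_ms`, `labels`, `trial_index`,
#'   `channel_names`, plus the window/step provenance.
#' @export
sliding_average <- function(epochs, window_ms = 20, step_ms = 10,
                            epoch_ms = c(0, 400)) {
  stopifnot(inherits(epochs, "epoch_set"), window_ms > 0, step_ms > 0)
  starts <- seq(epoch_ms[1], epoch_ms[2] - window_ms, by = step_ms)
  d <- dim(epochs$data)
  bins <- matrix(NA_real_, nrow = d[1] * d[2], ncol = length(starts))
  for (k in seq_along(starts)) {
    idx <- which(epochs$time_ms >= starts[k] &
                   epochs$time_ms < starts[k] + window_ms)
    if (length(idx) == 0)
      stop("window [", starts[k], ", ", starts[k] + window_ms,
           ") ms contains no samples")
    bins[, k] <- rowMeans(matrix(epochs$data[, , idx, drop = FALSE],
                                 nrow = d[1] * d[2]))
  }
  structure(list(
    data = array(bins, dim = c(d[1], d[2], length(starts))),
    bin_centers_ms = starts + window_ms / 2,
    labels = epochs$labels, trial_index = epochs$trial_index,
    channel_names = epochs$channel_names,
    window_ms = window_ms, step_ms = step_ms, kind = epochs$kind),
    class = "binned_epochs")
}

#' Select the early or late learning phase of a session
#'
#' The `n` trials with the smallest (`"early"`) or largest (`"late"`)
#' presentation index, in their original order. With the default balanced
#' session design each 100-trial phase holds exactly 50 trials per category.
#'
#' @param epochs An [epoch_set()].
#' @param phase `"early"` or `"late"`.
#' @param n Number of trials per phase (default 100).
#' @return An `epoch_set` restricted to the selected trials.
#' @export
select_phase <- function(epochs, phase = c("early", "late"), n = 100L) {
  stopifnot(inherits(epochs, "epoch_set"))
  phase <- match.arg(phase)
  n_total <- length(epochs$trial_index)
  if (n > n_total)
    stop("phase size n = ", n, " exceeds the ", n_total, " available trials")
  ord <- order(epochs$trial_index)
  keep <- if (phase == "early") ord[seq_len(n)]
          else ord[seq.int(n_total - n + 1L, n_total)]
  keep <- sort(keep)  # preserve original row order
  epoch_set(epochs$data[keep, , , drop = FALSE], epochs$labels[keep],
            epochs$trial_index[keep], epochs$time_ms,
            channel_names = epochs$channel_names, kind = epochs$kind)
}
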