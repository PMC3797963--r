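#' Canonical decoding time windows
#'
#' The four post-stimulus windows of the decoding analysis, half-open in ms:
#' baseline \[0, 50), M100 \[50, 150), M200 \[150, 250), M300 \[250, 350) --
#' the MEG analogues of the N170/N250 ERP components.
#'
#' @return A data frame with columns `name`, `start_ms`, `end_ms`.
#' @export
window_specs <- function() {
  data.frame(name = c("baseline", "M100", "M200", "M300"),
             start_ms = c(0, 50, 150, 250),
             end_ms = c(50, 150, 250, 350),
             stringsAsFactors = FALSE)
}

#' Average an epoch set within one latency window
#'
#' Per trial and channel, the mean over samples in the half-open window;
#' yields one feature per channel (dipole).
#'
#' @param epochs An [epoch_set()] covering the window.
#' @param window `c(start, end)` in ms, or a row of [window_specs()].
#' @return A trials x channels numeric matrix.
#' @export
window_average <- function(epochs, window) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.data.frame(window)) window <- c(window$start_ms, window$end_ms)
  stopifnot(length(window) == 2, window[2] > window[1])
  idx <- which(epochs$time_ms >= window[1] & epochs$time_ms < window[2])
  if (length(idx) == 0)
    stop("window [", window[1], ", ", window[2],
         ") ms contains no samples of the epoch time axis")
  d <- dim(epochs$data)
  out <- matrix(rowMeans(matrix(epochs$data[, , idx, drop = FALSE],
                                nrow = d[1] * d[2])),
                nrow = d[1], ncol = d[2])
  colnames(out) <- epochs$channel_names
  out
}

# Logistic fit on a design matrix (intercept included in z): maximum
# likelihood via Newton/IRLS with a warm start. On breakdown (singular
# weighted cross-product or non-finite coefficients, as under complete
# separation) falls back to a ridge-stabilized IRLS fit and flags it.
# Under separation the unpenalized likelihood has no finite maximizer; the
# iteration cap returns a finite fit whose predicted class memberships for
# the separable trials are already exact.
.fit_logistic <- function(z, y, start = NULL, ridge = 1e-3, maxit = 30L) {
  p <- ncol(z)
  beta <- if (is.null(start)) rep(0, p) else start
  ok <- TRUE
  for (it in seq_len(maxit)) {
    eta <- drop(z %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    step <- tryCatch(
      drop(solve(crossprod(z, z * w), crossprod(z, y - mu))),
      error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) { ok <- FALSE; break }
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  if (ok && all(is.finite(beta)))
    return(list(coef = beta, ridged = FALSE))
  beta <- rep(0, p)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  for (it in seq_len(100)) {
    eta <- drop(z %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    step <- solve(crossprod(z, z * w) + pen,
                  crossprod(z, y - mu) - pen %*% beta)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  list(coef = beta, ridged = TRUE)
}

#' Leave-one-trial-out logistic decoding accuracy
#'
#' Projects the feature matrix onto principal components retaining
#' `variance_fraction` of the variance (fit once on all trials of the tested
#' set by default, mirroring the projection-then-cross-validate order of the
#' source-space analysis; `refit_pca = TRUE` refits inside every fold), then
#' for each trial fits a logistic regression on the remaining trials and
#' predicts the held-out one. Predicted label is `"A"` when the predicted
#' probability of A is >= 0.5 (ties go to A, deterministically).
#'
#' @param features Trials x features numeric matrix.
#' @param labels Per-trial labels in `{"A","B"}`; both must be present.
#' @param variance_fraction PCA variance fraction (default 0.99).
#' @param refit_pca Refit the projection within each cross-validation fold.
#' @return A list of class `loo_result`: `accuracy`, `n_correct`,
#'   `n_trials`, `dims`, `n_ridged` (folds that needed the ridge fallback).
#' @export
loo_logistic_accuracy <- function(features, labels,
                                  variance_fraction = 0.99,
                                  refit_pca = FALSE) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 6) stop("need at least 6 trials for leave-one-out decoding")
  y <- as.integer(labels == "A")
  if (all(y == 1) || all(y == 0))
    stop("both category labels must be present")
  n_ridged <- 0L
  if (!refit_pca) {
    pr <- project_pca(x, variance_fraction, max_dims = n - 2L)
    z <- cbind(1, pr$scores)
    start <- .fit_logistic(z, y)$coef
    correct <- logical(n)
    for (i in seq_len(n)) {
      fit <- .fit_logistic(z[-i, , drop = FALSE], y[-i], start = start)
      if (fit$ridged) n_ridged <- n_ridged + 1L
      p_a <- stats::plogis(drop(z[i, ] %*% fit$coef))
      correct[i] <- (p_a >= 0.5) == (y[i] == 1L)
    }
    dims <- pr$dims
  } else {
    correct <- logical(n)
    dims_i <- integer(n)
    for (i in seq_len(n)) {
      pr <- project_pca(x[-i, , drop = FALSE], variance_fraction,
                        max_dims = n - 3L)
      zi <- cbind(1, pr$scores)
      fit <- .fit_logistic(zi, y[-i])
      if (fit$ridged) n_ridged <- n_ridged + 1L
      held <- drop(crossprod(pr$rotation, x[i, ] - pr$center))
      p_a <- stats::plogis(drop(c(1, held) %*% fit$coef))
      correct[i] <- (p_a >= 0.5) == (y[i] == 1L)
      dims_i[i] <- pr$dims
    }
    dims <- as.integer(round(mean(dims_i)))
  }
  structure(list(accuracy = mean(correct), n_correct = sum(correct),
                 n_trials = n, dims = dims, n_ridged = n_ridged),
            class = "loo_result")
}

#' Decoding accuracy over the region x window x phase grid
#'
#' For every region, learning phase (first / last `n_phase` trials) and
#' latency window: select the phase, average the baseline-removed epochs
#' within the window, and run leave-one-trial-out logistic decoding. The
#' default layout yields a 24 x 4 x 2 = 192-row table.
#'
#' @param region_epochs A [simulate_region_ensembles()] result (or any named
#'   list of baseline-removed `epoch_set`s with a `layout` attribute).
#' @param windows Data frame of windows (default [window_specs()]).
#' @param phases Character vector of phases (default early and late).
#' @param n_phase Trials per phase (default 100).
#' @param variance_fraction PCA variance fraction (default 0.99).
#' @return A data frame of class `decoding_table` with columns `region`,
#'   `pathway`, `window_name`, `phase`, `accuracy`, `n_correct`,
#'   `n_trials`, `dims`.
#' @export
decode_grid <- function(region_epochs, windows = window_specs(),
                        phases = c("early", "late"), n_phase = 100L,
                        variance_fraction = 0.99) {
  layout <- attr(region_epochs, "layout")
  pathway_of <- function(r) {
    if (is.null(layout)) NA_character_
    else layout$pathway[match(r, layout$region)]
  }
  rows <- list()
  for (r in names(region_epochs)) {
    for (ph in phases) {
      sel <- select_phase(region_epochs[[r]], ph, n = n_phase)
      for (w in seq_len(nrow(windows))) {
        res <- tryCatch({
          feats <- window_average(sel, windows[w, ])
          loo_logistic_accuracy(feats, sel$labels, variance_fraction)
        }, error = function(e)
          stop("decoding cell (", r, ", ", windows$name[w], ", ", ph,
               "): ", conditionMessage(e)))
        rows[[length(rows) + 1L]] <- data.frame(
          region = r, pathway = pathway_of(r),
          window_name = windows$name[w], phase = ph,
          accuracy = res$accuracy, n_correct = res$n_correct,
          n_trials = res$n_trials, dims = res$dims,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("decoding_table", "data.frame")
  out
}

#' Early-vs-late accuracy change per region and window
#'
#' For every (region, window) cell: the difference late - early in decoding
#' accuracy, with a two-sided two-proportion test (chi-squared with
#' continuity correction) on the correct counts. Identical accuracies give
#' difference 0 and p = 1.
#'
#' @param table A [decode_grid()] result containing both phases.
#' @return A data frame with columns `region`, `pathway`, `window_name`,
#'   `early_accuracy`, `late_accuracy`, `difference`, `p_value`.
#' @export
compare_phases <- function(table) {
  stopifnot(all(c("early", "late") %in% table$phase))
  early <- table[table$phase == "early", ]
  late <- table[table$phase == "late", ]
  key <- c("region", "window_name")
  m <- merge(early, late, by = key, suffixes = c("_early", "_late"))
  p <- mapply(function(xe, ne, xl, nl)
    suppressWarnings(stats::prop.test(c(xl, xe), c(nl, ne))$p.value),
    m$n_correct_early, m$n_trials_early, m$n_correct_late, m$n_trials_late)
  out <- data.frame(region = m$region, pathway = m$pathway_early,
                    window_name = m$window_name,
                    early_accuracy = m$accuracy_early,
                    late_accuracy = m$accuracy_late,
                    difference = m$accuracy_late - m$accuracy_early,
                    p_value = p, stringsAsFactors = FALSE)
  out[order(out$region, out$window_name), ]
}

#' Pool decoding accuracy by cortical pathway
#'
#' Per window and phase, the trial-weighted pooled accuracy (total correct /
#' total trials) over the VVP regions and over the PFC regions, their
#' difference, and a two-sided two-proportion test on the pooled counts.
#'
#' @param table A [decode_grid()] result with a `pathway` column.
#' @return A data frame with columns `window_name`, `phase`,
#'   `pooled_accuracy_vvp`, `pooled_accuracy_pfc`, `difference`, `p_value`.
#' @export
pool_pathways <- function(table) {
  stopifnot(all(c("VVP", "PFC") %in% table$pathway))
  cells <- unique(table[, c("window_name", "phase")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- table[table$window_name == cells$window_name[i] &
                   table$phase == cells$phase[i], ]
    v <- sub[sub$pathway == "VVP", ]
    f <- sub[sub$pathway == "PFC", ]
    acc_v <- sum(v$n_correct) / sum(v$n_trials)
    acc_f <- sum(f$n_correct) / sum(f$n_trials)
    p <- suppressWarnings(stats::prop.test(
      c(sum(v$n_correct), sum(f$n_correct)),
      c(sum(v$n_trials), sum(f$n_trials)))$p.value)
    data.frame(window_name = cells$window_name[i], phase = cells$phase[i],
               pooled_accuracy_vvp = acc_v, pooled_accuracy_pfc = acc_f,
               difference = acc_v - acc_f, p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
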