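#' PCA projection retaining a variance fraction
#'
#' Centers the columns of a trials x features matrix and projects onto the
#' smallest number of leading principal components whose cumulative variance
#' reaches `variance_fraction` (the 99% default guarantees a non-singular
#' pooled covariance in the downstream Hotelling test). The retained
#' dimensionality is additionally capped at `min(trials - 1, features,
#' max_dims)`.
#'
#' @param x Numeric matrix, trials x features, at least 2 rows.
#' @param variance_fraction Fraction in (0, 1\] of total variance to retain.
#' @param max_dims Optional hard cap on retained dimensions (e.g.
#'   `n_a + n_b - 2` for a two-sample test). A cap event is recorded in the
#'   `capped` field.
#' @return A list: `scores` (projected matrix), `dims`, `rotation`,
#'   `center`, `cumulative_variance`, `capped`.
#' @export
project_pca <- function(x, variance_fraction = 0.99, max_dims = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2, variance_fraction > 0, variance_fraction <= 1)
  ctr <- colMeans(x)
  xc <- x - rep(ctr, each = nrow(x))
  sv <- svd(xc)
  ev <- sv$d^2
  total <- sum(ev)
  if (total <= 0) stop("all-zero (zero-variance) matrix: nothing to project")
  cumfrac <- cumsum(ev) / total
  dims <- which(cumfrac >= variance_fraction - 1e-12)[1]
  cap <- min(nrow(x) - 1L, ncol(x),
             if (is.null(max_dims)) Inf else max_dims)
  capped <- dims > cap
  dims <- as.integer(min(dims, cap))
  rot <- sv$v[, seq_len(dims), drop = FALSE]
  list(scores = xc %*% rot, dims = dims, rotation = rot, center = ctr,
       cumulative_variance = cumfrac, capped = capped)
}

# Lean two-sample Hotelling T^2 on pre-split score matrices (no validation;
# hot loop of the permutation machinery).
.chi2_core <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  ac <- a - rep(ma, each = na)
  bc <- b - rep(mb, each = nb)
  s <- (crossprod(ac) + crossprod(bc)) / (na + nb - 2)
  delta <- ma - mb
  drop((na * nb / (na + nb)) * crossprod(delta, solve(s, delta)))
}

#' Two-sample Hotelling T-squared test statistic
#'
#' `T^2 = (n_a n_b / (n_a + n_b)) * delta' S^-1 delta` with `delta` the
#' difference of group means and `S` the pooled sample covariance. The
#' statistic is reported as a chi-squared value against the asymptotic
#' `chi^2_dims` reference (the small-sample F correction, negligible at the
#' trial counts this analysis uses, is available via `f_correct`).
#'
#' @param group_a,group_b Numeric matrices with the same number of columns
#'   (projected trial vectors per group).
#' @param f_correct If `TRUE`, also report the exact F-statistic
#'   `(n - p - 1) / (p (n - 2)) * T^2` and its `F(p, n - p - 1)` p-value.
#' @return An object of class `hotelling_result`: `t2`, `chi2` (= `t2`),
#'   `dims`, `n_a`, `n_b`, and with `f_correct` also `f_stat`, `f_p_value`.
#' @export
hotelling_chi2 <- function(group_a, group_b, f_correct = FALSE) {
  a <- as.matrix(group_a); b <- as.matrix(group_b)
  stopifnot(ncol(a) == ncol(b))
  p <- ncol(a); na <- nrow(a); nb <- nrow(b)
  if (na + nb - 2 < p)
    stop("pooled covariance not invertible: ", p, " dimensions but only ",
         na + nb, " trials; project to fewer components first")
  t2 <- tryCatch(.chi2_core(a, b), error = function(e)
    stop("singular pooled covariance (was PCA projection skipped or ",
         "insufficient?): ", conditionMessage(e)))
  out <- list(t2 = t2, chi2 = t2, dims = p, n_a = na, n_b = nb)
  if (f_correct) {
    n <- na + nb
    out$f_stat <- (n - p - 1) / (p * (n - 2)) * t2
    out$f_p_value <- stats::pf(out$f_stat, p, n - p - 1, lower.tail = FALSE)
  }
  structure(out, class = "hotelling_result")
}

# Per-bin pooled-PCA projections of a binned epoch set. The projection is a
# function of the pooled trial matrix only, so it is identical under any
# label permutation; computing it once per bin is exactly equivalent to
# refitting inside each permutation.
.bin_scores <- function(binned, variance_fraction, max_dims) {
  nb <- length(binned$bin_centers_ms)
  out <- vector("list", nb)
  for (k in seq_len(nb)) {
    out[[k]] <- tryCatch(
      project_pca(binned$data[, , k], variance_fraction, max_dims = max_dims),
      error = function(e)
        stop("bin ", k, " (center ", binned$bin_centers_ms[k], " ms): ",
             conditionMessage(e)))
  }
  out
}

.trace_from_scores <- function(scores, is_a) {
  chi2 <- numeric(length(scores))
  for (k in seq_along(scores)) {
    s <- scores[[k]]$scores
    chi2[k] <- .chi2_core(s[is_a, , drop = FALSE], s[!is_a, , drop = FALSE])
  }
  chi2
}

#' Time-resolved category-discriminability trace
#'
#' Per time bin: pool all trials into a trials x channels matrix, project it
#' onto the principal components retaining `variance_fraction` of the
#' variance, and apply the two-sample Hotelling test between the two label
#' groups. The per-bin chi-squared statistics form the discriminability
#' trace; the retained dimensionality per bin is recorded so null
#' comparisons are dimension-matched.
#'
#' @param binned A [sliding_average()] result.
#' @param labels Per-trial labels (default those carried by `binned`).
#' @param variance_fraction PCA variance fraction (default 0.99).
#' @return An object of class `discriminability_trace`: `bin_centers_ms`,
#'   `chi2`, `dims`.
#' @export
discriminability_trace <- function(binned, labels = binned$labels,
                                   variance_fraction = 0.99) {
  stopifnot(inherits(binned, "binned_epochs"))
  is_a <- labels == "A"
  n_a <- sum(is_a); n_b <- sum(!is_a)
  if (n_a == 0 || n_b == 0) stop("both labels must be present")
  scores <- .bin_scores(binned, variance_fraction, max_dims = n_a + n_b - 2L)
  structure(list(bin_centers_ms = binned$bin_centers_ms,
                 chi2 = .trace_from_scores(scores, is_a),
                 dims = vapply(scores, `[[`, integer(1), "dims")),
            class = "discriminability_trace")
}

#' Label-shuffled null discriminability traces
#'
#' Recomputes the full discriminability trace under `n_perm` random
#' permutations of the category labels (the label multiset is preserved),
#' giving the chance-level null distribution of the trace. The per-bin PCA
#' projection is fit on the pooled trial matrix, which label permutation
#' leaves unchanged, so each permuted trace uses the identical
#' dimension-matched projection pipeline as the observed trace.
#'
#' @param binned A [sliding_average()] result.
#' @param labels Per-trial labels (default those carried by `binned`).
#' @param n_perm Number of label permutations (default 100).
#' @param seed Optional integer seed for the permutation stream.
#' @param variance_fraction PCA variance fraction (default 0.99).
#' @return An object of class `null_trace_set`: `traces` (n_perm x bins
#'   matrix), `bin_centers_ms`, `dims`, `n_perm`, `seed`.
#' @export
shuffled_traces <- function(binned, labels = binned$labels, n_perm = 100L,
                            seed = NULL, variance_fraction = 0.99) {
  stopifnot(inherits(binned, "binned_epochs"), n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  is_a <- labels == "A"
  n_a <- sum(is_a); n_b <- sum(!is_a)
  if (n_a == 0 || n_b == 0) stop("both labels must be present")
  n <- length(labels)
  scores <- .bin_scores(binned, variance_fraction, max_dims = n_a + n_b - 2L)
  traces <- matrix(NA_real_, nrow = n_perm,
                   ncol = length(binned$bin_centers_ms))
  for (i in seq_len(n_perm)) {
    perm_a <- is_a[sample.int(n)]
    traces[i, ] <- .trace_from_scores(scores, perm_a)
  }
  structure(list(traces = traces, bin_centers_ms = binned$bin_centers_ms,
                 dims = vapply(scores, `[[`, integer(1), "dims"),
                 n_perm = as.integer(n_perm), seed = seed),
            class = "null_trace_set")
}

#' Export a discriminability trace and its null set as delimited text
#'
#' Writes one CSV with columns `bin_center_ms`, `chi2`, `dims`, plus one
#' `perm_i` column per permutation when `nulls` is given.
#'
#' @param trace A [discriminability_trace()] result.
#' @param file Output CSV path.
#' @param nulls Optional [shuffled_traces()] result on the same bin grid.
#' @return `file`, invisibly.
#' @export
write_trace <- function(trace, file, nulls = NULL) {
  stopifnot(inherits(trace, "discriminability_trace"))
  out <- data.frame(bin_center_ms = trace$bin_centers_ms, chi2 = trace$chi2,
                    dims = trace$dims)
  if (!is.null(nulls)) {
    stopifnot(identical(nulls$bin_centers_ms, trace$bin_centers_ms))
    nm <- t(nulls$traces)
    colnames(nm) <- sprintf("perm_%03d", seq_len(nulls$n_perm))
    out <- cbind(out, nm)
  }
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
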