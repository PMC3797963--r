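#' Supra-threshold excursion regions of a discriminability trace
#'
#' Proposes temporal regions of interest: maximal runs of consecutive bins
#' whose statistic exceeds `threshold`, keeping only runs of at least
#' `min_run` bins (isolated single supra-threshold bins are pruned as likely
#' chance events). Each region's mass is the sum of the statistic over its
#' bins. The default threshold of 20 is the value used for the source-space
#' chi-squared traces.
#'
#' @param trace A [discriminability_trace()] result, or a bare numeric
#'   vector of per-bin statistics.
#' @param threshold Positive excursion threshold (default 20).
#' @param min_run Minimum run length in bins (default 2).
#' @param bin_centers_ms Bin centers; taken from `trace` when it is a trace
#'   object.
#' @return An object of class `excursion_regions`: `regions` (data frame
#'   `start_bin`, `end_bin`, `start_ms`, `end_ms`, `mass`; zero rows when no
#'   run survives) and `threshold`.
#' @export
find_excursions <- function(trace, threshold = 20, min_run = 2L,
                            bin_centers_ms = NULL) {
  stopifnot(threshold > 0, min_run >= 1)
  if (inherits(trace, "discriminability_trace")) {
    if (is.null(bin_centers_ms)) bin_centers_ms <- trace$bin_centers_ms
    chi2 <- trace$chi2
  } else chi2 <- as.numeric(trace)
  if (is.null(bin_centers_ms)) bin_centers_ms <- seq_along(chi2)
  above <- chi2 > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  regions <- data.frame(
    start_bin = starts[keep], end_bin = ends[keep],
    start_ms = bin_centers_ms[starts[keep]],
    end_ms = bin_centers_ms[ends[keep]],
    mass = vapply(keep, function(i)
      sum(chi2[starts[i]:ends[i]]), numeric(1)))
  structure(list(regions = regions, threshold = threshold,
                 min_run = as.integer(min_run)),
            class = "excursion_regions")
}

.excursion_summary <- function(regions, summary) {
  if (nrow(regions$regions) == 0) return(0)
  switch(summary,
         max_mass = max(regions$regions$mass),
         total_mass = sum(regions$regions$mass))
}

#' Permutation p-value of the observed excursion regions
#'
#' Applies the same excursion procedure to every label-shuffled null trace
#' and compares summary statistics: by default the maximum region mass (the
#' max-statistic construction controlling family-wise error over time;
#' `"total_mass"` sums all region masses instead). The p-value is
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`, so with 100 permutations the
#' smallest attainable value is 1/101; an empty observed region set yields
#' p = 1.
#'
#' @param observed A [find_excursions()] result for the observed trace.
#' @param nulls A [shuffled_traces()] result on the same bin grid.
#' @param threshold Threshold applied to the null traces (default: the one
#'   stored in `observed`).
#' @param summary `"max_mass"` (default) or `"total_mass"`.
#' @return An object of class `excursion_test`: `observed`,
#'   `null_max_masses`, `p_value`, `summary_statistic`, `summary`.
#' @export
excursion_pvalue <- function(observed, nulls, threshold = observed$threshold,
                             summary = c("max_mass", "total_mass")) {
  stopifnot(inherits(observed, "excursion_regions"),
            inherits(nulls, "null_trace_set"))
  summary <- match.arg(summary)
  obs <- .excursion_summary(observed, summary)
  null_masses <- apply(nulls$traces, 1, function(tr)
    .excursion_summary(find_excursions(tr, threshold = threshold,
                                       min_run = observed$min_run,
                                       bin_centers_ms = nulls$bin_centers_ms),
                       summary))
  p <- (1 + sum(null_masses >= obs)) / (nulls$n_perm + 1)
  if (nrow(observed$regions) == 0) p <- 1
  structure(list(observed = observed, null_max_masses = null_masses,
                 p_value = p, summary_statistic = obs, summary = summary),
            class = "excursion_test")
}

#' Combine subject-level p-values with Fisher's method
#'
#' The statistic `-2 * sum(log(p_i))` is referred to the upper tail of the
#' chi-squared distribution with `2 k` degrees of freedom. Combining seven
#' subject minima of 1/101 (100 permutations, zero exceedances) gives the
#' group bound of about 1.8e-8.
#'
#' @param p_values Vector of p-values, each in (0, 1\].
#' @return An object of class `fisher_combination`: `subject_p_values`,
#'   `fisher_statistic`, `combined_p`, `df`.
#' @export
fisher_combine <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(p_values <= 0) || any(p_values > 1) || any(!is.finite(p_values)))
    stop("all p-values must lie in (0, 1]")
  stat <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  structure(list(subject_p_values = p_values, fisher_statistic = stat,
                 combined_p = stats::pchisq(stat, df, lower.tail = FALSE),
                 df = df),
            class = "fisher_combination")
}

#' Export excursion-test results as delimited text / JSON
#'
#' Writes `regions.csv` (start_ms, end_ms, mass), `null_summaries.csv`, and
#' `test.json` (threshold, summary type, observed summary, p-value) under
#' `dir`.
#'
#' @param test An [excursion_pvalue()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_excursion_test <- function(test, dir) {
  stopifnot(inherits(test, "excursion_test"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(test$observed$regions[, c("start_ms", "end_ms", "mass")],
                   file.path(dir, "regions.csv"), row.names = FALSE)
  utils::write.csv(data.frame(null_summary = test$null_max_masses),
                   file.path(dir, "null_summaries.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(threshold = test$observed$threshold, summary = test$summary,
         observed_summary = test$summary_statistic, p_value = test$p_value),
    file.path(dir, "test.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
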