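#' Draw a pair of blob category prototypes
#'
#' A blob category is defined by a prototype: a vector of 20 edge proportions,
#' each the distance of a polygon vertex from the origin expressed as a
#' fraction (30--70%) of the distance to a point on the unit circle. Two
#' prototypes define the two-category stimulus space; within-category jitter
#' is Gaussian with per-edge standard deviation `jitter_scale` times the
#' absolute per-edge difference between the two prototypes, so category spread
#' scales with category separation along each dimension.
#'
#' @param seed Integer seed; the draw is deterministic given `seed`. `NULL`
#'   uses the current RNG state.
#' @param min_mean_separation Minimum mean per-edge absolute difference
#'   between the two prototypes; pairs are redrawn until it is met. The
#'   default 0 accepts the first draw.
#' @param jitter_scale Proportionality constant linking per-edge jitter
#'   standard deviation to the per-edge prototype difference (default 0.2).
#' @param n_edges Number of polygon edges (dimensions); default 20.
#' @param max_tries Cap on rejection redraws before signalling that the
#'   requested separation is infeasible.
#' @return An object of class `blob_prototype_pair` with fields
#'   `prototype_a`, `prototype_b`, `jitter_scale`, `seed`.
#' @export
make_prototype_pair <- function(seed = NULL, min_mean_separation = 0,
                                jitter_scale = 0.2, n_edges = 20L,
                                max_tries = 1000L) {
  stopifnot(min_mean_separation >= 0, jitter_scale > 0, n_edges >= 1)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    a <- stats::runif(n_edges, 0.3, 0.7)
    b <- stats::runif(n_edges, 0.3, 0.7)
    if (mean(abs(a - b)) >= min_mean_separation) {
      return(structure(
        list(prototype_a = a, prototype_b = b,
             jitter_scale = jitter_scale, seed = seed),
        class = "blob_prototype_pair"))
    }
  }
  stop("could not draw a prototype pair with mean per-edge separation >= ",
       min_mean_separation, " in ", max_tries, " tries; the request is ",
       "infeasible for uniform prototypes on [0.3, 0.7]")
}

#' Sample one blob exemplar around a category prototype
#'
#' Adds independent Gaussian jitter to the category's prototype, with per-edge
#' standard deviation `jitter_scale * |prototype_a - prototype_b|`. Edges
#' falling outside (0.05, 0.95) are resampled edge-wise (retry-capped) so that
#' every exemplar renders as a valid polygon. Uses the current RNG state.
#'
#' @param pair A [make_prototype_pair()] object.
#' @param category `"A"` or `"B"`.
#' @param exemplar_id Integer identifier carried along (default `NA`).
#' @param retry_cap Per-call cap on resampling rounds.
#' @return An object of class `blob_exemplar` with fields `edges`,
#'   `category`, `exemplar_id`.
#' @export
sample_exemplar <- function(pair, category = c("A", "B"),
                            exemplar_id = NA_integer_, retry_cap = 100L) {
  stopifnot(inherits(pair, "blob_prototype_pair"))
  category <- match.arg(category)
  proto <- if (category == "A") pair$prototype_a else pair$prototype_b
  sd_edge <- pair$jitter_scale * abs(pair$prototype_a - pair$prototype_b)
  edges <- stats::rnorm(length(proto), proto, sd_edge)
  bad <- which(edges <= 0.05 | edges >= 0.95)
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > retry_cap)
      stop("degenerate jitter configuration: edge values cannot be kept in ",
           "(0.05, 0.95) within ", retry_cap, " resampling rounds")
    edges[bad] <- stats::rnorm(length(bad), proto[bad], sd_edge[bad])
    bad <- bad[edges[bad] <= 0.05 | edges[bad] >= 0.95]
  }
  structure(list(edges = edges, category = category,
                 exemplar_id = as.integer(exemplar_id)),
            class = "blob_exemplar")
}

# Balanced category sequence for one block: when the per-category block count
# divides into sub-blocks of <= 10 per category, shuffle within 10+10
# sub-blocks so that every sub-block boundary is exactly balanced (this makes
# the first/last 100 trials of the default 600-trial design hold 50 A and
# 50 B); otherwise shuffle the whole block.
.balanced_block_sequence <- function(n_a, n_b) {
  stopifnot(n_a == n_b)
  m <- ceiling(n_a / 10)
  if (n_a %% m == 0L) {
    s <- n_a / m
    unlist(lapply(seq_len(m), function(i) sample(rep(c("A", "B"), each = s))))
  } else {
    sample(rep(c("A", "B"), each = n_a))
  }
}

#' Generate a full two-category stimulus set with presentation order
#'
#' Draws `n_per_category` unique exemplars per category and a presentation
#' order in which category counts are balanced within each of `n_blocks`
#' equal blocks (the session structure: 600 trials in 5 blocks by default).
#' Balance is additionally enforced within 20-trial sub-blocks when block
#' sizes allow, so the first and last 100 trials of the default design are
#' exactly balanced.
#'
#' @param pair A [make_prototype_pair()] object.
#' @param n_per_category Exemplars per category (default 300); must be
#'   divisible by `n_blocks`.
#' @param n_blocks Number of session blocks (default 5).
#' @param seed Optional integer seed for determinism.
#' @return An object of class `stimulus_set`: `exemplars` (list of
#'   [sample_exemplar()] objects, A then B), `edges` (matrix, one row per
#'   exemplar), `presentation` (data frame `trial_index`, `exemplar_id`,
#'   `category`, `block`), and `pair`.
#' @export
generate_stimulus_set <- function(pair, n_per_category = 300L, n_blocks = 5L,
                                  seed = NULL) {
  stopifnot(inherits(pair, "blob_prototype_pair"), n_per_category >= 1)
  if (n_per_category %% n_blocks != 0L)
    stop("n_per_category (", n_per_category, ") must be divisible by the ",
         "block count (", n_blocks, ")")
  if (!is.null(seed)) set.seed(seed)
  n_total <- 2L * n_per_category
  exemplars <- vector("list", n_total)
  for (i in seq_len(n_per_category)) {
    exemplars[[i]] <- sample_exemplar(pair, "A", exemplar_id = i)
    exemplars[[n_per_category + i]] <-
      sample_exemplar(pair, "B", exemplar_id = n_per_category + i)
  }
  per_block <- n_per_category / n_blocks
  cats <- unlist(lapply(seq_len(n_blocks),
                        function(b) .balanced_block_sequence(per_block,
                                                             per_block)))
  # map category slots to exemplar ids in random order, each used once
  a_ids <- sample(seq_len(n_per_category))
  b_ids <- sample(n_per_category + seq_len(n_per_category))
  ids <- integer(n_total)
  ids[cats == "A"] <- a_ids
  ids[cats == "B"] <- b_ids
  presentation <- data.frame(
    trial_index = seq_len(n_total),
    exemplar_id = ids,
    category = cats,
    block = rep(seq_len(n_blocks), each = 2L * per_block),
    stringsAsFactors = FALSE)
  edges <- t(vapply(exemplars, `[[`, numeric(length(pair$prototype_a)),
                    "edges"))
  structure(list(exemplars = exemplars, edges = edges,
                 presentation = presentation, pair = pair,
                 n_blocks = n_blocks),
            class = "stimulus_set")
}

#' Render a blob exemplar as polygon vertex coordinates
#'
#' Vertex `k` (1-based) sits at angle `2*pi*(k-1)/n` on a ray from the origin,
#' at distance `edges[k] * radius`.
#'
#' @param exemplar A [sample_exemplar()] object (or bare numeric edge vector).
#' @param radius Scale of the enclosing circle; must be positive.
#' @return A matrix with one row per vertex and columns `x`, `y`.
#' @export
blob_to_polygon <- function(exemplar, radius = 1) {
  stopifnot(radius > 0)
  edges <- if (inherits(exemplar, "blob_exemplar")) exemplar$edges
           else as.numeric(exemplar)
  n <- length(edges)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = edges * radius * cos(theta), y = edges * radius * sin(theta))
}

#' PCA characterization of a stimulus set
#'
#' Eigen-decomposes the covariance of the pooled exemplar edge matrix (both
#' categories). With the default generator ~90% of the variance falls in the
#' first one to two components, reflecting the dominant prototype-difference
#' axis; the first-component edge weights show which edges carry the
#' category-discriminative variation.
#'
#' @param stimulus_set A [generate_stimulus_set()] object, or a numeric
#'   matrix of edge vectors (one row per exemplar).
#' @return An object of class `blob_pca_summary`: `cumulative_variance`
#'   (fractions, nondecreasing, last entry 1) and `first_component_weights`
#'   (unit-norm loading vector, sign fixed so its largest-magnitude entry is
#'   positive).
#' @export
pca_summary <- function(stimulus_set) {
  x <- if (inherits(stimulus_set, "stimulus_set")) stimulus_set$edges
       else as.matrix(stimulus_set)
  if (nrow(x) < 3L) stop("need at least 3 exemplars for a PCA summary")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) <= 0) stop("degenerate stimulus set: zero total variance")
  cumvar <- cumsum(v) / sum(v)
  # pad to the full dimensionality when n - 1 < n_edges
  if (length(cumvar) < ncol(x))
    cumvar <- c(cumvar, rep(1, ncol(x) - length(cumvar)))
  w <- pc$rotation[, 1]
  if (w[which.max(abs(w))] < 0) w <- -w
  structure(list(cumulative_variance = cumvar,
                 first_component_weights = w / sqrt(sum(w^2))),
            class = "blob_pca_summary")
}

#' Write / read a stimulus set as delimited text
#'
#' `write_stimulus_set` writes `stimuli.csv` (exemplar_id, category, one
#' column per edge) and `presentation.csv` (trial_index, exemplar_id) under
#' `dir`; `read_stimulus_set` reads them back into the same structure (the
#' prototype pair is not persisted).
#'
#' @param stimulus_set A [generate_stimulus_set()] object.
#' @param dir Output directory (created if needed).
#' @return `write_stimulus_set` returns `dir` invisibly; `read_stimulus_set`
#'   returns a list with `edges`, `categories`, `presentation`.
#' @export
write_stimulus_set <- function(stimulus_set, dir) {
  stopifnot(inherits(stimulus_set, "stimulus_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- stimulus_set$edges
  colnames(edges) <- sprintf("edge_%02d", seq_len(ncol(edges)))
  stim <- data.frame(
    exemplar_id = vapply(stimulus_set$exemplars, `[[`, integer(1),
                         "exemplar_id"),
    category = vapply(stimulus_set$exemplars, `[[`, character(1), "category"),
    edges, stringsAsFactors = FALSE)
  utils::write.csv(stim, file.path(dir, "stimuli.csv"), row.names = FALSE)
  utils::write.csv(stimulus_set$presentation[, c("trial_index",
                                                 "exemplar_id")],
                   file.path(dir, "presentation.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(dir) {
  stim <- utils::read.csv(file.path(dir, "stimuli.csv"),
                          stringsAsFactors = FALSE)
  pres <- utils::read.csv(file.path(dir, "presentation.csv"))
  edge_cols <- grep("^edge_", names(stim))
  list(edges = as.matrix(stim[, edge_cols]),
       categories = stim$category,
       presentation = pres)
}
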