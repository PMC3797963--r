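test_that("prototype pairs stay in range, are deterministic, and match the uniform-difference law", {
  pair <- make_prototype_pair(seed = 1)
  expect_length(pair$prototype_a, 20)
  expect_true(all(c(pair$prototype_a, pair$prototype_b) >= 0.3))
  expect_true(all(c(pair$prototype_a, pair$prototype_b) <= 0.7))
  expect_identical(make_prototype_pair(seed = 1), pair)

  # per-edge |difference| of two independent uniforms on a width-0.4
  # interval has expectation 0.4/3 = 2/15
  set.seed(99)
  diffs <- replicate(1000, {
    p <- make_prototype_pair()
    mean(abs(p$prototype_a - p$prototype_b))
  })
  expect_equal(mean(diffs), 2 / 15, tolerance = 0.01 / (2 / 15))
})

test_that("separation rejection honors the request and caps infeasible ones", {
  pair <- make_prototype_pair(seed = 3, min_mean_separation = 0.15)
  expect_gte(mean(abs(pair$prototype_a - pair$prototype_b)), 0.15)
  expect_error(make_prototype_pair(seed = 3, min_mean_separation = 0.39,
                                   max_tries = 50),
               "infeasible")
})

test_that("exemplar jitter follows the stated noise law", {
  pair <- make_prototype_pair(seed = 7)
  # zero-noise limit: jitter_scale ~ 0 reproduces the prototype
  pair0 <- pair
  pair0$jitter_scale <- 1e-12
  ex <- sample_exemplar(pair0, "A")
  expect_equal(ex$edges, pair$prototype_a, tolerance = 1e-9)

  # empirical per-edge sd over 10,000 draws matches 0.2 * |difference|
  set.seed(11)
  draws <- t(replicate(10000, sample_exemplar(pair, "B")$edges))
  sd_target <- pair$jitter_scale * abs(pair$prototype_a - pair$prototype_b)
  expect_true(all(abs(apply(draws, 2, sd) / sd_target - 1) < 0.05))
  expect_true(all(draws > 0 & draws < 1))
})

test_that("stimulus sets are balanced per block and exemplars unique", {
  stim <- tiny_stimulus_set(seed = 5, n_per_category = 300L)
  pres <- stim$presentation
  expect_equal(nrow(pres), 600)
  counts <- table(pres$block, pres$category)
  expect_true(all(counts == 60))
  # each 100-trial phase of the default design is exactly balanced
  expect_equal(sum(pres$category[1:100] == "A"), 50)
  expect_equal(sum(pres$category[501:600] == "A"), 50)
  expect_false(any(duplicated(stim$edges)))
  expect_setequal(pres$exemplar_id, 1:600)

  tiny <- tiny_stimulus_set(seed = 5, n_per_category = 5L)
  expect_true(all(table(tiny$presentation$block,
                        tiny$presentation$category) == 1))
  expect_error(generate_stimulus_set(stim$pair, n_per_category = 7L),
               "divisible")
})

test_that("polygon rendering follows the vertex-angle convention", {
  reg <- blob_to_polygon(rep(0.5, 20), radius = 1)
  expect_equal(sqrt(rowSums(reg^2)), rep(0.5, 20))
  expect_equal(colMeans(reg), c(x = 0, y = 0), tolerance = 1e-12)
  # rotating the edge vector by one position rotates the polygon by 18 deg
  # (vertex k of the shifted polygon is vertex k-1 of the original, rotated)
  e <- seq(0.3, 0.68, by = 0.02)
  rot <- blob_to_polygon(c(e[20], e[1:19]))
  ang <- 2 * pi / 20
  rot_mat <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  expect_equal(unname(rot[c(2:20, 1), ]),
               unname(blob_to_polygon(e) %*% t(rot_mat)),
               tolerance = 1e-12)
  expect_error(blob_to_polygon(e, radius = 0))
})

test_that("PCA summary has nondecreasing cumulative variance and isolates a rank-1 direction", {
  stim <- tiny_stimulus_set(seed = 6, n_per_category = 50L)
  ps <- pca_summary(stim)
  expect_true(all(diff(ps$cumulative_variance) >= -1e-12))
  expect_equal(ps$cumulative_variance[20], 1, tolerance = 1e-12)
  expect_equal(sum(ps$first_component_weights^2), 1, tolerance = 1e-12)

  # variation confined to edge 1 -> all first-component weight on edge 1
  x <- matrix(0.5, nrow = 50, ncol = 20)
  x[, 1] <- x[, 1] + rnorm(50, sd = 0.05)
  ps1 <- pca_summary(x)
  expect_equal(abs(ps1$first_component_weights[1]), 1, tolerance = 1e-9)
  expect_equal(ps1$cumulative_variance[1], 1, tolerance = 1e-9)
  expect_error(pca_summary(matrix(0.5, nrow = 10, ncol = 20)), "degenerate")
})

test_that("first principal component aligns with the prototype difference and separates the categories", {
  pair <- make_prototype_pair(seed = 8)
  stim <- generate_stimulus_set(pair, seed = 9)
  ps <- pca_summary(stim)
  delta <- pair$prototype_a - pair$prototype_b
  delta <- delta / sqrt(sum(delta^2))
  expect_gt(abs(sum(ps$first_component_weights * delta)), 0.95)

  # 1-d Bayes error along PC1 (equal-variance Gaussian approximation) < 5%
  pc <- stats::prcomp(stim$edges)
  proj <- pc$x[, 1]
  is_a <- vapply(stim$exemplars, `[[`, character(1), "category") == "A"
  d_prime <- abs(mean(proj[is_a]) - mean(proj[!is_a])) /
    sqrt((stats::var(proj[is_a]) + stats::var(proj[!is_a])) / 2)
  expect_lt(stats::pnorm(-d_prime / 2), 0.05)
})

test_that("stimulus sets round-trip through delimited text", {
  stim <- tiny_stimulus_set(seed = 10)
  dir <- withr::local_tempdir()
  write_stimulus_set(stim, dir)
  back <- read_stimulus_set(dir)
  expect_equal(unname(back$edges), unname(stim$edges), tolerance = 1e-12)
  expect_equal(back$presentation$exemplar_id,
               stim$presentation$exemplar_id)
})
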