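test_that("PCA projection honors rank, variance fraction and caps", {
  # rank-1 matrix -> one dimension, 100% variance
  x1 <- outer(rnorm(30), rnorm(5))
  p1 <- project_pca(x1, 0.99)
  expect_equal(p1$dims, 1L)
  expect_equal(p1$cumulative_variance[1], 1, tolerance = 1e-9)

  set.seed(41)
  x <- matrix(rnorm(100 * 50), 100)
  pf <- project_pca(x, 1.0)
  expect_equal(pf$dims, 50L)
  p99 <- project_pca(x, 0.99)
  # reconstruction from retained components explains >= 99% of variance
  xc <- scale(x, scale = FALSE)
  resid <- xc - p99$scores %*% t(p99$rotation)
  expect_gte(1 - sum(resid^2) / sum(xc^2), 0.99)
  expect_lte(p99$dims, min(99, 50))
  # hard cap flags and truncates
  pc <- project_pca(x, 1.0, max_dims = 10)
  expect_equal(pc$dims, 10L)
  expect_true(pc$capped)
  expect_error(project_pca(matrix(0, 10, 4)), "zero")
})

test_that("Hotelling statistic matches its closed forms", {
  # identical group means -> T^2 = 0
  base <- matrix(rnorm(40 * 3), 40)
  shift <- matrix(rnorm(40 * 3), 40)
  expect_equal(hotelling_chi2(base, base)$t2, 0, tolerance = 1e-24)

  # one dimension: T^2 equals the squared pooled-variance t statistic
  set.seed(42)
  a <- matrix(rnorm(25, 1), ncol = 1)
  b <- matrix(rnorm(30, 0), ncol = 1)
  ht <- hotelling_chi2(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(ht$t2, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_identical(ht$chi2, ht$t2)
  expect_equal(ht$dims, 1L)

  # affine invariance: any invertible linear map leaves T^2 unchanged
  set.seed(43)
  a3 <- matrix(rnorm(20 * 3, 0.5), ncol = 3)
  b3 <- matrix(rnorm(22 * 3), ncol = 3)
  m <- matrix(c(2, 0.3, -1, 0.5, 1.5, 0.2, 0, -0.7, 1), 3)
  t2_orig <- hotelling_chi2(a3, b3)$t2
  t2_map <- hotelling_chi2(a3 %*% m, b3 %*% m)$t2
  expect_equal(t2_map, t2_orig, tolerance = 1e-8 * t2_orig)

  # duplicating every trial roughly doubles T^2 (exactly 2(n-1)/(n-2))
  n <- nrow(a3) + nrow(b3)
  t2_dup <- hotelling_chi2(a3[rep(1:20, 2), ], b3[rep(1:22, 2), ])$t2
  expect_equal(t2_dup, 2 * t2_orig * (n - 1) / (n - 2), tolerance = 1e-8)

  expect_error(hotelling_chi2(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "invertible")
  # F-corrected variant reports the exact reference
  hf <- hotelling_chi2(a3, b3, f_correct = TRUE)
  expect_equal(hf$f_stat, (n - 3 - 1) / (3 * (n - 2)) * hf$t2)
})

test_that("trace localizes an injected effect and scales with trial count", {
  stim <- tiny_stimulus_set(seed = 44, n_per_category = 50L)
  layout <- default_region_layout(dipole_count = 8)[1, ]
  eff <- list(effect_spec(layout$region[1], window_ms = c(150, 250),
                          amplitude = 1.5,
                          learning = learning_params(1, 1, 0, 0)))
  peaks <- sapply(1:5, function(s) {
    regs <- simulate_region_ensembles(stim, layout, eff, seed = 44 + s)
    tr <- discriminability_trace(sliding_average(remove_baseline(regs[[1]])))
    tr$bin_centers_ms[which.max(tr$chi2)]
  })
  expect_true(all(peaks >= 150 & peaks < 250))
})

test_that("null traces have chi-squared moments and preserved label multisets", {
  set.seed(45)
  stats <- replicate(50, {
    ep <- noise_region_epochs(seed = sample.int(1e6, 1),
                              n_per_category = 100L, dipole_count = 6L)
    tr <- discriminability_trace(sliding_average(ep))
    c(ratio = mean(tr$chi2) / mean(tr$dims),
      exceed = mean(tr$chi2 > qchisq(0.95, tr$dims)))
  })
  # chi^2_d has mean d (the exact T^2 reference inflates it by (n-2)/(n-3-d))
  expect_equal(mean(stats["ratio", ]), 1, tolerance = 0.1)
  # calibration: ~5% of null bins exceed the chi^2 95th percentile
  expect_equal(mean(stats["exceed", ]), 0.05, tolerance = 0.02 / 0.05)

  ep <- noise_region_epochs(seed = 46, n_per_category = 25L,
                            dipole_count = 4L)
  binned <- sliding_average(ep)
  nulls <- shuffled_traces(binned, n_perm = 12, seed = 47)
  expect_equal(dim(nulls$traces), c(12, 39))
  expect_true(all(nulls$traces >= 0))
  # determinism of the permutation stream
  nulls2 <- shuffled_traces(binned, n_perm = 12, seed = 47)
  expect_identical(nulls$traces, nulls2$traces)
  # a shuffled-label trace equals the observed trace of the shuffled labels
  set.seed(47)
  perm <- sample.int(length(binned$labels))
  tr_manual <- discriminability_trace(binned, binned$labels[perm])
  expect_equal(nulls$traces[1, ], tr_manual$chi2, tolerance = 1e-10)
})

test_that("trace is invariant to channel order and nonnegative", {
  ep <- noise_region_epochs(seed = 48, n_per_category = 20L,
                            dipole_count = 5L)
  binned <- sliding_average(ep)
  tr <- discriminability_trace(binned)
  expect_true(all(tr$chi2 >= 0))
  perm <- c(3, 1, 5, 2, 4)
  ep_perm <- epoch_set(ep$data[, perm, , drop = FALSE], ep$labels,
                       ep$trial_index, ep$time_ms, kind = "region")
  tr_perm <- discriminability_trace(sliding_average(ep_perm))
  expect_equal(tr_perm$chi2, tr$chi2, tolerance = 1e-8)
})

test_that("peak discriminability grows monotonically with effect amplitude", {
  stim <- tiny_stimulus_set(seed = 49, n_per_category = 50L)
  layout <- default_region_layout(dipole_count = 8)[1, ]
  amps <- c(0.25, 0.5, 1, 2, 4)
  mean_peak <- sapply(amps, function(a) {
    eff <- list(effect_spec(layout$region[1], window_ms = c(150, 250),
                            amplitude = a,
                            learning = learning_params(1, 1, 0, 0)))
    mean(sapply(1:8, function(s) {
      regs <- simulate_region_ensembles(stim, layout, eff,
                                        seed = 1000 * a + s)
      max(discriminability_trace(
        sliding_average(remove_baseline(regs[[1]])))$chi2)
    }))
  })
  expect_equal(cor(amps, mean_peak, method = "spearman"), 1)
})
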