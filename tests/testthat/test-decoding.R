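test_that("window averaging reduces epochs to per-channel means", {
  const <- epoch_set(array(3, dim = c(4, 2, 80)), rep(c("A", "B"), 2), 1:4,
                     seq(0, 395, by = 5), kind = "region")
  expect_true(all(window_average(const, c(50, 150)) == 3))
  # full-epoch window equals the per-trial temporal mean
  set.seed(61)
  ep <- epoch_set(array(rnorm(4 * 2 * 80), dim = c(4, 2, 80)),
                  rep(c("A", "B"), 2), 1:4, seq(0, 395, by = 5),
                  kind = "region")
  expect_equal(window_average(ep, c(0, 400)),
               apply(ep$data, c(1, 2), mean), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(window_average(ep, c(396, 400)), "no samples")
})

test_that("window-averaged effect size matches the raised-cosine closed form", {
  stim <- tiny_stimulus_set(seed = 62, n_per_category = 20L)
  layout <- default_region_layout(dipole_count = 4)[1, ]
  amp <- 1.7
  eff <- list(effect_spec(layout$region[1], window_ms = c(150, 250),
                          amplitude = amp,
                          learning = learning_params(1, 1, 0, 0)))
  regs <- simulate_region_ensembles(stim, layout, eff,
                                    noise = quiet_noise(), seed = 63)
  feats <- window_average(remove_baseline(regs[[1]]), c(150, 250))
  is_a <- regs[[1]]$labels == "A"
  gap <- colMeans(feats[is_a, ]) - colMeans(feats[!is_a, ])
  # mean of the raised cosine over its own window is exactly 1/2;
  # uniform unit-norm pattern over 4 dipoles contributes 1/2 per dipole
  expect_equal(unname(gap), rep(2 * amp * 0.5 * 0.5, 4), tolerance = 0.02)
})

test_that("leave-one-out logistic decoding hits its limit cases", {
  # perfectly separated 1-d features -> accuracy 1
  x <- matrix(c(rnorm(20, 5), rnorm(20, -5)), ncol = 1)
  lab <- rep(c("A", "B"), each = 20)
  res <- loo_logistic_accuracy(x, lab)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$n_trials, 40)

  # shuffled labels on noise -> accuracy within the 95% binomial band
  set.seed(64)
  xn <- matrix(rnorm(100 * 8), 100)
  labn <- sample(rep(c("A", "B"), 50))
  rn <- loo_logistic_accuracy(xn, labn)
  band <- qbinom(c(0.025, 0.975), 100, 0.5) / 100
  expect_gte(rn$accuracy, band[1])
  expect_lte(rn$accuracy, band[2])

  # duplicated feature columns: PCA removes the collinearity, accuracy equal
  rd <- loo_logistic_accuracy(cbind(xn, xn), labn)
  expect_equal(rd$accuracy, rn$accuracy)

  expect_error(loo_logistic_accuracy(xn, rep("A", 100)), "both")
  expect_error(loo_logistic_accuracy(xn[1:4, ], labn[1:4]), "at least 6")
  # deterministic: no randomness in the cross-validation loop
  expect_identical(loo_logistic_accuracy(xn, labn)$accuracy, rn$accuracy)
  # fold-wise PCA refit is available and behaves
  rf <- loo_logistic_accuracy(xn, labn, refit_pca = TRUE)
  expect_gte(rf$accuracy, band[1] - 0.1)
})

test_that("LOO decoding agrees fold-for-fold with an independent glm route", {
  set.seed(67)
  for (rep in 1:3) {
    x <- matrix(rnorm(60 * 6), 60)
    lab <- sample(rep(c("A", "B"), 30))
    mine <- loo_logistic_accuracy(x, lab)
    pc <- prcomp(x)
    k <- which(cumsum(pc$sdev^2) / sum(pc$sdev^2) >= 0.99)[1]
    z <- pc$x[, 1:k, drop = FALSE]
    y <- as.integer(lab == "A")
    pred <- vapply(1:60, function(i) {
      df <- data.frame(y = y[-i], z[-i, , drop = FALSE])
      fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial))
      p <- predict(fit, newdata = data.frame(z[i, , drop = FALSE]),
                   type = "response")
      (p >= 0.5) == (y[i] == 1)
    }, logical(1))
    expect_equal(mine$accuracy, mean(pred))
    expect_equal(mine$dims, k)
  }
})

test_that("decode grid covers the region x window x phase cross", {
  stim <- tiny_stimulus_set(seed = 65, n_per_category = 20L)
  layout <- default_region_layout(dipole_count = 4)[c(1, 2, 13), ]
  eff <- list(effect_spec(layout$region[1], window_ms = c(150, 250),
                          amplitude = 3,
                          learning = learning_params(0.05, 1, 20, 0.5)))
  regs <- simulate_region_ensembles(stim, layout, eff, seed = 66)
  regs[] <- lapply(regs, remove_baseline)
  tab <- decode_grid(regs, n_phase = 16L)
  expect_equal(nrow(tab), 3 * 4 * 2)
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_equal(unique(tab$n_trials), 16)
  expect_setequal(unique(tab$pathway), c("VVP", "PFC"))
  # the injected late-learning effect shows up where it was put
  cell <- tab[tab$region == layout$region[1] & tab$window_name == "M200", ]
  expect_gt(cell$accuracy[cell$phase == "late"], 0.85)
})

test_that("phase comparison uses the two-proportion test", {
  tab <- data.frame(
    region = rep("r1", 2), pathway = "VVP", window_name = "M200",
    phase = c("early", "late"), accuracy = c(0.5, 0.83),
    n_correct = c(50L, 83L), n_trials = c(100L, 100L), dims = 4L,
    stringsAsFactors = FALSE)
  cmp <- compare_phases(tab)
  expect_equal(cmp$difference, 0.33)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$p_value,
               prop.test(c(83, 50), c(100, 100))$p.value, tolerance = 1e-12)

  tie <- tab; tie$n_correct <- c(60L, 60L); tie$accuracy <- 0.6
  cmp0 <- compare_phases(tie)
  expect_equal(cmp0$difference, 0)
  expect_equal(cmp0$p_value, 1)
})

test_that("pathway pooling is trial-weighted and order-invariant", {
  tab <- data.frame(
    region = c("v1", "v2", "p1", "p2"),
    pathway = c("VVP", "VVP", "PFC", "PFC"),
    window_name = "M200", phase = "late",
    accuracy = c(0.9, 0.7, 0.5, 0.5),
    n_correct = c(90L, 70L, 50L, 50L),
    n_trials = 100L, dims = 4L, stringsAsFactors = FALSE)
  pool <- pool_pathways(tab)
  expect_equal(pool$pooled_accuracy_vvp, 0.8)
  expect_equal(pool$pooled_accuracy_pfc, 0.5)
  expect_equal(pool$difference, 0.3)
  pool_rev <- pool_pathways(tab[4:1, ])
  expect_equal(pool_rev$pooled_accuracy_vvp, pool$pooled_accuracy_vvp)

  # all regions at exactly chance -> both pooled at 0.5, difference 0
  flat <- tab; flat$n_correct <- 50L; flat$accuracy <- 0.5
  pf <- pool_pathways(flat)
  expect_equal(pf$difference, 0)
  expect_equal(pf$p_value, 1)
})
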