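test_that("target transform log10-standardizes and inverts exactly", {
  m <- hand_map(c(10, 1000), ladder = amplitude_ladder(5, 2000, 10))
  tt <- transform_targets(m, c(0, 1), use_log = TRUE)
  expect_equal(tt$values, c(-1, 1))  # log10 -> (1, 3), center 2, scale 1
  expect_equal(tt$transform$center, 2)
  expect_equal(tt$transform$scale, 1)
  expect_false(tt$transform$scale_clamped)
  # round trip to 1e-12 relative
  expect_equal(inverse_transform(tt$values, tt$transform), c(10, 1000),
               tolerance = 1e-12)

  # degenerate constant input: scale clamped, not an error
  mc <- hand_map(c(100, 100))
  ttc <- transform_targets(mc, c(0, 1), use_log = TRUE)
  expect_equal(ttc$values, c(0, 0))
  expect_true(ttc$transform$scale_clamped)
  expect_equal(inverse_transform(ttc$values, ttc$transform), c(100, 100))
})

test_that("log marginal likelihood matches scalar closed forms and the dense oracle", {
  X1 <- matrix(c(0, 0), 1)
  sp1 <- kernel_spec("rbf", signal_variance = 1, length_scale = 1,
                     noise_variance = 0)
  # one point, K = [1]: LML = -y^2/2 - log(2 pi)/2
  expect_equal(log_marginal_likelihood(sp1, X1, 0), -0.5 * log(2 * pi),
               tolerance = 1e-8)
  expect_equal(log_marginal_likelihood(sp1, X1, 2), -2 - 0.5 * log(2 * pi),
               tolerance = 1e-8)
  expect_equal(-0.5 * log(2 * pi), -0.91894, tolerance = 1e-5)

  # multi-point problems against the explicit-inverse oracle, all families
  set.seed(4)
  for (family in c("rbf", "matern15", "hybrid")) {
    for (n in c(2, 10)) {
      X <- matrix(runif(2 * n, 0, 9), n, 2)
      y <- rnorm(n)
      sp <- kernel_spec(family, signal_variance = 1.4, length_scale = 2.5,
                        length_scale_rbf = 1.5, length_scale_matern = 4,
                        mix_weight = 0.6, noise_variance = 0.1)
      K <- kernel_matrix(sp, X, include_noise = TRUE)
      expect_equal(log_marginal_likelihood(sp, X, y), oracle_lml(K, y),
                   tolerance = 1e-8)
    }
  }
})

test_that("posterior mean and variance match the dense linear-algebra oracle", {
  # hand-set hyperparameters, 2-point and 10-point problems, all families
  set.seed(9)
  g <- electrode_grid(6, 10)
  for (family in c("rbf", "matern15", "hybrid")) {
    for (n in c(2, 10)) {
      sp <- kernel_spec(family, signal_variance = 1.2, length_scale = 3,
                        length_scale_rbf = 2, length_scale_matern = 5,
                        mix_weight = 0.35, noise_variance = 0.05)
      train <- sample(0:59, n)
      lad <- amplitude_ladder(40, 677, 60)
      thr <- rep(NA_real_, 60)
      thr[] <- sample(lad$values[1:59], 60, replace = TRUE)
      map <- threshold_map(g, thr, ladder = lad)
      fit <- gp_fit(map, train, family = family, optimize = FALSE, spec = sp,
                    n_restarts = 1)
      query <- setdiff(0:59, train)[1:5]
      pr <- predict(fit, query)

      Xtr <- g$positions[train + 1, , drop = FALSE]
      Xq <- g$positions[query + 1, , drop = FALSE]
      K <- kernel_matrix(sp, Xtr, include_noise = TRUE) + diag(1e-10, n)
      Kc <- kernel_matrix(sp, Xq, Xtr)
      orc <- oracle_gp_posterior(
        K, Kc, rep(sp$signal_variance + sp$noise_variance, 5), fit$y)
      expect_equal(pr$mean_transformed, orc$mean, tolerance = 1e-8)
      expect_equal(pr$std_transformed, sqrt(pmax(orc$var, 0)),
                   tolerance = 1e-8)
      expect_equal(pr$mean_uA,
                   inverse_transform(orc$mean, fit$transform),
                   tolerance = 1e-8)
    }
  }
})

test_that("predictions near-interpolate training electrodes at tiny noise", {
  map <- generate_map(make_preset("smooth", seed = 3))
  ids <- which(map$grid$active) - 1L
  train <- ids[seq(1, length(ids), by = 2)]
  sp <- kernel_spec("matern15", signal_variance = 1, length_scale = 3,
                    noise_variance = 1e-5)
  fit <- gp_fit(map, train, family = "matern15", optimize = FALSE, spec = sp)
  pr <- predict(fit, train)
  expect_true(all(abs(pr$mean_uA / map$thresholds[train + 1] - 1) < 0.005))
  expect_true(all(pr$std_transformed >= 0))
})

test_that("far queries revert to the prior", {
  # train at one end of a long thin array, query the far end
  g <- electrode_grid(1, 120)
  lad <- amplitude_ladder(40, 677, 60)
  thr <- rep(lad$values[30], 120)
  thr[1:5] <- lad$values[c(10, 20, 30, 40, 50)]
  map <- threshold_map(g, thr, ladder = lad)
  sp <- kernel_spec("rbf", signal_variance = 0.8, length_scale = 1,
                    noise_variance = 0.04)
  fit <- gp_fit(map, 0:4, family = "rbf", optimize = FALSE, spec = sp)
  pr <- predict(fit, 119)  # distance 115 >> l
  expect_equal(pr$mean_transformed, 0, tolerance = 1e-3)
  expect_equal(pr$std_transformed, sqrt(0.8 + 0.04), tolerance = 1e-3)
})

test_that("empty queries and grid membership are handled", {
  map <- generate_map(make_preset("smooth", seed = 5))
  fit <- gp_fit(map, c(0, 5, 12, 30), family = "rbf", n_restarts = 2, seed = 1)
  expect_equal(nrow(predict(fit, integer(0))), 0)
  expect_error(predict(fit, 999), "grid")
})

test_that("fit respects bounds, never worsens the objective, and is deterministic", {
  map <- generate_map(make_preset("smooth", seed = 2))
  train <- sample_poisson_disk(map$grid, 25, seed = 4)$ordered_ids
  for (family in c("rbf", "matern15", "hybrid")) {
    fit <- gp_fit(map, train, family = family, n_restarts = 4, seed = 7)
    co <- coef(fit)
    b <- fit$kernel_spec$bounds
    for (nm in names(co)) {
      expect_gte(co[[nm]], b[[nm]][1] - 1e-9)
      expect_lte(co[[nm]], b[[nm]][2] + 1e-9)
    }
    expect_gte(fit$lml, fit$lml_init - 1e-9)
    fit2 <- gp_fit(map, train, family = family, n_restarts = 4, seed = 7)
    expect_identical(coef(fit), coef(fit2))
    expect_identical(fit$lml, fit2$lml)
  }
})

test_that("fit recovers a known length scale within a factor of two", {
  # data simulated from a known matern15 GP on the grid; the fitted length
  # scale should land within [l/2, 2l] in most replicates
  g <- electrode_grid(6, 10)
  l_true <- 3
  sp_true <- kernel_spec("matern15", signal_variance = 1,
                         length_scale = l_true, noise_variance = 0.01)
  lad <- amplitude_ladder(1, 1e5, 200)
  hits <- 0
  n_rep <- 10
  for (rep in seq_len(n_rep)) {
    K <- kernel_matrix(sp_true, g$positions, include_noise = TRUE)
    set.seed(100 + rep)
    z <- as.numeric(t(chol(K)) %*% rnorm(60))
    thr <- pmin(pmax(10^(2 + 0.3 * z), 1), 1e5)
    map <- threshold_map(g, thr, ladder = lad)
    train <- sample_uniform(g, 40, seed = rep)$ordered_ids
    fit <- gp_fit(map, train, family = "matern15", n_restarts = 5, seed = rep)
    l_hat <- coef(fit)[["length_scale"]]
    if (l_hat >= l_true / 2 && l_hat <= l_true * 2) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("censored electrodes are excluded from training by default", {
  cfg <- make_preset("censored-heavy", seed = 6)
  map <- generate_map(cfg)
  expect_gt(sum(map$censored), 0)
  act <- which(map$grid$active) - 1L
  fit <- gp_fit(map, act, family = "rbf", n_restarts = 2, seed = 1)
  expect_true(all(!map$censored[fit$train_ids + 1]))
  fit_inc <- gp_fit(map, act, family = "rbf", n_restarts = 2, seed = 1,
                    include_censored = TRUE)
  expect_gt(length(fit_inc$train_ids), length(fit$train_ids))
})

test_that("single-electrode training is allowed but flagged", {
  map <- generate_map(make_preset("smooth", seed = 8))
  expect_warning(fit <- gp_fit(map, 0, family = "rbf"), "single")
  pr <- predict(fit, 59)
  expect_true(is.finite(pr$mean_uA))
})

test_that("posterior variance shrinks as training points are added", {
  map <- generate_map(make_preset("smooth", seed = 10))
  sp <- kernel_spec("rbf", signal_variance = 1, length_scale = 3,
                    noise_variance = 0.05)
  act <- which(map$grid$active) - 1L
  train <- act[1:6]
  extra <- act[7]
  query <- act[10:20]
  f1 <- gp_fit(map, train, family = "rbf", optimize = FALSE, spec = sp)
  f2 <- gp_fit(map, c(train, extra), family = "rbf", optimize = FALSE,
               spec = sp)
  v1 <- predict(f1, query)$std_transformed^2
  v2 <- predict(f2, query)$std_transformed^2
  expect_true(all(v2 <= v1 + 1e-10))
  # at training electrodes the (latent + noise) variance is at most about
  # the noise floor
  vt <- predict(f2, c(train, extra))$std_transformed^2
  expect_true(all(vt <= 2 * sp$noise_variance + 1e-6))
})

test_that("the pipeline is scale-equivariant under the log transform", {
  g <- electrode_grid(3, 4)
  lad <- amplitude_ladder(1, 1e6, 100)
  thr <- c(50, 80, 120, 200, 60, 90, 150, 220, 70, 110, 160, 300)
  c0 <- 2.5
  m1 <- threshold_map(g, thr, ladder = lad)
  m2 <- threshold_map(g, thr * c0, ladder = lad)
  sp <- kernel_spec("matern15", signal_variance = 1, length_scale = 2,
                    noise_variance = 0.01)
  f1 <- gp_fit(m1, 0:7, family = "matern15", optimize = FALSE, spec = sp)
  f2 <- gp_fit(m2, 0:7, family = "matern15", optimize = FALSE, spec = sp)
  expect_equal(f1$y, f2$y, tolerance = 1e-12)  # standardization absorbs scale
  p1 <- predict(f1, 8:11)
  p2 <- predict(f2, 8:11)
  expect_equal(p1$mean_transformed, p2$mean_transformed, tolerance = 1e-10)
  expect_equal(p2$mean_uA, p1$mean_uA * c0, tolerance = 1e-10)
})

test_that("fit serialization round-trips through JSON", {
  map <- generate_map(make_preset("smooth", seed = 12))
  fit <- gp_fit(map, c(1, 7, 22, 35, 48), family = "hybrid",
                n_restarts = 2, seed = 5)
  path <- file.path(tempdir(), "fit.json")
  write_gp_fit(fit, path)
  back <- read_gp_fit(path)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
  expect_equal(predict(back)$mean_uA, predict(fit)$mean_uA, tolerance = 1e-9)
  unlink(path)
})
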