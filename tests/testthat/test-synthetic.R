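test_that("random_stable_model is stable, seeded, and honors a forced pole", {
  m1 <- random_stable_model(1, dt = 0.01, seed = 3, pole_band = c(-3, -3))
  expect_equal(m1$A, matrix(-3))

  for (n in 1:5) {
    m <- random_stable_model(n, dt = 0.002, seed = 10 + n)
    expect_lt(max(Re(eigen(m$A)$values)), 0)
    # conjugate pairing: response is real by construction
    expect_false(is.complex(m$A))
  }

  expect_identical(random_stable_model(4, seed = 6)$A,
                   random_stable_model(4, seed = 6)$A)
  expect_error(random_stable_model(2, pole_band = c(1, 2)), "negative")
})

test_that("impulse responses of generated models decay", {
  m <- random_stable_model(4, dt = 0.002, seed = 8, pole_band = c(-12, -2))
  # 4 s is many times the slowest (1/2 s) time constant
  g <- impulse_response(m, 2000, 0.002)$samples
  expect_lt(abs(g[2000]), max(abs(g)) * 1e-2)
})

test_that("simulate_erp is exact when noiseless and seeded when noisy", {
  m <- random_stable_model(3, dt = 0.002, seed = 15)
  clean <- simulate_erp(m, 200, noise_sd = 0)
  expect_identical(clean$samples, impulse_response(m, 200, 0.002)$samples)

  n1 <- simulate_erp(m, 471, noise_sd = 0.4, seed = 5)
  n2 <- simulate_erp(m, 471, noise_sd = 0.4, seed = 5)
  expect_identical(n1$samples, n2$samples)

  # injected noise variance concentrates near its nominal value
  resid <- n1$samples - simulate_erp(m, 471, noise_sd = 0)$samples
  expect_lt(abs(var(resid) - 0.4^2), 0.2 * 0.4^2)
})

test_that("baseline samples are noise-only and precede the response", {
  m <- random_stable_model(2, dt = 0.002, seed = 44)
  g <- simulate_erp(m, 100, noise_sd = 0, baseline_samples = 30)
  expect_equal(g$samples[1:30], rep(0, 30))
  expect_equal(g$samples[31:100], impulse_response(m, 70, 0.002)$samples)
})

test_that("generate_dataset yields the configured geometry, balanced and seeded", {
  cfg <- generator_config(n_per_class = 5, n_electrodes = 3, n_samples = 100,
                          seed = 7)
  ds <- generate_dataset(cfg)
  expect_equal(dim(ds$data), c(10, 3, 100))
  expect_equal(as.vector(table(ds$labels)), c(5, 5))
  expect_equal(ds$baseline_samples, 70)
  gt <- attr(ds, "ground_truth")
  expect_length(gt$go, 3)
  expect_length(gt$nogo, 3)

  # pure function of the config
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$data, ds2$data)

  # classes differ in their clean dynamics
  expect_false(isTRUE(all.equal(gt$go[[1]]$A, gt$nogo[[1]]$A)))
})

test_that("default configuration matches the study geometry", {
  cfg <- generator_config()
  expect_equal(2 * cfg$n_per_class, 510)
  expect_equal(cfg$n_electrodes, 62)
  expect_equal(cfg$n_samples, 471)
  expect_equal(cfg$dt, 0.002)
  expect_equal(cfg$baseline_samples, 70)
})

test_that("noiseless generated electrodes are recovered by the order search", {
  cfg <- generator_config(n_per_class = 1, n_electrodes = 2, n_samples = 150,
                          baseline_samples = 0L, noise_sd = 0, true_order = 4,
                          seed = 23)
  ds <- generate_dataset(cfg)
  gt <- attr(ds, "ground_truth")
  for (e in 1:2) {
    g <- impulse_response(ds$data[1, e, ], dt = cfg$dt)
    fit <- fit_optimal_order(g, n_min = 1, n_cap = 8)
    g_hat <- suppressWarnings(impulse_response(fit$model, 150, cfg$dt))
    expect_lt(max(abs(g_hat$samples - g$samples)), 1e-6 * max(abs(g$samples)))
    # and the fitted tf matches the ground-truth model's response
    g_true <- impulse_response(gt$go[[e]], 150, cfg$dt)
    expect_lt(max(abs(g_hat$samples - g_true$samples)),
              1e-6 * max(abs(g_true$samples)))
  }
})

test_that("noisy fits attain mse near the injected noise power", {
  cfg <- generator_config(n_per_class = 2, n_electrodes = 2, n_samples = 200,
                          noise_sd = 0.05, seed = 31)
  ds <- generate_dataset(cfg)
  noise_power <- (cfg$noise_sd * cfg$amplitude)^2
  for (e in 1:2) {
    g <- impulse_response(ds$data[1, e, 71:200], dt = cfg$dt)
    fit <- fit_optimal_order(g, n_min = 1, n_cap = 10)
    expect_lte(fit$mse, 2 * noise_power)
  }
})

test_that("class_effect zero makes the two classes share clean dynamics", {
  cfg <- generator_config(n_per_class = 2, n_electrodes = 1, n_samples = 80,
                          class_effect = 0, noise_sd = 0, seed = 3)
  ds <- generate_dataset(cfg)
  expect_identical(ds$data[1, 1, ], ds$data[3, 1, ])
})

test_that("classification difficulty tracks noise level and class effect", {
  # scaled-down grid: accuracy should not degrade when noise drops or the
  # class effect grows (one inversion tolerated for simulation error)
  run_one <- function(noise, effect) {
    cfg <- generator_config(n_per_class = 12, n_electrodes = 6,
                            n_samples = 150, baseline_samples = 0L,
                            noise_sd = noise, class_effect = effect, seed = 17)
    fm <- build_feature_matrix(generate_dataset(cfg),
                               fit_config(target_order = 8, n_cap = 10))
    kfold_cv(fm$values, fm$labels, "KNN", k = 4, seed = 2,
             n_components = 3, pca_scale = TRUE)$mean_accuracy
  }
  acc_noise <- vapply(c(0.02, 0.1, 0.5), run_one, numeric(1), effect = 0.15)
  acc_effect <- vapply(c(0.05, 0.15, 0.3), run_one, numeric(1), noise = 0.1)
  expect_lte(sum(diff(acc_noise) > 0.05), 1)    # non-increasing in noise
  expect_lte(sum(diff(acc_effect) < -0.05), 1)  # non-decreasing in effect
  expect_gt(acc_noise[1], acc_noise[3] - 1e-9)
})
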