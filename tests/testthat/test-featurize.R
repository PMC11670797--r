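test_that("unfold concatenates electrodes time-major and refold inverts it", {
  data <- array(0, dim = c(1, 2, 2))
  data[1, 1, ] <- c(1, 2)  # electrode 1: a, b
  data[1, 2, ] <- c(3, 4)  # electrode 2: c, d
  ds <- epoch_dataset(data, labels = "g", dt = 0.002)
  expect_equal(unname(unfold(ds)[1, ]), c(1, 2, 3, 4))
})

test_that("unfold shape accounting matches the study geometry", {
  # geometry only: contents are irrelevant, use a thin random array
  set.seed(2)
  ds <- tiny_dataset(P = 6, Ne = 3, Tn = 40)
  X <- unfold(ds)
  expect_equal(dim(X), c(6, 120))
  back <- refold(X, 3, 40)
  expect_identical(back, ds$data)
})

test_that("truncate_window slices time and adjusts the baseline count", {
  ds <- tiny_dataset(P = 4, Ne = 2, Tn = 80)
  full <- truncate_window(ds, 1, 80)
  expect_identical(full$data, ds$data)

  win <- truncate_window(ds, 21, 40)
  expect_equal(dim(win$data)[3], 40)
  expect_identical(win$data[, , 1], ds$data[, , 21])
  expect_equal(win$baseline_samples, 0)

  expect_error(truncate_window(ds, 60, 40), "outside")
})

test_that("stimulus-onset window arithmetic holds at study scale", {
  # 471 samples at 500 Hz with a 140 ms baseline: onset at sample 71,
  # a 250-sample window ends at sample 320 (+498 ms)
  cfg <- generator_config(n_per_class = 1, n_electrodes = 1)
  expect_equal(cfg$baseline_samples, 70)
  ds <- generate_dataset(cfg)
  win <- truncate_window(ds, cfg$baseline_samples + 1, 250)
  expect_equal(dim(win$data)[3], 250)
  expect_equal(win$baseline_samples, 0)
})

test_that("tf_to_features pads, truncates and splits deterministically", {
  tf <- transfer_function(c(0, 1), c(3, 2))  # 1/(s^2+3s+2)
  f <- tf_to_features(tf, target_order = 20)
  expect_length(f, 80)
  # numerator block: 40 values, only the constant-term real slot is 1
  num <- f[1:40]
  expect_equal(unname(num[39]), 1)   # degree-0 real slot
  expect_equal(sum(num != 0), 1)
  den <- f[41:80]
  expect_equal(unname(den[37]), 3)   # degree-1 real slot
  expect_equal(unname(den[39]), 2)   # degree-0 real slot
  expect_equal(sum(den != 0), 2)
  # real tf: all imaginary slots exactly zero
  expect_true(all(f[seq(2, 80, by = 2)] == 0))

  # truncation drops the highest-degree coefficients
  tf5 <- transfer_function(5:1, 10:6)
  f3 <- tf_to_features(tf5, target_order = 3)
  expect_equal(unname(f3[seq(1, 5, by = 2)]), c(3, 2, 1))
  expect_equal(unname(f3[seq(7, 11, by = 2)]), c(8, 7, 6))

  # complex coefficients land in the imaginary slots
  fc <- tf_to_features(transfer_function(1 + 2i, 3 - 1i), target_order = 2)
  expect_equal(unname(fc), c(0, 0, 1, 2, 0, 0, 3, -1))
})

test_that("build_feature_matrix has fixed width and deterministic output", {
  ds <- tiny_dataset(P = 2, Ne = 1, Tn = 60)
  cfgf <- fit_config(target_order = 20, n_min = 1, n_cap = 6)
  fm <- build_feature_matrix(ds, cfgf)
  expect_equal(dim(fm$values), c(2, 80))
  expect_length(fm$feature_names, 80)
  expect_false(any(fm$failed))
  expect_true(all(is.finite(fm$values)))

  # identical inputs give bit-identical features
  fm2 <- build_feature_matrix(ds, cfgf)
  expect_identical(fm$values, fm2$values)

  # duplicated signals give identical rows
  ds2 <- ds
  ds2$data[2, , ] <- ds2$data[1, , ]
  fm3 <- build_feature_matrix(ds2, cfgf)
  expect_identical(fm3$values[1, ], fm3$values[2, ])
})

test_that("featurized transfer functions reconstruct noiseless signals", {
  # fidelity: rebuild the signal from the padded coefficients via the
  # observable canonical realization of the stored feature slots
  for (n in c(2, 4)) {
    m <- random_stable_model(n, dt = 0.01, seed = 70 + n)
    g <- model_samples(m, 120, 0.01)
    fit <- fit_optimal_order(g, n_min = 1, n_cap = 8)
    f <- tf_to_features(fit$tf, target_order = 20)
    num <- complex(real = f[seq(1, 40, 2)], imaginary = f[seq(2, 40, 2)])
    den <- complex(real = f[seq(41, 80, 2)], imaginary = f[seq(42, 80, 2)])
    # strip the zero padding to recover the fitted order, then re-realize
    lead <- which(num != 0 | den != 0)[1]
    tf_back <- transfer_function(num[lead:20], den[lead:20])
    g_back <- suppressWarnings(
      impulse_response(to_observable_canonical(tf_back), 120, 0.01))
    expect_lt(fitting_error(g, g_back), 1e-8 * mean(g$samples^2))
  }
})

test_that("feature width scales as N_e * 4 * target_order", {
  ds <- tiny_dataset(P = 2, Ne = 3, Tn = 50)
  fm <- build_feature_matrix(ds, fit_config(target_order = 5, n_min = 1, n_cap = 4))
  expect_equal(ncol(fm$values), 3 * 4 * 5)
  expect_match(fm$feature_names[1], "^E01_num_d4_re$")
})
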