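test_that("realize recovers closed-form first-order dynamics", {
  g <- first_order_signal(n = 100, dt = 0.01)
  m <- realize(factor_hankel(build_hankel(g), nx = 1), dt = 0.01)
  expect_equal(Re(eigen(m$A)$values), -3, tolerance = 1e-6)
  expect_equal(Re((m$C %*% m$B)[1]), 2, tolerance = 1e-6)
})

test_that("realize recovers damped-oscillator poles -1 +/- 2i", {
  g <- damped_osc_signal(n = 100, dt = 0.01)
  m <- realize(factor_hankel(build_hankel(g), nx = 2), dt = 0.01)
  ev <- sort(eigen(m$A)$values)
  expect_equal(sort(c(-1 + 2i, -1 - 2i)), ev, tolerance = 1e-6)
})

test_that("impulse response of simple models matches scalar exponentials", {
  m <- state_space(-1, 1, 1)
  expect_equal(impulse_response(m, 3, dt = 0.5)$samples,
               c(1, exp(-0.5), exp(-1)))
  expect_equal(impulse_response(state_space(0, 1, 1), 5, dt = 0.3)$samples,
               rep(1, 5))
})

test_that("unstable models raise an overflow error naming the first bad sample", {
  m <- state_space(400, 1, 1)  # e^(400 t) overflows quickly
  err <- expect_error(impulse_response(m, 2000, dt = 1), "overflow at sample")
  expect_match(conditionMessage(err), "sample [0-9]+")
})

test_that("realization round trip reproduces noiseless signals", {
  set.seed(7)
  for (n in 1:6) {
    m <- random_stable_model(n, dt = 0.02, seed = 40 + n)
    g <- model_samples(m, 150, 0.02)
    mr <- realize(factor_hankel(build_hankel(g), nx = n), dt = 0.02)
    gr <- impulse_response(mr, 150, 0.02)
    expect_lt(max(abs(gr$samples - g$samples)), 1e-6 * max(abs(g$samples)))
  }
})

test_that("impulse response is invariant under similarity transformation", {
  set.seed(21)
  m <- random_stable_model(4, dt = 0.02, seed = 77)
  g0 <- impulse_response(m, 80, 0.02)$samples
  for (r in 1:5) {
    mt <- apply_similarity(m, random_similarity(4))
    expect_lt(max(abs(impulse_response(mt, 80, 0.02)$samples - g0)),
              1e-8 * max(abs(g0)))
  }
})

test_that("markov_parameters follows h(0)=0, h(i)=C A^(i-1) B", {
  expect_equal(markov_parameters(state_space(-3, 2, 1), 3), c(0, 2, -6))
  set.seed(3)
  m <- random_stable_model(3, dt = 0.01, seed = 9)
  h <- markov_parameters(m, 5)
  expect_equal(h[2], (m$C %*% m$B)[1])
})

test_that("fitting_error is the mean squared sample difference", {
  a <- impulse_response(c(1, 2), dt = 0.002)
  expect_equal(fitting_error(a, a), 0)
  expect_equal(fitting_error(a, impulse_response(c(0, 0), dt = 0.002)), 2.5)
  set.seed(12)
  x <- rnorm(40)
  g <- impulse_response(x, dt = 0.01)
  expect_equal(fitting_error(g, impulse_response(x + 1, dt = 0.01)), 1)
  expect_error(fitting_error(g, impulse_response(x[1:10], dt = 0.01)), "length")
})

test_that("fit_optimal_order finds a low order on noiseless oscillators", {
  g <- damped_osc_signal(n = 100, dt = 0.05)
  fit <- fit_optimal_order(g, n_min = 1, n_cap = 6)
  expect_gte(fit$chosen_order, 2)
  expect_lt(fit$mse, 1e-10)
  # trace covers each order once, strictly increasing, and mse is its minimum
  expect_equal(fit$order_trace$order, sort(unique(fit$order_trace$order)))
  expect_equal(fit$mse, min(fit$order_trace$mse))
  expect_equal(fit$chosen_order,
               fit$order_trace$order[which.min(fit$order_trace$mse)])
})

test_that("fit_optimal_order defaults start the search at order 17", {
  expect_equal(formals(fit_optimal_order)$n_min, 17L)
  expect_equal(formals(fit_optimal_order)$n_cap, 26L)
})

test_that("degenerate all-zero signals are rejected", {
  g <- impulse_response(rep(0, 60), dt = 0.01)
  expect_error(fit_optimal_order(g, n_min = 1, n_cap = 4), "degenerate")
})

test_that("realized models of sign-alternating data may be complex-valued", {
  # a sampled decaying alternation has a negative discrete eigenvalue, whose
  # principal log is complex
  g <- impulse_response((-0.8)^(0:30), dt = 0.1)
  m <- realize(factor_hankel(build_hankel(g), nx = 1), dt = 0.1)
  expect_true(is.complex(m$A))
  expect_equal(Im(eigen(m$A)$values[1]), pi / 0.1, tolerance = 1e-6)
  gf <- suppressWarnings(impulse_response(m, 31, 0.1))
  expect_lt(max(abs(gf$samples - g$samples)), 1e-6)
})
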