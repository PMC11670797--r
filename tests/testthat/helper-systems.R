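# Closed-form test systems and small utilities shared across tests.

# g(t) = 2 exp(-3 t): order-1 system A = -3, C B = 2
first_order_signal <- function(n = 100, dt = 0.01) {
  impulse_response(2 * exp(-3 * (seq_len(n) - 1) * dt), dt = dt)
}

# g(t) = exp(-t) sin(2 t): order-2 system with poles -1 +/- 2i
damped_osc_signal <- function(n = 100, dt = 0.01) {
  t <- (seq_len(n) - 1) * dt
  impulse_response(exp(-t) * sin(2 * t), dt = dt)
}

# random invertible similarity transform with bounded condition number
random_similarity <- function(n) {
  repeat {
    T <- matrix(stats::rnorm(n * n), n, n)
    if (rcond(T) > 1e-3) return(T)
  }
}

apply_similarity <- function(m, T) {
  state_space(A = T %*% m$A %*% solve(T), B = T %*% m$B,
              C = m$C %*% solve(T), dt = m$dt)
}

# noiseless samples of a model (exact simulation, no noise)
model_samples <- function(m, n, dt) impulse_response(m, n_samples = n, dt = dt)

# long-division oracle: series coefficients of H(s) in powers of s^-1.
# r starts as the numerator (degrees nx-1..0, then zeros); at step i the
# leading entry is h(i) and h(i) * denominator is subtracted one slot on.
tf_series_coefficients <- function(tf, k) {
  nx <- tf$order
  den <- c(1, tf$denominator)
  r <- c(tf$numerator, rep(0, k))
  h <- vector(mode(r), k)
  for (i in seq_len(k)) {
    h[i] <- r[i]
    r[i:(i + nx)] <- r[i:(i + nx)] - h[i] * den
  }
  h
}

# tiny two-class epoch dataset for featurize/io tests
tiny_dataset <- function(P = 4, Ne = 2, Tn = 60, seed = 11, noise_sd = 0.02) {
  cfg <- generator_config(n_per_class = P / 2, n_electrodes = Ne,
                          n_samples = Tn, baseline_samples = 0L,
                          true_order = 2L, noise_sd = noise_sd, seed = seed)
  generate_dataset(cfg)
}
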