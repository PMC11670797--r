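#' Configuration for the synthetic ERP generator
#'
#' Defaults mirror the geometry of a two-condition Go/NoGo ERP study:
#' 255 averaged signals per class over 62 electrodes, 471 samples at 500 Hz
#' spanning -140 to 800 ms (70 pre-stimulus baseline samples). Each
#' electrode follows damped-oscillatory dynamics of a known low-order
#' state-space model; the two classes differ in damping and frequency of
#' those dynamics (the generator's stand-in for the N2 amplitude/latency
#' difference between conditions), with additive measurement noise.
#'
#' @param n_per_class signals per class.
#' @param n_electrodes electrode count.
#' @param n_samples samples per epoch.
#' @param dt sampling interval in seconds.
#' @param baseline_samples pre-stimulus (noise-only) samples.
#' @param true_order ground-truth model order per electrode.
#' @param class_effect relative shift of damping and frequency between the
#'   classes, in `[0, 1)`.
#' @param noise_sd additive noise standard deviation relative to the peak
#'   response amplitude.
#' @param amplitude peak post-stimulus amplitude in microvolts.
#' @param seed integer seed; the generated dataset is a pure function of
#'   this configuration.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_per_class = 255L, n_electrodes = 62L,
                             n_samples = 471L, dt = 0.002,
                             baseline_samples = 70L, true_order = 4L,
                             class_effect = 0.15, noise_sd = 0.05,
                             amplitude = 10, seed = 1L) {
  stopifnot(n_per_class >= 1L, n_electrodes >= 1L, n_samples >= 2L, dt > 0,
            baseline_samples >= 0L, baseline_samples < n_samples,
            true_order >= 1L, noise_sd >= 0, class_effect >= 0,
            class_effect < 1, amplitude > 0)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_electrodes = as.integer(n_electrodes),
                 n_samples = as.integer(n_samples), dt = dt,
                 baseline_samples = as.integer(baseline_samples),
                 true_order = as.integer(true_order),
                 class_effect = class_effect, noise_sd = noise_sd,
                 amplitude = amplitude, seed = as.integer(seed)),
            class = "generator_config")
}

# draw modal parameters (damping rates, angular frequencies, input/output
# weights) under the caller's RNG stream
draw_modal_params <- function(order, pole_band, freq_band) {
  n_pair <- order %/% 2L
  n_real <- order %% 2L
  list(sigma = stats::runif(n_pair + n_real, pole_band[1L], pole_band[2L]),
       omega = 2 * pi * stats::runif(n_pair, freq_band[1L], freq_band[2L]),
       b = stats::rnorm(order), c = stats::rnorm(order))
}

# assemble a real modal-form model: 2x2 blocks [[sigma, omega], [-omega,
# sigma]] per complex pair, then any real pole; conjugate pairing keeps the
# impulse response real
assemble_modal <- function(par, dt) {
  order <- length(par$b)
  n_pair <- length(par$omega)
  A <- matrix(0, order, order)
  for (q in seq_len(n_pair)) {
    ix <- (2L * q - 1L):(2L * q)
    A[ix, ix] <- matrix(c(par$sigma[q], -par$omega[q], par$omega[q], par$sigma[q]), 2L, 2L)
  }
  if (order %% 2L == 1L) A[order, order] <- par$sigma[n_pair + 1L]
  state_space(A = A, B = par$b, C = par$c, dt = dt)
}

# rescale C so the peak |g| over `horizon` samples equals `amplitude`
scale_to_amplitude <- function(m, amplitude, horizon, dt) {
  g <- impulse_response(m, n_samples = horizon, dt = dt)
  peak <- max(abs(g$samples))
  if (peak == 0) stop("degenerate model with identically zero response", call. = FALSE)
  state_space(A = m$A, B = m$B, C = m$C * (amplitude / peak), dt = dt)
}

#' Draw a random stable state-space model
#'
#' Damping rates (real parts of the eigenvalues) are drawn uniformly from
#' `pole_band` (which must be strictly negative, guaranteeing stability) and
#' oscillation frequencies from `freq_band` (Hz); complex poles come in
#' conjugate pairs so the impulse response is real. The output weights are
#' scaled so the peak response magnitude equals `amplitude`.
#'
#' @param order model order (odd orders get one real pole).
#' @param dt sampling interval in seconds.
#' @param seed integer seed; the same seed yields the same model.
#' @param pole_band range of eigenvalue real parts, in 1/s (negative).
#' @param freq_band range of oscillation frequencies, in Hz.
#' @param amplitude peak impulse-response magnitude.
#' @param horizon samples over which the peak is normalized.
#' @return A real-valued stable [state_space()] model.
#' @export
random_stable_model <- function(order, dt = 0.002, seed = 1L,
                                pole_band = c(-12, -2), freq_band = c(2, 10),
                                amplitude = 10, horizon = 400L) {
  if (length(pole_band) != 2L || any(pole_band >= 0) || pole_band[1L] > pole_band[2L])
    stop("pole_band must be an increasing pair of negative damping rates",
         call. = FALSE)
  par <- with_seed(cell_seed(seed, 2L), draw_modal_params(order, pole_band, freq_band))
  scale_to_amplitude(assemble_modal(par, dt), amplitude, horizon, dt)
}

#' Simulate a noisy ERP-like epoch from a state-space model
#'
#' The post-stimulus segment is the model's impulse response; an optional
#' pre-stimulus baseline of near-zero (noise-only) samples is prepended;
#' independent zero-mean Gaussian noise of standard deviation `noise_sd`
#' (microvolts, absolute) is added throughout.
#'
#' @param model a stable [state_space()] model.
#' @param n_samples total epoch length including the baseline.
#' @param dt sampling interval in seconds.
#' @param noise_sd absolute noise standard deviation; 0 gives the exact
#'   noiseless response.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param baseline_samples pre-stimulus samples.
#' @return An [impulse_response()] epoch of length `n_samples`.
#' @export
simulate_erp <- function(model, n_samples, dt = model$dt, noise_sd = 0,
                         seed = NULL, baseline_samples = 0L) {
  stopifnot(baseline_samples >= 0L, baseline_samples < n_samples)
  clean <- c(rep(0, baseline_samples),
             impulse_response(model, n_samples - baseline_samples, dt)$samples)
  noisy <- if (noise_sd > 0) {
    draw <- function() clean + stats::rnorm(n_samples, sd = noise_sd)
    if (is.null(seed)) draw() else with_seed(cell_seed(seed, 3L), draw())
  } else clean
  impulse_response(noisy, dt = dt)
}

#' Generate a synthetic two-class ERP epoch dataset
#'
#' For every electrode one base model is drawn; the first class ("Go") uses
#' it as is, while the second class ("NoGo") uses a perturbed variant whose
#' damping rates are scaled by `1 - class_effect` (slower decay, larger
#' sustained deflection) and frequencies by `1 + class_effect` (shifted
#' latency). The class difference therefore lives entirely in the dynamics
#' — the quantity the transfer-function features measure — not in additive
#' offsets. Every signal is that electrode's clean class response plus
#' independent noise; the whole dataset is a pure function of the
#' configuration, including its seed.
#'
#' @param cfg a [generator_config()].
#' @return An [epoch_dataset()] (`2 * n_per_class` signals, labels `"Go"`
#'   then `"NoGo"`) with attributes `ground_truth` (per-electrode `go` and
#'   `nogo` ground-truth models) and `config`.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  P <- 2L * cfg$n_per_class
  post <- cfg$n_samples - cfg$baseline_samples
  data <- array(0, dim = c(P, cfg$n_electrodes, cfg$n_samples))
  go_models <- nogo_models <- vector("list", cfg$n_electrodes)
  for (e in seq_len(cfg$n_electrodes)) {
    par <- with_seed(cell_seed(cfg$seed, 10L, e),
                     draw_modal_params(cfg$true_order, c(-12, -2), c(2, 10)))
    go <- scale_to_amplitude(assemble_modal(par, cfg$dt), cfg$amplitude, post, cfg$dt)
    par_b <- par
    par_b$sigma <- par$sigma * (1 - cfg$class_effect)
    par_b$omega <- par$omega * (1 + cfg$class_effect)
    nogo <- state_space(A = assemble_modal(par_b, cfg$dt)$A, B = go$B, C = go$C,
                        dt = cfg$dt)
    go_models[[e]] <- go
    nogo_models[[e]] <- nogo
    clean_go <- c(rep(0, cfg$baseline_samples),
                  impulse_response(go, post, cfg$dt)$samples)
    clean_nogo <- c(rep(0, cfg$baseline_samples),
                    impulse_response(nogo, post, cfg$dt)$samples)
    sd_abs <- cfg$noise_sd * cfg$amplitude
    noise <- if (sd_abs > 0)
      with_seed(cell_seed(cfg$seed, 20L, e),
                matrix(stats::rnorm(P * cfg$n_samples, sd = sd_abs), P, cfg$n_samples))
    else matrix(0, P, cfg$n_samples)
    data[seq_len(cfg$n_per_class), e, ] <-
      noise[seq_len(cfg$n_per_class), , drop = FALSE] +
      matrix(clean_go, cfg$n_per_class, cfg$n_samples, byrow = TRUE)
    data[cfg$n_per_class + seq_len(cfg$n_per_class), e, ] <-
      noise[cfg$n_per_class + seq_len(cfg$n_per_class), , drop = FALSE] +
      matrix(clean_nogo, cfg$n_per_class, cfg$n_samples, byrow = TRUE)
  }
  ds <- epoch_dataset(data,
                      labels = rep(c("Go", "NoGo"), each = cfg$n_per_class),
                      dt = cfg$dt, baseline_samples = cfg$baseline_samples)
  attr(ds, "ground_truth") <- list(go = go_models, nogo = nogo_models)
  attr(ds, "config") <- cfg
  ds
}
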