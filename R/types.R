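#' Construct a state-space model
#'
#' A continuous-time single-input single-output (SISO) linear model
#' \deqn{\dot x(t) = A x(t) + B u(t), \quad y(t) = C x(t),}
#' with feedthrough fixed at zero (an impulse-response model has no direct
#' term). Matrices may be complex-valued: the principal matrix logarithm used
#' during identification produces complex parameters whenever the discrete
#' transition matrix has eigenvalues on the closed negative real axis, and
#' such models are retained rather than rejected.
#'
#' @param A square state matrix (`nx` x `nx`), real or complex.
#' @param B input vector (`nx` x 1 matrix or length-`nx` vector).
#' @param C output vector (1 x `nx` matrix or length-`nx` vector).
#' @param dt sampling interval in seconds associated with the model at
#'   identification time, or `NULL` for analytically constructed models.
#' @return An object of class `state_space` with elements `A`, `B`, `C`,
#'   `D` (always 0), `order` and `dt`.
#' @examples
#' m <- state_space(A = -3, B = 2, C = 1)
#' impulse_response(m, n_samples = 5, dt = 0.1)
#' @export
state_space <- function(A, B, C, dt = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square", call. = FALSE)
  nx <- nrow(A)
  B <- matrix(B, ncol = 1L)
  C <- matrix(C, nrow = 1L)
  if (nrow(B) != nx || ncol(C) != nx)
    stop("B must be ", nx, "x1 and C 1x", nx, " to match order ", nx, call. = FALSE)
  if (!is.null(dt) && (!is.numeric(dt) || length(dt) != 1L || dt <= 0))
    stop("dt must be a single positive number", call. = FALSE)
  structure(list(A = A, B = B, C = C, D = 0, order = nx, dt = dt),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> order %d%s%s\n", x$order,
              if (is.complex(x$A) || is.complex(x$B) || is.complex(x$C)) ", complex-valued" else "",
              if (!is.null(x$dt)) sprintf(", dt = %g s", x$dt) else ""))
  invisible(x)
}

#' Construct a transfer function
#'
#' Rational Laplace-domain representation
#' \deqn{H(s) = \frac{\beta_{nx} s^{nx-1} + \cdots + \beta_2 s + \beta_1}
#'               {s^{nx} + \alpha_{nx} s^{nx-1} + \cdots + \alpha_2 s + \alpha_1}}
#' with a monic denominator whose leading coefficient (1) is implicit, so the
#' model is described by exactly `2 * order` parameters -- the parsimony that
#' makes these coefficients usable as classifier features.
#'
#' @param numerator coefficients of degrees `order-1` down to 0 (possibly
#'   complex).
#' @param denominator coefficients of degrees `order-1` down to 0 below the
#'   implicit leading `s^order` term.
#' @return An object of class `transfer_function`.
#' @examples
#' transfer_function(numerator = c(0, 1), denominator = c(3, 2))  # 1/(s^2+3s+2)
#' @export
transfer_function <- function(numerator, denominator) {
  if (length(numerator) != length(denominator))
    stop("numerator and denominator must have the same length (the model order)",
         call. = FALSE)
  if (length(denominator) < 1L) stop("order must be at least 1", call. = FALSE)
  structure(list(order = length(denominator),
                 numerator = maybe_real(numerator),
                 denominator = maybe_real(denominator)),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function> order %d (%s coefficients)\n", x$order,
              if (is.complex(x$numerator) || is.complex(x$denominator)) "complex" else "real"))
  invisible(x)
}

#' Impulse-response signals
#'
#' `impulse_response()` is a generic. Applied to a numeric vector it wraps
#' measured samples into an `impulse_response` object; applied to a
#' [state_space()] model it simulates the model's impulse response
#' \eqn{g(t) = C e^{At} B} at `n_samples` points spaced `dt` seconds apart
#' (starting at t = 0, so `g(0) = C B`).
#'
#' For a realized model of a real signal the simulated response may carry a
#' tiny imaginary residue from complex arithmetic; it is discarded after
#' checking that it is numerically negligible (below `1e-6` of the real
#' magnitude), and a warning is raised otherwise. A model whose response
#' overflows raises an error naming the first offending sample.
#'
#' @param x numeric vector of samples, or a `state_space` model.
#' @param ... passed between methods.
#' @return An object of class `impulse_response` with elements `samples`,
#'   `dt` and `n_samples`.
#' @examples
#' impulse_response(c(1, 0.5, 0.25), dt = 0.01)
#' impulse_response(state_space(-1, 1, 1), n_samples = 3, dt = 0.5)
#' @export
impulse_response <- function(x, ...) UseMethod("impulse_response")

#' @rdname impulse_response
#' @param dt sampling interval in seconds (must be positive).
#' @export
impulse_response.default <- function(x, dt, ...) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("impulse-response samples must all be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  structure(list(samples = x, dt = dt, n_samples = length(x)),
            class = "impulse_response")
}

#' @rdname impulse_response
#' @param n_samples number of samples to simulate.
#' @export
impulse_response.state_space <- function(x, n_samples, dt = x$dt, ...) {
  if (is.null(dt)) stop("dt must be supplied for a model without one", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  if (n_samples < 1L) stop("n_samples must be at least 1", call. = FALSE)
  g <- sim_modes(x$A, x$B, x$C, n_samples, dt)
  if (is.null(g)) {
    # defective state matrix: step the discretized system instead
    Ad <- expm_sq(x$A * dt)
    g <- complex(n_samples)
    xi <- x$B + 0i
    Cc <- x$C + 0i
    for (k in seq_len(n_samples)) {
      g[k] <- (Cc %*% xi)[1L]
      xi <- Ad %*% xi
    }
  }
  bad <- which(!is.finite(Re(g)) | !is.finite(Im(g)) | Mod(g) > 1e300)
  if (length(bad))
    stop("impulse response overflow at sample ", bad[1L] - 1L,
         " (unstable model)", call. = FALSE)
  mx <- max(Mod(g))
  if (mx > 0 && max(abs(Im(g))) > 1e-6 * mx)
    warning("imaginary residue of simulated impulse response exceeds 1e-6 of its magnitude; ",
            "the model may not represent a real signal")
  impulse_response(Re(g), dt = dt)
}

# eigen-mode impulse-response evaluation g(k dt) = C e^{A k dt} B; returns
# NULL when A is too close to defective for a reliable eigenbasis
sim_modes <- function(A, B, C, n_samples, dt) {
  e <- eigen(A)
  lam <- as.complex(e$values)
  V <- e$vectors
  Vi <- tryCatch(solve(V), error = function(err) NULL)
  if (is.null(Vi)) return(NULL)
  mA <- max(Mod(A))
  if (mA > 0 && max(Mod(V %*% (lam * Vi) - A)) > 1e-8 * mA) return(NULL)
  wz <- as.vector((C + 0i) %*% V) * as.vector(Vi %*% (B + 0i))
  lt <- outer((0:(n_samples - 1L)) * dt, lam)
  # clamp growth so overflow shows up as huge-but-finite values (caught by
  # the caller's overflow check) instead of NaN from Inf * 0
  lt <- matrix(complex(real = pmin(Re(lt), 709), imaginary = Im(lt)),
               nrow = nrow(lt))
  as.vector(exp(lt) %*% wz)
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf("<impulse_response> %d samples at dt = %g s (%.0f Hz)\n",
              x$n_samples, x$dt, 1 / x$dt))
  invisible(x)
}

#' Mean squared fitting error between two impulse responses
#'
#' \deqn{f = \frac{1}{N}\sum_{t=0}^{N-1} (g(t) - g_{fit}(t))^2}
#' in squared microvolts; zero if and only if the signals are identical.
#'
#' @param g,g_fit [impulse_response()] objects of equal length and sampling
#'   interval.
#' @return A single non-negative number.
#' @examples
#' a <- impulse_response(c(1, 2), dt = 0.002)
#' b <- impulse_response(c(0, 0), dt = 0.002)
#' fitting_error(a, b)  # (1 + 4) / 2 = 2.5
#' @export
fitting_error <- function(g, g_fit) {
  stopifnot(inherits(g, "impulse_response"), inherits(g_fit, "impulse_response"))
  if (g$n_samples != g_fit$n_samples)
    stop("signals have different lengths (", g$n_samples, " vs ", g_fit$n_samples, ")",
         call. = FALSE)
  if (!isTRUE(all.equal(g$dt, g_fit$dt)))
    stop("signals have different sampling intervals", call. = FALSE)
  mean((g$samples - g_fit$samples)^2)
}

#' Markov parameters of a state-space model
#'
#' The sequence `h(0) = D = 0`, `h(i) = C A^(i-1) B` for `i >= 1`: the
#' coefficients of the transfer function's series expansion in powers of
#' `1/s`.
#'
#' @param m a [state_space()] model.
#' @param count total number of parameters to return.
#' @return Vector `(h(0), ..., h(count-1))` of length `count`.
#' @examples
#' markov_parameters(state_space(-3, 2, 1), count = 3)  # 0, 2, -6
#' @export
markov_parameters <- function(m, count) {
  stopifnot(inherits(m, "state_space"), count >= 1L)
  h <- vector(if (is.complex(m$A) || is.complex(m$B) || is.complex(m$C)) "complex" else "numeric",
              count)
  v <- m$B
  for (i in seq_len(count - 1L)) {
    h[i + 1L] <- (m$C %*% v)[1L]
    v <- m$A %*% v
  }
  h
}
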