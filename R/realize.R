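#' Realize a continuous-time state-space model from Hankel factors
#'
#' Kung's realization algorithm. From the rank-`nx` observability factor
#' `Oc` the shifted pair `Oc1` (first `i - 1` rows) and `Oc2` (last `i - 1`
#' rows) satisfies `Oc1 %*% expm(A dt) = Oc2`, so
#' \deqn{A = \frac{\log_e\!\big(O_{c1}^{\dagger} O_{c2}\big)}{\Delta T},
#'  \qquad B = C_c[, 1], \qquad C = O_c[1, ],}
#' with the pseudoinverse computed by SVD-based least squares (relative
#' cutoff `1e-12`) and the principal matrix logarithm. When the discrete
#' transition matrix has eigenvalues on the closed negative real axis the
#' logarithm -- and hence the model -- is complex-valued; such models are
#' retained, which is precisely why downstream features are split into real
#' and imaginary parts.
#'
#' @param h a `hankel_factorization` factored by [factor_hankel()] at the
#'   desired order; its row count must be at least `order + 1`.
#' @param dt sampling interval in seconds (defaults to the one recorded from
#'   the source signal).
#' @return A [state_space()] model of the factored order.
#' @examples
#' g <- impulse_response(2 * exp(-3 * (0:99) * 0.01), dt = 0.01)
#' m <- realize(factor_hankel(build_hankel(g), nx = 1))
#' m$A  # ~ -3
#' @export
realize <- function(h, dt = h$dt) {
  stopifnot(inherits(h, "hankel_factorization"))
  if (is.null(h$Oc)) stop("Hankel matrix has not been factored; call factor_hankel() first",
                          call. = FALSE)
  if (is.null(dt) || !is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  nx <- h$order
  if (h$i < nx + 1L)
    stop("need at least order + 1 = ", nx + 1L, " block rows for the shifted ",
         "observability matrices; Hankel has i = ", h$i, call. = FALSE)
  Oc1 <- h$Oc[-h$i, , drop = FALSE]
  Oc2 <- h$Oc[-1L, , drop = FALSE]
  Ad <- pinv_solve(Oc1, Oc2, rcond = 1e-12)
  A <- maybe_real(logm_eig(Ad) / dt)
  state_space(A = A, B = h$Cctrb[, 1L], C = h$Oc[1L, ], dt = dt)
}

#' Convert a state-space model to transfer-function form
#'
#' \deqn{H(s) = C (sI - A)^{-1} B}
#' computed through the determinant identity: the denominator is the
#' characteristic polynomial of `A` (monic; the leading 1 is implicit in the
#' stored coefficients) and the numerator is
#' `det(sI - A + B C) - det(sI - A)`, of degree at most `nx - 1`. Both
#' characteristic polynomials are expanded from eigenvalues
#' (root-to-coefficient products), which stays well conditioned at the
#' orders (~20) this pipeline fits. Complex `A` yields complex coefficients.
#'
#' @param m a [state_space()] model (feedthrough is zero by construction).
#' @return A [transfer_function()] of the same order.
#' @examples
#' m <- state_space(A = rbind(c(0, 1), c(-2, -3)), B = c(0, 1), C = c(1, 0))
#' ss2tf(m)  # 1 / (s^2 + 3 s + 2)
#' @export
ss2tf <- function(m) {
  stopifnot(inherits(m, "state_space"))
  den_full <- poly_from_roots(eigen(m$A, only.values = TRUE)$values)
  num_full <- poly_from_roots(eigen(m$A - m$B %*% m$C, only.values = TRUE)$values)
  num <- (num_full - den_full)[-1L]
  transfer_function(numerator = num, denominator = den_full[-1L])
}

#' Evaluate a transfer function at complex points
#'
#' @param tf a [transfer_function()].
#' @param s numeric or complex vector of evaluation points (not poles).
#' @return Complex vector `H(s)`.
#' @export
tf_eval <- function(tf, s) {
  stopifnot(inherits(tf, "transfer_function"))
  s <- as.complex(s)
  num <- as.complex(c(0, tf$numerator))   # implicit zero s^nx term
  den <- as.complex(c(1, tf$denominator)) # implicit monic lead
  vapply(s, function(si) {
    p <- 1 + 0i; nv <- 0 + 0i; dv <- 0 + 0i
    for (k in rev(seq_along(den))) {
      nv <- nv + num[k] * p
      dv <- dv + den[k] * p
      p <- p * si
    }
    nv / dv
  }, complex(1))
}

#' Observable canonical realization of a transfer function
#'
#' Builds the observable canonical form: `A` carries the negated denominator
#' coefficients in its last column over a subdiagonal identity, `B` holds the
#' numerator coefficients from the constant term up, and `C = (0, ..., 0, 1)`.
#' `ss2tf()` of the result reproduces the input coefficients.
#'
#' @param tf a [transfer_function()].
#' @return A [state_space()] model of the same order.
#' @examples
#' to_observable_canonical(transfer_function(c(0, 1), c(3, 2)))
#' @export
to_observable_canonical <- function(tf) {
  stopifnot(inherits(tf, "transfer_function"))
  n <- tf$order
  alpha <- rev(tf$denominator)   # alpha_1 (constant term) first
  beta <- rev(tf$numerator)
  zero <- if (is.complex(alpha) || is.complex(beta)) 0i else 0
  A <- matrix(zero, n, n)
  A[, n] <- -alpha
  if (n > 1L) A[cbind(2:n, 1:(n - 1L))] <- 1 + zero
  Cc <- rep(zero, n)
  Cc[n] <- 1 + zero
  state_space(A = A, B = beta, C = Cc)
}

#' MSE-driven model-order search
#'
#' Fits state-space models of increasing order to an impulse response and
#' selects the order by fitting error. A single near-square Hankel matrix is
#' built and decomposed once; for each candidate order starting at `n_min`
#' the truncated factors are realized, the model's impulse response is
#' simulated, and the mean squared error against the data is recorded. The
#' order is incremented while each step improves the MSE by more than
#' `improve_tol` (relative, against the best MSE so far), stopping once
#' `patience` consecutive orders fail to improve or at `n_cap`. A candidate
#' whose realization or simulation fails (e.g. an unstable noise mode
#' overflowing) is recorded with infinite MSE and ends the search; the best
#' valid model seen is returned.
#'
#' The default patience of 2 exists because stable oscillatory systems
#' carry poles in conjugate pairs: an odd-order candidate between two
#' even-order fits often shows no gain, and stopping at that first plateau
#' would systematically underfit by one pair.
#'
#' The defaults (`n_min = 17`, `n_cap = 26`) reflect the singular-value
#' cut-offs observed for averaged ERP waveforms, where spectra flatten into
#' a noise floor past order ~22; for signals of unknown order start the
#' search at `n_min = 1` and let the error floor locate the order.
#'
#' @param g an [impulse_response()] signal.
#' @param n_min first order to try.
#' @param n_cap largest order to try.
#' @param improve_tol minimum relative MSE decrease to count as an
#'   improvement. The default `NULL` uses `max(1e-3, 4 / N)`: raising the
#'   order by one adds two free parameters, which absorb roughly `2 / N` of
#'   the residual even from pure noise, so a real improvement must clear
#'   about twice that fraction or the search would creep up the order
#'   ladder fitting noise.
#' @param patience consecutive non-improving orders tolerated before the
#'   search stops.
#' @param i,j optional Hankel dimensions (default near-square on all
#'   samples).
#' @return An object of class `order_fit` with elements `model`, `tf`,
#'   `chosen_order`, `mse` and `order_trace` (a data frame of each order
#'   evaluated, in increasing order, with its MSE).
#' @examples
#' g <- impulse_response(exp(-(0:80) * 0.05) * sin(2 * (0:80) * 0.05), dt = 0.05)
#' fit <- fit_optimal_order(g, n_min = 1, n_cap = 6)
#' fit$chosen_order
#' @export
fit_optimal_order <- function(g, n_min = 17L, n_cap = 26L, improve_tol = NULL,
                              patience = 2L, i = NULL, j = NULL) {
  stopifnot(inherits(g, "impulse_response"))
  if (is.null(improve_tol)) improve_tol <- max(1e-3, 4 / g$n_samples)
  if (n_min < 1L || n_cap < n_min)
    stop("need 1 <= n_min <= n_cap", call. = FALSE)
  h <- build_hankel(g, i = i, j = j)
  max_order <- min(h$i - 1L, h$j)
  if (n_min > max_order)
    stop("Hankel matrix (", h$i, " x ", h$j, ") too small for minimum order ",
         n_min, "; at most order ", max_order, " is realizable", call. = FALSE)
  n_cap <- min(n_cap, max_order)
  sv <- svd(h$G, nu = min(h$i, n_cap), nv = min(h$j, n_cap))
  estimate_order(sv$d)  # rejects degenerate all-zero signals
  orders <- integer(0)
  mses <- numeric(0)
  models <- list()
  best_mse <- Inf
  stalled <- 0L
  for (n in n_min:n_cap) {
    res <- tryCatch(eval_order(h, sv, n, g), error = function(e) list(model = NULL, mse = Inf))
    orders <- c(orders, n)
    mses <- c(mses, res$mse)
    models[[length(orders)]] <- res$model
    if (!is.finite(res$mse)) break
    if (is.finite(best_mse) && (best_mse - res$mse) <= improve_tol * best_mse) {
      stalled <- stalled + 1L
      if (stalled >= patience) break
    } else {
      stalled <- 0L
      best_mse <- res$mse
    }
  }
  best <- which.min(mses)
  if (!is.finite(mses[best]))
    stop("no candidate order produced a valid realization", call. = FALSE)
  model <- models[[best]]
  structure(list(model = model, tf = ss2tf(model),
                 chosen_order = orders[best], mse = mses[best],
                 order_trace = data.frame(order = orders, mse = mses)),
            class = "order_fit")
}

# realize one candidate order from a shared truncated SVD and score its fit.
# Mathematically identical to realize() + impulse_response(), but the
# eigendecomposition of the discrete transition matrix is computed once and
# reused for the matrix logarithm and the mode-sum simulation.
eval_order <- function(h, sv, n, g) {
  hf <- fill_factors(h, sv, n)
  Oc1 <- hf$Oc[-h$i, , drop = FALSE]
  Oc2 <- hf$Oc[-1L, , drop = FALSE]
  Ad <- pinv_solve(Oc1, Oc2, rcond = 1e-12)
  e <- eigen(Ad)
  lam <- as.complex(e$values)
  if (any(Mod(lam) < 1e-14 * max(Mod(lam))))
    stop("singular discrete transition matrix", call. = FALSE)
  V <- e$vectors
  Vi <- solve(V)
  if (max(Mod(V %*% (lam * Vi) - Ad)) > 1e-6 * max(Mod(Ad)))
    stop("near-defective transition matrix", call. = FALSE)
  lam_c <- log(lam) / g$dt
  A <- maybe_real(V %*% (lam_c * Vi))
  B <- hf$Cctrb[, 1L]
  C <- hf$Oc[1L, ]
  wz <- as.vector((C + 0i) %*% V) * as.vector(Vi %*% (B + 0i))
  gfit <- Re(exp(outer((0:(g$n_samples - 1L)) * g$dt, lam_c)) %*% wz)
  if (!all(is.finite(gfit))) stop("unstable candidate model", call. = FALSE)
  list(model = state_space(A = A, B = B, C = C, dt = g$dt),
       mse = mean((g$samples - gfit)^2))
}

#' @export
print.order_fit <- function(x, ...) {
  cat(sprintf("<order_fit> chosen order %d, mse %.4g over %d orders tried\n",
              x$chosen_order, x$mse, nrow(x$order_trace)))
  invisible(x)
}
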