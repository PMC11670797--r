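#' Build a Hankel matrix from impulse-response samples
#'
#' Arranges the samples `g(0), ..., g(N-1)` into the block-Hankel matrix
#' `G[r, c] = g(r + c)` (0-based), the object whose rank equals the minimal
#' order of the underlying linear system and whose SVD factorization drives
#' the realization algorithm.
#'
#' By default the matrix is made as close to square as the sample count
#' allows (`i = ceiling((N + 1) / 2)`, `j = N - i + 1`), which uses every
#' sample and maximizes the usable rank.
#'
#' @param g an [impulse_response()] signal with `N` samples.
#' @param i,j row and column counts; `i + j - 1` must not exceed `N`.
#' @return An object of class `hankel_factorization` holding `G`, `i`, `j`
#'   and the sampling interval; the SVD slots are filled by
#'   [factor_hankel()].
#' @examples
#' g <- impulse_response(c(1, 2, 3, 4, 5), dt = 0.1)
#' build_hankel(g, i = 2, j = 4)$G
#' @export
build_hankel <- function(g, i = NULL, j = NULL) {
  stopifnot(inherits(g, "impulse_response"))
  N <- g$n_samples
  if (is.null(i)) i <- as.integer(ceiling((N + 1) / 2))
  if (is.null(j)) j <- N - i + 1L
  if (i < 1L || j < 1L) stop("i and j must be at least 1", call. = FALSE)
  if (i + j - 1L > N)
    stop("Hankel dimensions too large: i + j - 1 = ", i + j - 1L,
         " exceeds the ", N, " available samples (maximum usable i + j is ",
         N + 1L, ")", call. = FALSE)
  G <- matrix(g$samples[outer(seq_len(i), seq_len(j), `+`) - 1L], nrow = i, ncol = j)
  structure(list(G = G, i = i, j = j, dt = g$dt,
                 singular_values = NULL, U1 = NULL, S1 = NULL, V1 = NULL,
                 Oc = NULL, Cctrb = NULL, order = NULL),
            class = "hankel_factorization")
}

#' @export
print.hankel_factorization <- function(x, ...) {
  cat(sprintf("<hankel_factorization> %d x %d%s\n", x$i, x$j,
              if (is.null(x$order)) " (unfactored)"
              else sprintf(", factored at order %d", x$order)))
  invisible(x)
}

#' Factor a Hankel matrix by truncated SVD
#'
#' Computes the full singular value decomposition `G = U S V'` and the
#' rank-`nx` observability and controllability factors
#' \deqn{O_c = U_1 S_1^{1/2}, \qquad C_c = S_1^{1/2} V_1',}
#' whose product is the best rank-`nx` approximation of `G`.
#'
#' @param h a `hankel_factorization` from [build_hankel()].
#' @param nx truncation order, at most `min(i, j)`.
#' @return `h` with `singular_values` (all `min(i, j)` of them), `U1`, `S1`,
#'   `V1`, `Oc`, `Cctrb` and `order` filled in.
#' @export
factor_hankel <- function(h, nx) {
  stopifnot(inherits(h, "hankel_factorization"))
  m <- min(h$i, h$j)
  if (nx < 1L || nx > m)
    stop("order nx = ", nx, " must lie in 1..min(i, j) = ", m, call. = FALSE)
  sv <- svd(h$G)
  fill_factors(h, sv, nx)
}

# fill the truncated factors from a precomputed SVD (shared by the order
# search, which factors the same Hankel matrix at several orders)
fill_factors <- function(h, sv, nx) {
  idx <- seq_len(nx)
  sqs <- sqrt(sv$d[idx])
  h$singular_values <- sv$d
  h$U1 <- sv$u[, idx, drop = FALSE]
  h$S1 <- sv$d[idx]
  h$V1 <- sv$v[, idx, drop = FALSE]
  h$Oc <- sweep(h$U1, 2L, sqs, `*`)
  h$Cctrb <- sqs * t(h$V1)
  h$order <- nx
  h
}

#' Estimate model order from a singular-value spectrum
#'
#' Counts the singular values exceeding `rel_tol` relative to the largest
#' one. On noiseless data this equals the rank of the Hankel matrix and
#' hence the minimal system order; on noisy data the spectrum decays
#' gradually and the count marks the cut-off above the noise floor.
#'
#' @param singular_values non-increasing, non-negative values.
#' @param rel_tol relative threshold (default `1e-6`, suited to noiseless
#'   signals; the MSE-driven search in [fit_optimal_order()] governs noisy
#'   data).
#' @return Estimated order, between 1 and `length(singular_values)`.
#' @examples
#' estimate_order(c(10, 5, 1e-9, 1e-11), rel_tol = 1e-6)  # 2
#' @export
estimate_order <- function(singular_values, rel_tol = 1e-6) {
  if (length(singular_values) == 0L || all(singular_values <= 0))
    stop("degenerate signal: all singular values are zero, the model order is undefined",
         call. = FALSE)
  sum(singular_values / singular_values[1L] > rel_tol)
}
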