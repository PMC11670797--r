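# Internal linear-algebra helpers for the realization machinery.
# All routines accept complex matrices; base R and the installed matrix
# packages provide expm/logm for real input only, and the principal matrix
# logarithm of a matrix with negative-real eigenvalues -- the step that makes
# identified models complex-valued -- needs complex arithmetic throughout.

#' Matrix exponential by scaling and squaring
#'
#' Truncated Taylor series on the scaled matrix, then repeated squaring.
#' Accurate to machine precision for the small (nx <= ~30) matrices the
#' realization step produces.
#' @noRd
expm_sq <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(matrix(exp(A[1L, 1L]), 1L, 1L))
  nrm <- max(rowSums(Mod(A)))
  s <- if (nrm > 0.5) ceiling(log2(nrm)) + 1L else 0L
  As <- A / 2^s
  E <- term <- diag(1 + 0i, n)
  for (k in 1:40) {
    term <- term %*% As / k
    E <- E + term
    if (max(Mod(term)) < .Machine$double.eps * max(Mod(E))) break
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

#' Principal matrix logarithm via eigendecomposition
#'
#' log(M) = V diag(Log lambda) V^-1 with the principal branch of the complex
#' scalar logarithm. Eigenvalues on the closed negative real axis yield a
#' complex logarithm (imaginary part pi); this is expected and kept.
#' Defective (non-diagonalizable) or singular input is rejected.
#' @noRd
logm_eig <- function(M) {
  n <- nrow(M)
  if (n == 1L) {
    lam <- M[1L, 1L]
    if (Mod(lam) < .Machine$double.eps) stop("matrix logarithm of a (near-)singular matrix", call. = FALSE)
    return(matrix(log(as.complex(lam)), 1L, 1L))
  }
  e <- eigen(M)
  lam <- as.complex(e$values)
  if (any(Mod(lam) < 1e-14 * max(Mod(lam))))
    stop("matrix logarithm of a (near-)singular matrix", call. = FALSE)
  V <- e$vectors
  Vi <- tryCatch(solve(V), error = function(err)
    stop("matrix logarithm: defective matrix (eigenvector basis is singular)", call. = FALSE))
  L <- V %*% (log(lam) * Vi)
  # diagonalization residual check: reject near-defective input
  resid <- max(Mod(V %*% (lam * Vi) - M)) / max(Mod(M))
  if (!is.finite(resid) || resid > 1e-6)
    stop("matrix logarithm: matrix is too close to defective for a reliable eigendecomposition",
         call. = FALSE)
  L
}

#' SVD-based least-squares solve pinv(A) %*% B with relative cutoff
#'
#' Singular values below `rcond * s_max` are discarded, mirroring a
#' pseudoinverse with relative tolerance.
#' @noRd
pinv_solve <- function(A, B, rcond = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > rcond * sv$d[1L]
  if (!any(keep)) stop("rank-deficient matrix in least-squares solve", call. = FALSE)
  sv$v[, keep, drop = FALSE] %*% ((crossprod(sv$u[, keep, drop = FALSE], B)) / sv$d[keep])
}

#' Monic polynomial coefficients from roots
#'
#' Returns coefficients of prod(s - r_k), highest degree first (leading 1
#' included), by iterated convolution. Complex-safe.
#' @noRd
poly_from_roots <- function(roots) {
  p <- if (is.complex(roots)) c(1 + 0i) else 1
  for (r in roots) p <- c(p, 0) - c(0, r * p)
  p
}

# drop an all-but-negligible imaginary part, else keep complex
maybe_real <- function(x, tol = 1e-10) {
  if (!is.complex(x)) return(x)
  mx <- max(Mod(x), 0)
  if (mx == 0 || max(abs(Im(x))) <= tol * mx) Re(x) else x
}
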