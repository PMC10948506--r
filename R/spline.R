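#' Spherical-spline scalp basis
#'
#' Shared implementation of the spherical-spline basis (Perrin-style
#' parameterization) used both by bad-channel interpolation and by the
#' surface-Laplacian spatial filter, so the two stay in exact agreement.
#'
#' `g(x)` is the potential basis and `h(x)` the Laplacian basis, evaluated at
#' `x = cos(angle)` between sensor pairs:
#' \deqn{g(x) = \frac{1}{4\pi}\sum_{n=1}^{N} \frac{2n+1}{(n(n+1))^m} P_n(x)}
#' \deqn{h(x) = \frac{-1}{4\pi}\sum_{n=1}^{N} \frac{2n+1}{(n(n+1))^{m-1}} P_n(x)}
#' with Legendre polynomials \eqn{P_n}, spline order `m = 4`, `N = 50` terms
#' and Tikhonov regularization `lambda = 1e-5` on the interpolation system.
#'
#' @name spline-basis
#' @keywords internal
NULL

# Sum of Legendre series c_n * P_n(x) for n = 1..length(cn), elementwise on a
# matrix of cosines, via the three-term recurrence.
.legendre_series <- function(x, cn) {
  p_nm1 <- array(1, dim = dim(x))   # P_0
  p_n <- x                          # P_1
  out <- cn[1] * p_n
  for (n in 2:length(cn)) {
    p_np1 <- ((2 * n - 1) * x * p_n - (n - 1) * p_nm1) / n
    out <- out + cn[n] * p_np1
    p_nm1 <- p_n
    p_n <- p_np1
  }
  out
}

.spline_g <- function(x, m = 4, nterms = 50) {
  n <- seq_len(nterms)
  .legendre_series(x, (2 * n + 1) / (n * (n + 1))^m) / (4 * pi)
}

.spline_h <- function(x, m = 4, nterms = 50) {
  n <- seq_len(nterms)
  -.legendre_series(x, (2 * n + 1) / (n * (n + 1))^(m - 1)) / (4 * pi)
}

# Solve the constrained spline system on the sensors in `pos` (k x 3):
#   [G + lambda*I, 1; 1', 0] [c; c0] = [v; 0]
# Returns the (k+1) x k matrix mapping sensor values v to [c; c0].
.spline_solve_matrix <- function(cosang, lambda = 1e-5, m = 4, nterms = 50) {
  k <- nrow(cosang)
  G <- .spline_g(cosang, m = m, nterms = nterms)
  A <- rbind(cbind(G + diag(lambda, k), rep(1, k)),
             c(rep(1, k), 0))
  solve(A)[, seq_len(k), drop = FALSE]
}

#' Surface-Laplacian transform matrix for a montage
#'
#' Returns the channels x channels linear operator that maps scalp potentials
#' to their spherical-spline surface Laplacian (arbitrary units). A spatially
#' constant potential maps to zero exactly (the spline constant term absorbs
#' it).
#'
#' @param mont a [montage()].
#' @param lambda Tikhonov regularization of the spline system.
#' @param m spline order.
#' @param nterms number of Legendre terms.
#' @return n x n numeric matrix.
#' @export
laplacian_matrix <- function(mont, lambda = 1e-5, m = 4, nterms = 50) {
  stopifnot(inherits(mont, "montage"))
  if (length(mont$labels) < 8)
    stop("surface Laplacian needs >= 8 channels")
  cosang <- .cosangles(mont)
  if (any(cosang[upper.tri(cosang)] > 1 - 1e-10))
    stop("duplicate sensor positions in montage")
  Minv <- .spline_solve_matrix(cosang, lambda = lambda, m = m, nterms = nterms)
  H <- .spline_h(cosang, m = m, nterms = nterms)
  L <- H %*% Minv[seq_len(nrow(cosang)), , drop = FALSE]
  dimnames(L) <- list(mont$labels, mont$labels)
  L
}

# Pseudo-inverse of the Laplacian operator (dropping its near-null constant
# mode): maps focal current-source-density patterns to the smooth scalp
# fields that produce them. Used by the synthetic generator to place sources
# "under" electrodes. Per-mode scalp gain is capped at `gain_cap` so the
# near-singular smooth modes cannot blow up the scalp amplitude; the capped
# modes are reproduced with mild shrinkage instead of dropped.
.laplacian_pinv <- function(L, tol = 1e-8, gain_cap = 1) {
  sv <- svd(L)
  keep <- sv$d > tol * max(sv$d)
  g <- pmin(1 / sv$d[keep], gain_cap)
  sv$v[, keep, drop = FALSE] %*% (t(sv$u[, keep, drop = FALSE]) * g)
}

# Row vector of interpolation weights: value at the bad sensor as a linear
# combination of the good sensors (spherical-spline interpolation).
.interp_weights <- function(mont, bad, good, lambda = 1e-5, m = 4, nterms = 50) {
  pos <- mont$pos
  cos_gg <- tcrossprod(pos[good, , drop = FALSE])
  cos_gg[cos_gg > 1] <- 1; cos_gg[cos_gg < -1] <- -1
  cos_bg <- pos[bad, , drop = FALSE] %*% t(pos[good, , drop = FALSE])
  cos_bg[cos_bg > 1] <- 1; cos_bg[cos_bg < -1] <- -1
  Minv <- .spline_solve_matrix(cos_gg, lambda = lambda, m = m, nterms = nterms)
  g_bg <- .spline_g(cos_bg, m = m, nterms = nterms)
  # v_bad = [g_bg, 1] %*% [c; c0]
  cbind(g_bg, 1) %*% Minv
}
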