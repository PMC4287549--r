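#' Matern correlation function
#'
#' \deqn{\rho(h) = \frac{1}{2^{\nu-1}\Gamma(\nu)} (\kappa h)^\nu K_\nu(\kappa h)}
#' with \eqn{\rho(0) = 1} by continuity, where \eqn{K_\nu} is the modified
#' Bessel function of the second kind.  The smoothness is fixed at
#' \eqn{\nu = 1} throughout the package unless overridden.
#'
#' @param h distance(s), >= 0.
#' @param kappa scale parameter (> 0), inversely related to the practical
#'   range: correlation falls to ~0.14 at `sqrt(8 * nu) / kappa`.
#' @param nu smoothness (> 0), default 1.
#' @return correlation values in (0, 1].
#' @examples
#' matern_correlation(1, kappa = 1)        # 1 * besselK(1, 1) ~= 0.60191
#' matern_correlation(sqrt(8), kappa = 1)  # ~0.14, the practical range
#' @export
matern_correlation <- function(h, kappa, nu = 1) {
  if (any(h < 0)) stop("negative distance h rejected")
  if (kappa <= 0) stop("kappa must be > 0")
  if (nu <= 0) stop("nu must be > 0")
  out <- numeric(length(h))
  pos <- h > 0
  kh <- kappa * h[pos]
  out[pos] <- (1 / (2^(nu - 1) * gamma(nu))) * kh^nu * besselK(kh, nu)
  out[!pos] <- 1
  out
}

#' Practical range of the Matern correlation
#'
#' The distance at which correlation has decayed to approximately 0.14
#' ("almost nil"): `sqrt(8 * nu) / kappa`.
#'
#' @inheritParams matern_correlation
#' @export
matern_practical_range <- function(kappa, nu = 1) sqrt(8 * nu) / kappa

#' Matern covariance matrix on a tract geometry
#'
#' Builds the dense covariance `sigma2_sp * rho(h_ij)` over the pairwise
#' centroid distances and guarantees a Cholesky factorization by escalating
#' a diagonal jitter (x10 per step, at most `max_escalations` steps).
#'
#' @param geometry a `tract_geometry` (or a bare distance matrix).
#' @param sigma2_sp marginal variance of the spatial field.
#' @param kappa,nu Matern parameters.
#' @param jitter initial diagonal jitter.
#' @param max_escalations maximum number of x10 jitter escalations.
#' @return covariance matrix with attributes `jitter` (the jitter actually
#'   used) and `chol` (its upper-triangular Cholesky factor).
#' @export
matern_covariance <- function(geometry, sigma2_sp, kappa, nu = 1,
                              jitter = 1e-10, max_escalations = 6) {
  d <- if (inherits(geometry, "tract_geometry")) geometry$dist else as.matrix(geometry)
  if (sigma2_sp < 0) stop("sigma2_sp must be >= 0")
  C <- sigma2_sp * matern_correlation_matrix(d, kappa, nu)
  j <- jitter
  for (esc in 0:max_escalations) {
    Cj <- C + diag(j, nrow(C))
    ch <- tryCatch(chol(Cj), error = function(e) NULL)
    if (!is.null(ch)) {
      attr(Cj, "jitter") <- j
      attr(Cj, "chol") <- ch
      return(Cj)
    }
    j <- j * 10
  }
  stop(sprintf(
    "Matern covariance not positive definite after %d jitter escalations (last jitter %.1e); check kappa=%.3g and the distance matrix",
    max_escalations, j / 10, kappa
  ))
}

# correlation matrix over a distance matrix (internal, vectorized)
matern_correlation_matrix <- function(d, kappa, nu = 1) {
  R <- matrix(matern_correlation(as.vector(d), kappa, nu), nrow(d), ncol(d))
  dimnames(R) <- dimnames(d)
  R
}
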