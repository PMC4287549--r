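#' RW1 structure matrix
#'
#' Tridiagonal structure matrix R of a first-order random walk:
#' diagonal `(1, 2, ..., 2, 1)`, off-diagonals `-1`, so that the precision
#' is `Q = tau * R`, `R %*% 1 = 0` and `rank(R) = n - 1`.
#'
#' @param n path length (>= 2).
#' @return dense `n x n` matrix.
#' @export
rw1_structure <- function(n) {
  if (n < 2) stop("RW1 path length must be >= 2")
  R <- diag(c(1, rep(2, n - 2), 1))
  idx <- cbind(seq_len(n - 1), 2:n)
  R[idx] <- -1
  R[idx[, 2:1, drop = FALSE]] <- -1
  R
}

#' RW1 log-density
#'
#' Density of a first-order random walk path derived from its `n - 1`
#' independent Gaussian increments:
#' \deqn{\frac{n-1}{2}\log\frac{\tau}{2\pi} - \frac{\tau}{2}\sum_t (x_{t+1}-x_t)^2.}
#' This is the increments convention (`normalization = "increments"`).
#' `normalization = "gmrf"` adds the constant `log(pdet(R))/2 = log(n)/2`,
#' giving the generalized density of the rank-deficient intrinsic GMRF with
#' precision `Q = tau R`; the two differ only by that constant.
#'
#' @param x numeric path, length n >= 2.
#' @param tau precision of the increments (> 0).
#' @param normalization `"increments"` (default) or `"gmrf"`.
#' @return scalar log-density.  Invariant to adding a constant to `x`.
#' @export
rw1_logdensity <- function(x, tau, normalization = c("increments", "gmrf")) {
  normalization <- match.arg(normalization)
  n <- length(x)
  if (n < 2) stop("RW1 path length must be >= 2")
  if (tau <= 0) stop("tau must be > 0")
  qf <- sum(diff(x)^2)
  ld <- ((n - 1) / 2) * log(tau / (2 * pi)) - (tau / 2) * qf
  if (normalization == "gmrf") ld <- ld + 0.5 * log(n)
  ld
}

#' Simulate a (sum-to-zero) RW1 path
#'
#' Cumulative sum of iid Normal(0, 1/tau) increments starting at zero,
#' optionally recentred to sum to zero (the identifiability constraint used
#' throughout the package).
#'
#' @param n path length.
#' @param tau increment precision.
#' @param centered recentre the path to sum to zero (default TRUE).
#' @return numeric path of length `n`.
#' @export
simulate_rw1 <- function(n, tau, centered = TRUE) {
  x <- c(0, cumsum(stats::rnorm(n - 1, 0, 1 / sqrt(tau))))
  if (centered) x <- x - mean(x)
  x
}

#' Block-diagonal precision of the spatio-temporal interaction
#'
#' One RW1 precision block `tau_int * R` (length `n_years`) per tract:
#' independent RW1 paths over time within each tract, a single shared
#' precision (Knorr-Held type-II interaction).  Rank is
#' `n_tracts * (n_years - 1)`.
#'
#' @param n_tracts,n_years dimensions (`n_tracts` >= 1, `n_years` >= 2).
#' @param tau_int shared precision (> 0).
#' @return sparse symmetric matrix (`Matrix::bdiag`), `n_tracts * n_years`
#'   square, ordered tract-major (tract 1 years 1..T, tract 2 years 1..T, ...).
#' @export
build_interaction_precision <- function(n_tracts, n_years, tau_int) {
  if (n_tracts < 1 || n_years < 2) stop("need n_tracts >= 1 and n_years >= 2")
  if (tau_int <= 0) stop("tau_int must be > 0")
  R <- tau_int * rw1_structure(n_years)
  Matrix::bdiag(replicate(n_tracts, R, simplify = FALSE))
}
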