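# Independent oracles used across the suite.  Each deliberately re-derives
# the quantity through a different route than the package implementation.

# Modified Bessel function of the second kind via its integral
# representation K_nu(x) = int_0^inf exp(-x cosh t) cosh(nu t) dt
bessel_k_integral <- function(x, nu) {
  stats::integrate(function(t) exp(-x * cosh(t)) * cosh(nu * t),
                   0, 30, rel.tol = 1e-12)$value
}

matern_rho_oracle <- function(h, kappa, nu = 1) {
  if (h == 0) return(1)
  kh <- kappa * h
  (1 / (2^(nu - 1) * gamma(nu))) * kh^nu * bessel_k_integral(kh, nu)
}

# Step-by-step DP2 oracle: materializes every regression with lm() on data
# frames; population-SD standardization, min base, Frechet start, iterate
# ordering by |cor| until stable.
dp2_oracle <- function(X, orientation = rep(1, ncol(X)), max_iter = 50) {
  X <- sweep(as.matrix(X), 2, orientation, "*")
  n <- nrow(X); p <- ncol(X)
  sds <- apply(X, 2, function(v) sqrt(sum((v - mean(v))^2) / n))
  base <- apply(X, 2, min)
  D <- sweep(sweep(X, 2, base, "-"), 2, sds, "/")
  index <- rowSums(D)
  ord_prev <- NULL
  for (iter in seq_len(max_iter)) {
    r <- sapply(seq_len(p), function(k) stats::cor(X[, k], index))
    ord <- order(abs(r), decreasing = TRUE)
    w <- numeric(p)
    w[ord[1]] <- 1
    for (k in seq_len(p)[-1]) {
      df <- data.frame(y = X[, ord[k]], X[, ord[seq_len(k - 1)], drop = FALSE])
      w[ord[k]] <- 1 - summary(stats::lm(y ~ ., data = df))$r.squared
    }
    index_new <- as.vector(D %*% w)
    if ((!is.null(ord_prev) && identical(ord, ord_prev)) ||
        max(abs(index_new - index)) < 1e-8) {
      return(list(index = index_new, weights = w, order = ord, iterations = iter))
    }
    index <- index_new
    ord_prev <- ord
  }
  stop("oracle did not converge")
}

# plain componentwise random-walk MH for a Poisson GLM with offset:
# independent reference sampler for the fixed-effects-only subcase
reference_poisson_mh <- function(O, offset, X, beta_sd = 10,
                                 n_iter = 20000, scale = 0.1, seed = 1) {
  set.seed(seed)
  p <- ncol(X)
  b <- rep(0, p)
  lpost <- function(b) {
    eta <- offset + as.vector(X %*% b)
    sum(stats::dpois(O, exp(eta), log = TRUE)) +
      sum(stats::dnorm(b, 0, beta_sd, log = TRUE))
  }
  cur <- lpost(b)
  out <- matrix(NA_real_, n_iter, p)
  acc <- numeric(p)
  for (i in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      bp <- b; bp[j] <- b[j] + stats::rnorm(1, 0, scale)
      new <- lpost(bp)
      if (log(stats::runif(1)) < new - cur) {
        b <- bp; cur <- new; acc[j] <- acc[j] + 1
      }
    }
    out[i, ] <- b
  }
  list(draws = out, accept = acc / n_iter)
}

# Monte-Carlo standard error through the package-independent batch-means
mc_se <- function(x, batches = 50) {
  m <- floor(length(x) / batches)
  bm <- colMeans(matrix(x[seq_len(m * batches)], nrow = m))
  stats::sd(bm) / sqrt(batches)
}
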