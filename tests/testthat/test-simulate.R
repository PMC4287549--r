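test_that("field simulation honors degenerate limits", {
  g <- generate_geometry(20, seed = 1)
  tr0 <- bym_truth(sigma_sp = 0)
  f <- simulate_fields(g, 4, tr0, seed = 2)
  expect_equal(f$s, rep(0, 20))
  # infinite-precision limit: the temporal path collapses
  set.seed(3)
  mx <- max(vapply(1:1000, function(i) max(abs(simulate_rw1(8, 1e8))), 0))
  expect_lt(mx, 1e-2)
  # sum-to-zero constraints hold exactly
  f2 <- simulate_fields(g, 6, bym_truth(), seed = 4)
  expect_lt(abs(sum(f2$u)), 1e-10)
  expect_lt(abs(sum(f2$s)), 1e-10)
  expect_lt(abs(sum(f2$tau_t)), 1e-10)
  expect_lt(max(abs(rowSums(f2$eta))), 1e-10)
})

test_that("spatial field is correlated at short range when kappa is small", {
  g <- generate_geometry(40, extent = 50, seed = 5)
  tr <- bym_truth(kappa = 0.08, sigma_sp = 1)  # long range
  Sig <- matern_covariance(g, 1, tr$kappa)
  U <- attr(Sig, "chol")
  set.seed(6)
  reps <- vapply(1:200, function(i) as.vector(crossprod(U, rnorm(40))),
                 numeric(40))
  d <- g$dist[upper.tri(g$dist)]
  co <- cor(t(reps))[upper.tri(g$dist)]
  close5 <- co[d <= quantile(d, 0.05)]
  far5 <- co[d >= quantile(d, 0.95)]
  expect_gt(mean(close5), mean(far5))
  expect_gt(mean(close5), 0.5)
})

test_that("sampled spatial variance matches sigma_sp^2 across replicates", {
  # short range (kappa = 2) so that the sum-to-zero recentring removes a
  # negligible share of the variance
  g <- generate_geometry(40, extent = 50, seed = 7)
  tr <- bym_truth(sigma_sp = 0.3, kappa = 2)
  set.seed(8)
  S <- vapply(1:500, function(i)
    simulate_fields(g, 2, tr, seed = 5000 + i)$s, numeric(40))
  vbar <- mean(apply(S, 1, var))
  expect_lt(abs(vbar - tr$sigma_sp^2) / tr$sigma_sp^2, 0.05)
})

test_that("counts follow the stated emission laws", {
  g <- generate_geometry(100, seed = 9)
  pan <- simulate_covariates(g, 2000:2001, quintile = rep(1, 100),
                             pop_median = 10000, pop_sdlog = 0, seed = 10)
  # all effects zero, beta0 = log(1e-4), Pob = 10000 -> mean count 1
  tr <- bym_truth(beta0 = log(1e-4), sigma_het = 0, sigma_sp = 0,
                  tau_rw = 1e12, tau_int = 1e12,
                  gamma = c(0, 0), beta = rep(0, 4))
  tr <- simulate_fields(g, 2, tr, seed = 11)
  counts <- replicate(50, simulate_counts(pan, tr, "poisson")$O)
  m <- mean(counts)  # 10000 draws in total
  expect_lt(abs(m - 1), 3 * sqrt(1 / length(counts)))

  # zip with p_zero = 1: everything is a structural zero
  tr1 <- tr; tr1$p_zero <- 1
  expect_true(all(simulate_counts(pan, tr1, "zip", seed = 12)$O == 0))

  # zip zero fraction: p0 + (1 - p0) exp(-lambda) at lambda = 2, p0 = 0.3
  pan2 <- pan; pan2$Pob <- 20000  # mu = 2
  tr2 <- tr; tr2$p_zero <- 0.3
  O <- replicate(60, simulate_counts(pan2, tr2, "zip")$O)
  p <- 0.3 + 0.7 * exp(-2)
  expect_lt(abs(mean(O == 0) - p), 3 * sqrt(p * (1 - p) / length(O)))

  # bernoulli emits the at-least-one-case indicator
  Ob <- simulate_counts(pan2, tr, "bernoulli", seed = 13)$O
  expect_true(all(Ob %in% 0:1))
  pb <- -expm1(-2)
  expect_lt(abs(mean(Ob) - pb), 3 * sqrt(pb * (1 - pb) / length(Ob)))
})

test_that("simulated ZIP counts match the analytic pmf in total variation", {
  g <- generate_geometry(500, seed = 14)
  pan <- simulate_covariates(g, 1:100, quintile = rep(1, 500),
                             pop_median = 20000, pop_sdlog = 0, seed = 15)
  tr <- bym_truth(beta0 = log(1e-4), sigma_het = 0, sigma_sp = 0,
                  tau_rw = 1e12, tau_int = 1e12, gamma = c(0, 0),
                  beta = rep(0, 4), p_zero = 0.3)
  tr <- simulate_fields(g, 100, tr, seed = 16)
  O <- simulate_counts(pan, tr, "zip", seed = 17)$O  # 50000 draws at mu = 2
  O <- c(O, simulate_counts(pan, tr, "zip", seed = 18)$O)
  K <- max(O)
  emp <- tabulate(O + 1, K + 1) / length(O)
  tv <- 0.5 * (sum(abs(emp - dzip(0:K, 2, 0.3))) + (1 - sum(dzip(0:K, 2, 0.3))))
  expect_lt(tv, 0.01)
})

test_that("count simulation rejects bad input", {
  g <- generate_geometry(5, seed = 19)
  pan <- simulate_covariates(g, 2000, quintile = rep(1, 5), seed = 20)
  tr <- bym_truth(beta0 = 40)
  tr$u <- rep(0, 5); tr$s <- rep(0, 5); tr$tau_t <- 0
  tr$eta <- matrix(0, 5, 1)
  expect_error(simulate_counts(pan, tr, "poisson"), "overflow|exceeds 30")
  expect_error(simulate_counts(pan, bym_truth(), "negbin"), "arg")
})

test_that("panels are byte-identical under the same seed", {
  a <- default_study_scenario(seed = 5, n_tracts = 40, n_years = 3)
  b <- default_study_scenario(seed = 5, n_tracts = 40, n_years = 3)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth, b$truth)
  c <- default_study_scenario(seed = 6, n_tracts = 40, n_years = 3)
  expect_false(identical(a$panel$O, c$panel$O))
})

test_that("panel and truth files round-trip", {
  sc <- default_study_scenario(seed = 7, n_tracts = 30, n_years = 3)
  validate_panel(sc$panel)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_panel(sc$panel, f1)
  expect_equal(read_panel(f1), sc$panel, tolerance = 1e-10,
               ignore_attr = TRUE)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_truth(sc$truth, f2)
  tr2 <- read_truth(f2)
  expect_equal(tr2$beta, sc$truth$beta)
  expect_equal(tr2$eta, sc$truth$eta, tolerance = 1e-12, ignore_attr = TRUE)
  bad <- sc$panel; bad$quintile[1] <- 9L
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_panel(bad, f3)
  expect_error(read_panel(f3), "quintile")
})
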