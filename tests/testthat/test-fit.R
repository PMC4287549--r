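# the MCMC tests are sized to keep the suite fast; the dedicated acceptance
# tests exercise the sampler at the full study-emulating scale

test_that("fixed-effects-only posterior matches an independent reference sampler", {
  set.seed(101)
  n <- 60
  pan <- data.frame(
    tract_id = seq_len(n), year = 2000,
    Pob = 800, P4564 = 0, P65M = 0,
    quintile = rep(1:5, length.out = n)
  )
  g <- generate_geometry(n, seed = 101)
  tr <- bym_truth(beta0 = -6.2, sigma_het = 0, sigma_sp = 0,
                  tau_rw = 1e12, tau_int = 1e12, gamma = c(0, 0))
  tr <- simulate_fields(g, 2, tr, seed = 102)
  tr$tau_t <- 0  # single year
  tr$eta <- matrix(0, n, 1)
  pan$O <- rpois(n, pan$Pob * exp(tr$beta0 + c(0, tr$beta)[pan$quintile]))

  f <- fit_bym(pan, g,
               spec = model_spec("poisson", age = FALSE, heterogeneity = FALSE,
                                 spatial = FALSE, temporal = FALSE),
               mcmc = mcmc_control(n_iter = 12000, n_burnin = 3000, thin = 1,
                                   chains = 1, seed = 103))
  draws <- f$chains[[1]]$fixed

  X <- cbind(1, outer(pan$quintile, 2:5, "==") * 1)
  ref <- reference_poisson_mh(pan$O, log(pan$Pob), X, n_iter = 25000,
                              scale = 0.25, seed = 104)
  ref_draws <- ref$draws[-(1:5000), ]
  for (j in 1:5) {
    se <- sqrt(mc_se(draws[, j])^2 + mc_se(ref_draws[, j])^2)
    expect_lt(abs(mean(draws[, j]) - mean(ref_draws[, j])), 3 * se)
    # spreads agree too (posterior SDs within 15%)
    expect_lt(abs(sd(draws[, j]) / sd(ref_draws[, j]) - 1), 0.15)
  }
})

test_that("with the likelihood switched off the intercept recovers its prior", {
  sc <- make_small_scenario(n_tracts = 12, n_years = 3, seed = 110)
  f <- fit_bym(sc$panel, sc$geometry,
               spec = model_spec("poisson", quintiles = FALSE, age = FALSE,
                                 heterogeneity = FALSE, spatial = FALSE,
                                 temporal = FALSE),
               mcmc = mcmc_control(n_iter = 30000, n_burnin = 5000, thin = 5,
                                   chains = 1, seed = 111, prior_only = TRUE))
  b0 <- f$chains[[1]]$fixed[, "beta0"]
  se <- mc_se(b0)
  expect_lt(abs(mean(b0) - 0), 3 * pmax(se, 1e-6))
  expect_lt(abs(sd(b0) - 10) / 10, 0.2)
})

test_that("the full model recovers a strong quintile effect", {
  tr <- bym_truth(beta = c(-0.2, -0.5, -0.9, -1.4))
  sc <- make_small_scenario(n_tracts = 40, n_years = 6, seed = 120, truth = tr)
  f <- fit_bym(sc$panel, sc$geometry,
               spec = model_spec("poisson"),
               mcmc = mcmc_control(n_iter = 3000, n_burnin = 1500, thin = 2,
                                   chains = 2, seed = 121))
  s <- summarize_fit(f)
  expect_true(all(s$rr$lower <= s$rr$mean & s$rr$mean <= s$rr$upper))
  expect_true(all(s$rr$mean > 0))
  # Q5 is a big effect: significant and near truth
  expect_true(s$rr["Q5", "significant"])
  expect_true(s$rr["Q5", "lower"] <= exp(-1.4) && exp(-1.4) <= s$rr["Q5", "upper"])
  expect_lt(abs(log(s$rr["Q5", "mean"]) - (-1.4)), 1)
  # chains agree on the fixed effects (weakly identified hyperparameters
  # may legitimately warn at this chain length)
  cr <- suppressWarnings(convergence_report(f))
  expect_true(all(cr$rhat[cr$parameter %in% c("beta0", "Q5")] < 1.2))
})

test_that("zip and bernoulli families fit without degeneracy", {
  tr <- bym_truth(p_zero = 0.4)
  sc <- make_small_scenario(n_tracts = 25, n_years = 4, seed = 130,
                            family = "zip", truth = tr)
  f <- fit_bym(sc$panel, sc$geometry, spec = model_spec("zip"),
               mcmc = mcmc_control(n_iter = 2000, n_burnin = 1000, thin = 2,
                                   chains = 1, seed = 131))
  s <- summarize_fit(f, information_criteria = FALSE)
  expect_true(s$p_zero > 0.05 && s$p_zero < 0.8)

  scb <- make_small_scenario(n_tracts = 25, n_years = 4, seed = 140,
                             family = "bernoulli")
  fb <- fit_bym(scb$panel, scb$geometry, spec = model_spec("bernoulli"),
                mcmc = mcmc_control(n_iter = 1500, n_burnin = 700, thin = 2,
                                    chains = 1, seed = 141))
  sb <- summarize_fit(fb, information_criteria = FALSE)
  expect_true(all(is.finite(as.matrix(sb$rr[1:3]))))
})

test_that("relabeling tracts leaves the summary unchanged up to MC noise", {
  sc <- make_small_scenario(n_tracts = 30, n_years = 4, seed = 150)
  ctrl <- mcmc_control(n_iter = 2500, n_burnin = 1200, thin = 2, chains = 1,
                       seed = 151)
  f1 <- fit_bym(sc$panel, sc$geometry, spec = model_spec("poisson"), mcmc = ctrl)

  # present the same tracts in a different order, under different labels
  set.seed(152)
  perm <- sample(30)
  g2 <- tract_geometry(tract_id = sc$geometry$tract_id[perm] * 100,
                       x = sc$geometry$x[perm], y = sc$geometry$y[perm])
  pan2 <- sc$panel
  pan2$tract_id <- pan2$tract_id * 100
  f2 <- fit_bym(pan2, g2, spec = model_spec("poisson"), mcmc = ctrl)

  s1 <- summarize_fit(f1, information_criteria = FALSE)
  s2 <- summarize_fit(f2, information_criteria = FALSE)
  expect_equal(s2$rr$mean, s1$rr$mean, tolerance = 0.15)
  expect_equal(s2$beta0$mean, s1$beta0$mean, tolerance = 0.15)
})

test_that("fit validates its inputs", {
  sc <- make_small_scenario(n_tracts = 10, n_years = 3, seed = 160)
  pan <- sc$panel
  pan$tract_id[1] <- 999
  expect_error(fit_bym(pan, sc$geometry), "absent from the geometry")
  expect_error(mcmc_control(n_iter = 100, n_burnin = 100), "n_iter")
})
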