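test_that("point-mass posterior gives p_D = 0 and DIC = Dhat", {
  ll <- matrix(rep(c(-1.2, -0.7, -2.0), each = 5), nrow = 5, byrow = FALSE)
  d <- dic_from_loglik(ll, c(-1.2, -0.7, -2.0))
  expect_equal(d$p_d, 0)
  expect_equal(d$dic, d$dhat)
  expect_equal(d$dic, -2 * sum(c(-1.2, -0.7, -2.0)))
})

test_that("two-draw toy matches the hand-computed DIC", {
  # y = (1, 0); draw 1 has mu = (1.0, 0.5), draw 2 mu = (2.0, 1.0);
  # plug-in at the mean mu = (1.5, 0.75)
  y <- c(1, 0)
  mus <- rbind(c(1, 0.5), c(2, 1))
  ll <- t(apply(mus, 1, function(m) dpois(y, m, log = TRUE)))
  llhat <- dpois(y, colMeans(mus), log = TRUE)
  d <- dic_from_loglik(ll, llhat)
  dev1 <- -2 * sum(dpois(y, mus[1, ], log = TRUE))
  dev2 <- -2 * sum(dpois(y, mus[2, ], log = TRUE))
  dbar <- (dev1 + dev2) / 2
  dhat <- -2 * sum(llhat)
  expect_equal(d$mean_deviance, dbar, tolerance = 1e-12)
  expect_equal(d$p_d, dbar - dhat, tolerance = 1e-12)
  expect_equal(d$dic, dhat + 2 * (dbar - dhat), tolerance = 1e-12)
  expect_error(dic_from_loglik(matrix(c(-1, -Inf), 2, 1), -1), "non-finite")
})

test_that("DIC decomposition holds on a real fit to 1e-9", {
  sc <- make_small_scenario(n_tracts = 20, n_years = 3, seed = 201)
  f <- fit_bym(sc$panel, sc$geometry, spec = model_spec("poisson"),
               mcmc = mcmc_control(n_iter = 800, n_burnin = 300, thin = 1,
                                   chains = 1, seed = 202))
  d <- dic(f)
  expect_lt(abs(d$dic - (d$mean_deviance + d$p_d)), 1e-9)
  expect_true(is.finite(d$p_d))
})

test_that("CPO degenerates correctly and cv_ls is order invariant", {
  # point-mass posterior: CPO equals the likelihood at that point
  ll <- matrix(rep(log(c(0.3, 0.8)), each = 4), nrow = 4)
  out <- cpo_from_loglik(ll)
  expect_equal(out$cpo, c(0.3, 0.8), tolerance = 1e-12)
  # all CPO = 1 => cv_ls = 0
  expect_equal(cpo_from_loglik(matrix(0, 3, 5))$cv_ls, 0)
  # order invariance
  set.seed(71)
  L <- matrix(rnorm(200, -1), 10, 20)
  expect_equal(cpo_from_loglik(L[, 20:1])$cv_ls, cpo_from_loglik(L)$cv_ls,
               tolerance = 1e-12)
  # zero likelihood at some draw surfaces as CPO = 0
  L2 <- L; L2[1, 3] <- -Inf
  expect_warning(out2 <- cpo_from_loglik(L2), "CPO = 0")
  expect_equal(out2$cpo[3], 0)
  expect_equal(out2$cv_ls, Inf)
})

test_that("harmonic-mean CPO matches the conjugate leave-one-out oracle", {
  # Beta(1,1) prior, y = (1, 0, 1); posterior Beta(3, 2); exact LOO
  # predictives: 0.5, 0.25, 0.5
  set.seed(72)
  S <- 50000
  th <- rbeta(S, 3, 2)
  y <- c(1, 0, 1)
  ll <- sapply(y, function(yi) if (yi == 1) log(th) else log(1 - th))
  out <- cpo_from_loglik(ll)
  exact <- c(0.5, 0.25, 0.5)
  for (i in 1:3) {
    w <- exp(-ll[, i])
    se_cpo <- (sd(w) / sqrt(S)) / mean(w)^2  # delta method
    expect_lt(abs(out$cpo[i] - exact[i]), 3 * se_cpo)
  }
})

test_that("report renders significance and model preference", {
  s_null <- fake_summary(rr_mean = c(0.9, 1.1, 0.95, 1.05),
                         rr_lower = c(0.7, 0.8, 0.7, 0.8),
                         rr_upper = c(1.2, 1.4, 1.3, 1.3),
                         dic = 1010, cv_ls = 1.1)
  rep1 <- render_report(fit = s_null)
  expect_false(any(grepl("\\*", rep1$fit[1:4])))

  # the reported Q5 interval (0.4771, 0.6969) excludes 1: flagged
  s_sig <- fake_summary(rr_mean = c(0.86, 0.81, 0.73, 0.5768),
                        rr_lower = c(0.70, 0.66, 0.60, 0.4771),
                        rr_upper = c(1.01, 1.00, 0.89, 0.6969),
                        dic = 1000, cv_ls = 1.05, interaction = TRUE)
  rep2 <- render_report(m = s_sig)
  expect_true(grepl("\\*", rep2$m[4]))
  expect_false(grepl("\\*", rep2$m[1]))

  cmp <- compare_models(est1 = s_sig, est2 = s_null)
  expect_equal(nrow(cmp), 2)
  expect_equal(cmp$estimation, c("estimation 2", "estimation 1"))
  expect_true(cmp$preferred_dic[1] && cmp$preferred_cvls[1])
  expect_false(cmp$preferred_dic[2] || cmp$preferred_cvls[2])
  both <- render_report(est1 = s_sig, est2 = s_null)
  expect_equal(nrow(attr(both, "comparison")), 2)
})
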