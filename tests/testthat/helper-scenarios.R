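# small end-to-end scenario used by fit/evaluation tests
make_small_scenario <- function(n_tracts = 30, n_years = 5, seed = 1,
                                family = "poisson",
                                truth = bym_truth(), interaction = FALSE) {
  set.seed(seed)
  g <- generate_geometry(n_tracts, extent = 50, seed = seed)
  tr <- simulate_fields(g, n_years, truth, seed = seed + 1)
  if (!interaction) tr$eta <- matrix(0, n_tracts, n_years)
  q <- rep_len(1:5, n_tracts)[sample.int(n_tracts)]
  pan <- simulate_covariates(g, seq(2000, length.out = n_years),
                             quintile = q, seed = seed + 2)
  pan <- simulate_counts(pan, tr, family, seed = seed + 3)
  list(geometry = g, panel = pan, truth = tr)
}

# minimal hand-built bym_fit for summary-math tests
fake_fit <- function(fixed, spec = model_spec(), sigma_het = 0.1,
                     sigma_sp = 0.1) {
  S <- nrow(fixed)
  hyper <- matrix(0, S, 7, dimnames = list(NULL, c(
    "sigma_het", "sigma_sp", "kappa", "tau_rw", "tau_int", "p_zero", "loglik")))
  hyper[, "sigma_het"] <- sigma_het
  hyper[, "sigma_sp"] <- sigma_sp
  path_sd <- matrix(0, S, 2, dimnames = list(NULL, c("sd_temporal", "sd_interaction")))
  structure(
    list(chains = list(list(fixed = fixed, hyper = hyper, path_sd = path_sd,
                            loglik = NULL, latent = NULL)),
         spec = spec, mcmc = mcmc_control(chains = 1),
         tract_ids = 1, years = 1, elapsed = 0),
    class = "bym_fit"
  )
}

fake_summary <- function(rr_mean, rr_lower, rr_upper, dic = NA, cv_ls = NA,
                         interaction = FALSE) {
  structure(
    list(rr = data.frame(mean = rr_mean, lower = rr_lower, upper = rr_upper,
                         significant = rr_lower > 1 | rr_upper < 1,
                         row.names = paste0("Q", seq_along(rr_mean) + 1)),
         log_rr_age = NULL,
         beta0 = data.frame(mean = 0, lower = 0, upper = 0),
         re_sd = c(heterogeneity = NA, spatial = NA, temporal = NA,
                   interaction = NA),
         p_zero = NA, dic = dic, p_d = NA_real_, cv_ls = cv_ls,
         n_draws = 1000, family = "poisson", interaction = interaction),
    class = "bym_summary"
  )
}
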