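#' MCMC settings
#'
#' @param n_iter total iterations per chain.
#' @param n_burnin burn-in iterations discarded (adaptation of proposal
#'   scales runs only during burn-in, then freezes, preserving detailed
#'   balance for the retained draws).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param chains number of independent chains.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param prior_only switch the likelihood off (posterior = prior), used
#'   for prior-recovery checks.
#' @param store_latent keep full draws of the latent fields (else only
#'   their running means, which DIC needs).
#' @param store_loglik keep the per-observation log-likelihood at every
#'   retained draw (needed by [cpo()]; DIC uses it too).
#' @export
mcmc_control <- function(n_iter = 10000, n_burnin = 5000, thin = 2,
                         chains = 3, seed = 1, prior_only = FALSE,
                         store_latent = TRUE, store_loglik = TRUE) {
  stopifnot(n_iter > n_burnin, thin >= 1, chains >= 1)
  list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
       thin = as.integer(thin), chains = as.integer(chains),
       seed = as.integer(seed), prior_only = isTRUE(prior_only),
       store_latent = isTRUE(store_latent), store_loglik = isTRUE(store_loglik))
}

#' Fit the spatio-temporal BYM model by MCMC
#'
#' Metropolis-within-Gibbs sampler for the hierarchical model declared by
#' [model_spec()].  Fixed effects move by adaptive scalar random walks on a
#' covariate-centred parametrization; each latent field moves as a block
#' whose proposal is shaped by its prior (whitened by the Matern Cholesky
#' for the spatial field) and recentred so the sum-to-zero constraints hold
#' exactly at every iteration; the RW1 precisions are Gibbs-updated from
#' their conditional Gamma distributions; the remaining hyperparameters
#' (field SDs, Matern kappa, ZIP mixing weight) move on log / logit scales.
#' Proposal scales adapt toward standard acceptance targets (0.44 scalar,
#' 0.234 blocks) during burn-in only.
#'
#' @param panel tract-year panel with columns `tract_id, year, O, Pob,
#'   P4564, P65M, quintile`.
#' @param geometry a `tract_geometry` covering every tract in the panel.
#' @param spec a [model_spec()].
#' @param mcmc an [mcmc_control()].
#' @return object of class `bym_fit`: `chains` (per-chain draw matrices),
#'   `accept` (acceptance rates), the data and settings, and per-chain
#'   posterior means of the latent fields.
#' @export
fit_bym <- function(panel, geometry, spec = model_spec(),
                    mcmc = mcmc_control()) {
  dat <- .prep_data(panel, geometry, spec)
  chains <- vector("list", mcmc$chains)
  t0 <- proc.time()[["elapsed"]]
  for (c in seq_len(mcmc$chains)) {
    chains[[c]] <- .run_chain(dat, spec, mcmc, seed = mcmc$seed + c - 1L,
                              chain_id = c)
  }
  structure(
    list(chains = chains, panel = dat$panel, geometry = geometry,
         spec = spec, mcmc = mcmc, tract_ids = dat$tract_ids,
         years = dat$years, elapsed = proc.time()[["elapsed"]] - t0),
    class = "bym_fit"
  )
}

#' @export
print.bym_fit <- function(x, ...) {
  ch <- x$chains[[1]]
  cat(sprintf(
    "<bym_fit> family=%s, %d tracts x %d years, %d chain(s) x %d kept draws (%.1fs)\n",
    x$spec$family, length(x$tract_ids), length(x$years),
    length(x$chains), nrow(ch$fixed), x$elapsed
  ))
  invisible(x)
}

# ---- internals -------------------------------------------------------------

.prep_data <- function(panel, geometry, spec) {
  validate_panel(panel)
  if (!all(panel$tract_id %in% geometry$tract_id))
    stop("panel contains tracts absent from the geometry")
  tract_ids <- geometry$tract_id
  years <- sort(unique(panel$year))
  it <- match(panel$tract_id, tract_ids)
  iy <- match(panel$year, years)
  cols <- character(0)
  X <- NULL
  if (spec$quintiles) {
    Q <- matrix(0, nrow(panel), 4, dimnames = list(NULL, paste0("Q", 2:5)))
    for (j in 2:5) Q[panel$quintile == j, j - 1L] <- 1
    X <- Q; cols <- colnames(Q)
  }
  if (spec$age) {
    A <- cbind(P4564 = panel$P4564, P65M = panel$P65M)
    X <- cbind(X, A); cols <- c(cols, colnames(A))
  }
  if (is.null(X)) X <- matrix(0, nrow(panel), 0)
  xm <- if (ncol(X)) colMeans(X) else numeric(0)
  Xc <- if (ncol(X)) sweep(X, 2, xm) else X
  if (spec$family == "bernoulli" && !all(panel$O %in% c(0L, 1L))) {
    # dichotomize: at least one case
    panel$O <- as.integer(panel$O >= 1)
  }
  list(panel = panel, tract_ids = tract_ids, years = years,
       it = it, iy = iy, X = Xc, xm = xm, xnames = cols,
       offset = log(panel$Pob), O = panel$O,
       lgO = lgamma(panel$O + 1), zidx = panel$O == 0,
       n = length(tract_ids), Tn = length(years), N = nrow(panel),
       diam = max(geometry$dist), dist = geometry$dist)
}

.run_chain <- function(dat, spec, ctrl, seed, chain_id = 1L) {
  set.seed(seed)
  n <- dat$n; Tn <- dat$Tn; N <- dat$N
  p <- ncol(dat$X)
  O <- dat$O; lgO <- dat$lgO; zidx <- dat$zidx
  pri <- spec$priors
  kap_meanlog <- pri$kappa_meanlog %||% log(sqrt(8) / (dat$diam / 2))
  prior_only <- ctrl$prior_only

  llrow <- function(lp, p0) {
    if (prior_only) return(numeric(N))
    mu <- exp(lp)
    switch(spec$family,
      poisson = O * lp - mu - lgO,
      zip = {
        t <- log1p(-p0) + O * lp - mu - lgO
        t[zidx] <- log(p0 + (1 - p0) * exp(-mu[zidx]))
        t
      },
      bernoulli = {
        lp1 <- ifelse(mu > 1e-8, log(-expm1(-mu)), log(mu) - mu / 2)
        O * lp1 - (1 - O) * mu
      }
    )
  }
  guard_ok <- function(lp) prior_only || max(abs(lp)) <= 30

  # --- initial state: fixed effects from a Poisson GLM (rough but in the
  # right region for every family; falls back to the crude rate)
  rate0 <- (sum(O) + 0.5) / sum(dat$panel$Pob)
  a0 <- log(rate0)
  th <- rep(0, p)
  if (!prior_only) {
    co <- tryCatch(
      suppressWarnings(
        stats::glm.fit(cbind(1, dat$X), O, offset = dat$offset,
                       family = stats::poisson())$coefficients),
      error = function(e) NULL)
    if (!is.null(co) && all(is.finite(co))) {
      a0 <- co[1]; th <- co[-1]
    }
  }
  a0 <- a0 + stats::rnorm(1, 0, 0.1 * (chain_id > 1))
  th <- th + stats::rnorm(p, 0, 0.05 * (chain_id > 1))
  u <- numeric(n); s <- numeric(n); tt <- numeric(Tn)
  eta <- matrix(0, n, Tn)
  sig_het <- 0.05; sig_sp <- 0.05
  kappa <- exp(kap_meanlog)
  tau_rw <- 1000; tau_int <- 1000
  p0 <- if (spec$family == "zip") 0.1 else 0

  # spatial correlation machinery at current kappa
  upd_spatial <- function(kappa) {
    C <- matern_correlation_matrix(dat$dist, kappa) + diag(1e-10, n)
    U <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    list(U = U, logdetC = 2 * sum(log(diag(U))), log1C1 = log(sum(C)))
  }
  sp <- if (spec$spatial) upd_spatial(kappa) else NULL
  qfC <- function(v, U) sum(backsolve(U, v, transpose = TRUE)^2)

  lp_vec <- dat$offset + a0 + (if (p) as.vector(dat$X %*% th) else 0) +
    u[dat$it] + s[dat$it] + tt[dat$iy] + eta[cbind(dat$it, dat$iy)]
  ll_row <- llrow(lp_vec, p0)
  qf_s <- if (spec$spatial) qfC(s, sp$U) else 0
  qf_tt <- sum(diff(tt)^2)
  qf_eta <- apply(eta, 1, function(r) sum(diff(r)^2))
  sum_u2 <- sum(u^2)

  fx_logprior <- function(a0, th) {
    b0 <- a0 - sum(dat$xm * th)
    stats::dnorm(b0, 0, pri$beta_sd, log = TRUE) +
      sum(stats::dnorm(th, 0, pri$beta_sd, log = TRUE))
  }
  cur_fx_prior <- fx_logprior(a0, th)

  # proposal scales (log), adapted during burn-in
  ls <- c(a0 = log(0.05), stats::setNames(rep(log(0.05), p), sprintf("th%d", seq_len(p))),
          u = log(0.02), s = log(0.3), tt = log(0.03), eta = log(0.01),
          sig_het = log(0.4), sig_sp = log(0.4), kap = log(0.4), p0 = log(0.4))
  targets <- c(0.44, rep(0.44, p), 0.234, 0.234, 0.234, 0.44,
               0.44, 0.44, 0.44, 0.44)
  names(targets) <- names(ls)
  acc_n <- acc_k <- stats::setNames(numeric(length(ls)), names(ls))

  adapt <- function(name, apr, i) {
    if (i <= ctrl$n_burnin) {
      g <- min(0.3, 3 / i^0.6)
      ls[name] <<- ls[name] + g * (apr - targets[name])
    }
    acc_n[name] <<- acc_n[name] + 1
    acc_k[name] <<- acc_k[name] + apr
  }
  mh_logr <- function(logr, comp) {
    if (is.na(logr))
      stop("non-finite log-posterior while updating component: ", comp)
    logr
  }

  # --- storage
  n_kept <- (ctrl$n_iter - ctrl$n_burnin) %/% ctrl$thin
  fixed <- matrix(NA_real_, n_kept, 1 + p,
                  dimnames = list(NULL, c("beta0", dat$xnames)))
  hyper <- matrix(NA_real_, n_kept, 7,
                  dimnames = list(NULL, c("sigma_het", "sigma_sp", "kappa",
                                          "tau_rw", "tau_int", "p_zero",
                                          "loglik")))
  path_sd <- matrix(NA_real_, n_kept, 2,
                    dimnames = list(NULL, c("sd_temporal", "sd_interaction")))
  LL <- if (ctrl$store_loglik) matrix(NA_real_, n_kept, N) else NULL
  lat <- if (ctrl$store_latent)
    list(u = matrix(NA_real_, n_kept, n), s = matrix(NA_real_, n_kept, n),
         tt = matrix(NA_real_, n_kept, Tn),
         eta = matrix(NA_real_, n_kept, n * Tn)) else NULL
  m_u <- numeric(n); m_s <- numeric(n); m_tt <- numeric(Tn)
  m_eta <- matrix(0, n, Tn)
  k <- 0L

  for (i in seq_len(ctrl$n_iter)) {
    ## -- intercept (centred parametrization)
    d <- stats::rnorm(1, 0, exp(ls["a0"]))
    lp_new <- lp_vec + d
    if (guard_ok(lp_new)) {
      ll_new <- llrow(lp_new, p0)
      pr_new <- fx_logprior(a0 + d, th)
      logr <- mh_logr(sum(ll_new) - sum(ll_row) + pr_new - cur_fx_prior, "beta0")
      apr <- min(1, exp(logr))
      if (stats::runif(1) < apr) {
        a0 <- a0 + d; lp_vec <- lp_new; ll_row <- ll_new; cur_fx_prior <- pr_new
      }
    } else apr <- 0
    adapt("a0", apr, i)

    ## -- fixed effects, scalar updates
    for (j in seq_len(p)) {
      nm <- paste0("th", j)
      d <- stats::rnorm(1, 0, exp(ls[nm]))
      lp_new <- lp_vec + d * dat$X[, j]
      if (guard_ok(lp_new)) {
        th_new <- th; th_new[j] <- th[j] + d
        ll_new <- llrow(lp_new, p0)
        pr_new <- fx_logprior(a0, th_new)
        logr <- mh_logr(sum(ll_new) - sum(ll_row) + pr_new - cur_fx_prior,
                        dat$xnames[j])
        apr <- min(1, exp(logr))
        if (stats::runif(1) < apr) {
          th <- th_new; lp_vec <- lp_new; ll_row <- ll_new; cur_fx_prior <- pr_new
        }
      } else apr <- 0
      adapt(nm, apr, i)
    }

    ## -- heterogeneity field (joint, centred => sum-to-zero preserved)
    if (spec$heterogeneity) {
      z <- stats::rnorm(n); z <- z - mean(z)
      du <- exp(ls["u"]) * sig_het * z
      u_new <- u + du
      lp_new <- lp_vec + du[dat$it]
      if (guard_ok(lp_new)) {
        ll_new <- llrow(lp_new, p0)
        sum_u2_new <- sum(u_new^2)
        logr <- mh_logr(sum(ll_new) - sum(ll_row) -
                          (sum_u2_new - sum_u2) / (2 * sig_het^2), "u")
        apr <- min(1, exp(logr))
        if (stats::runif(1) < apr) {
          u <- u_new; sum_u2 <- sum_u2_new; lp_vec <- lp_new; ll_row <- ll_new
        }
      } else apr <- 0
      adapt("u", apr, i)
    }

    ## -- spatial field (prior-whitened block, centred)
    if (spec$spatial) {
      z <- as.vector(crossprod(sp$U, stats::rnorm(n)))
      z <- z - mean(z)
      ds <- exp(ls["s"]) * sig_sp * z
      s_new <- s + ds
      lp_new <- lp_vec + ds[dat$it]
      if (guard_ok(lp_new)) {
        ll_new <- llrow(lp_new, p0)
        qf_new <- qfC(s_new, sp$U)
        logr <- mh_logr(sum(ll_new) - sum(ll_row) -
                          (qf_new - qf_s) / (2 * sig_sp^2), "s")
        apr <- min(1, exp(logr))
        if (stats::runif(1) < apr) {
          s <- s_new; qf_s <- qf_new; lp_vec <- lp_new; ll_row <- ll_new
        }
      } else apr <- 0
      adapt("s", apr, i)
    }

    ## -- temporal RW1 (joint, centred)
    if (spec$temporal) {
      z <- stats::rnorm(Tn); z <- z - mean(z)
      dtt <- exp(ls["tt"]) * z
      tt_new <- tt + dtt
      lp_new <- lp_vec + dtt[dat$iy]
      if (guard_ok(lp_new)) {
        ll_new <- llrow(lp_new, p0)
        qf_new <- sum(diff(tt_new)^2)
        logr <- mh_logr(sum(ll_new) - sum(ll_row) -
                          (tau_rw / 2) * (qf_new - qf_tt), "tau_t")
        apr <- min(1, exp(logr))
        if (stats::runif(1) < apr) {
          tt <- tt_new; qf_tt <- qf_new; lp_vec <- lp_new; ll_row <- ll_new
        }
      } else apr <- 0
      adapt("tt", apr, i)

      ## tau_rw: conjugate Gamma update on the (n-1) increments
      tau_rw <- stats::rgamma(1, shape = pri$tau_shape + (Tn - 1) / 2,
                              rate = pri$tau_rate + qf_tt / 2)
    }

    ## -- interaction field: per-tract RW1 paths, centred, parallel accepts
    if (spec$interaction) {
      Z <- matrix(stats::rnorm(n * Tn), n, Tn)
      Z <- Z - rowMeans(Z)
      D <- exp(ls["eta"]) * Z
      eta_new <- eta + D
      lp_new <- lp_vec + D[cbind(dat$it, dat$iy)]
      ok <- guard_ok(lp_new)
      if (ok) {
        ll_new <- llrow(lp_new, p0)
        qf_new <- rowSums((eta_new[, -1, drop = FALSE] -
                             eta_new[, -Tn, drop = FALSE])^2)
        dll <- rowsum(ll_new - ll_row, dat$it, reorder = TRUE)[, 1]
        logr_i <- dll - (tau_int / 2) * (qf_new - qf_eta)
        if (anyNA(logr_i))
          stop("non-finite log-posterior while updating component: eta")
        accept_i <- log(stats::runif(n)) < logr_i
        if (any(accept_i)) {
          rows <- accept_i[dat$it]
          eta[accept_i, ] <- eta_new[accept_i, ]
          qf_eta[accept_i] <- qf_new[accept_i]
          lp_vec[rows] <- lp_new[rows]
          ll_row[rows] <- ll_new[rows]
        }
        apr <- mean(pmin(1, exp(logr_i)))
      } else apr <- 0
      adapt("eta", apr, i)

      tau_int <- stats::rgamma(1, shape = pri$tau_shape + n * (Tn - 1) / 2,
                               rate = pri$tau_rate + sum(qf_eta) / 2)
    }

    ## -- heterogeneity SD (log-scale MH; (n-1) exponent: field is centred)
    if (spec$heterogeneity) {
      d <- stats::rnorm(1, 0, exp(ls["sig_het"]))
      sig_new <- sig_het * exp(d)
      logr <- mh_logr(
        (-(n - 1) * log(sig_new) - sum_u2 / (2 * sig_new^2) -
           sig_new^2 / (2 * pri$sigma_scale^2) + log(sig_new)) -
          (-(n - 1) * log(sig_het) - sum_u2 / (2 * sig_het^2) -
             sig_het^2 / (2 * pri$sigma_scale^2) + log(sig_het)), "sigma_het")
      apr <- min(1, exp(logr))
      if (stats::runif(1) < apr) sig_het <- sig_new
      adapt("sig_het", apr, i)
    }

    ## -- spatial SD and Matern kappa (log-scale MH)
    if (spec$spatial) {
      s_logpost <- function(sig, qf, logdetC, log1C1)
        -(n - 1) * log(sig) - 0.5 * logdetC + 0.5 * log1C1 -
          qf / (2 * sig^2)

      d <- stats::rnorm(1, 0, exp(ls["sig_sp"]))
      sig_new <- sig_sp * exp(d)
      logr <- mh_logr(
        s_logpost(sig_new, qf_s, sp$logdetC, sp$log1C1) -
          sig_new^2 / (2 * pri$sigma_scale^2) + log(sig_new) -
          s_logpost(sig_sp, qf_s, sp$logdetC, sp$log1C1) +
          sig_sp^2 / (2 * pri$sigma_scale^2) - log(sig_sp), "sigma_sp")
      apr <- min(1, exp(logr))
      if (stats::runif(1) < apr) sig_sp <- sig_new
      adapt("sig_sp", apr, i)

      d <- stats::rnorm(1, 0, exp(ls["kap"]))
      kap_new <- kappa * exp(d)
      sp_new <- upd_spatial(kap_new)
      if (!is.null(sp_new)) {
        qf_new <- qfC(s, sp_new$U)
        logr <- mh_logr(
          s_logpost(sig_sp, qf_new, sp_new$logdetC, sp_new$log1C1) +
            stats::dnorm(log(kap_new), kap_meanlog, pri$kappa_sdlog, log = TRUE) -
            s_logpost(sig_sp, qf_s, sp$logdetC, sp$log1C1) -
            stats::dnorm(log(kappa), kap_meanlog, pri$kappa_sdlog, log = TRUE),
          "kappa")
        apr <- min(1, exp(logr))
        if (stats::runif(1) < apr) {
          kappa <- kap_new; sp <- sp_new; qf_s <- qf_new
        }
      } else apr <- 0
      adapt("kap", apr, i)
    }

    ## -- ZIP mixing weight (logit-scale MH, Uniform(0,1) prior)
    if (spec$family == "zip") {
      l0 <- stats::qlogis(p0)
      l_new <- l0 + stats::rnorm(1, 0, exp(ls["p0"]))
      p_new <- stats::plogis(l_new)
      ll_new <- llrow(lp_vec, p_new)
      logr <- mh_logr(sum(ll_new) - sum(ll_row) +
                        log(p_new * (1 - p_new)) - log(p0 * (1 - p0)), "p_zero")
      apr <- min(1, exp(logr))
      if (stats::runif(1) < apr) { p0 <- p_new; ll_row <- ll_new }
      adapt("p0", apr, i)
    }

    ## -- store
    if (i > ctrl$n_burnin && (i - ctrl$n_burnin) %% ctrl$thin == 0L) {
      k <- k + 1L
      b0 <- a0 - sum(dat$xm * th)
      fixed[k, ] <- c(b0, th)
      hyper[k, ] <- c(sig_het, sig_sp, kappa, tau_rw, tau_int, p0, sum(ll_row))
      path_sd[k, ] <- c(stats::sd(tt), stats::sd(as.vector(eta)))
      if (!is.null(LL)) LL[k, ] <- ll_row
      if (!is.null(lat)) {
        lat$u[k, ] <- u; lat$s[k, ] <- s; lat$tt[k, ] <- tt
        lat$eta[k, ] <- as.vector(eta)
      }
      m_u <- m_u + u; m_s <- m_s + s; m_tt <- m_tt + tt; m_eta <- m_eta + eta
    }
  }

  list(fixed = fixed, hyper = hyper, path_sd = path_sd, loglik = LL,
       latent = lat,
       field_means = list(u = m_u / k, s = m_s / k, tt = m_tt / k,
                          eta = m_eta / k),
       accept = acc_k / pmax(acc_n, 1), seed = seed,
       scales = exp(ls))
}
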