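#' DIC from per-draw log-likelihoods
#'
#' `Dbar` is the posterior mean of the deviance `-2 loglik`; `Dhat` the
#' deviance at the posterior mean of all parameters (the plug-in);
#' `p_D = Dbar - Dhat` the effective number of parameters; and
#' `DIC = Dhat + 2 p_D = Dbar + p_D`.
#'
#' @param loglik_draws matrix, retained draws x observations, of per-row
#'   log-likelihood terms.
#' @param loglik_plugin per-observation log-likelihood at the posterior
#'   means (vector, or its precomputed sum).
#' @return list with `dic`, `p_d`, `mean_deviance` (`Dbar`) and `dhat`.
#' @export
dic_from_loglik <- function(loglik_draws, loglik_plugin) {
  dev <- -2 * rowSums(loglik_draws)
  if (any(!is.finite(dev)))
    stop("non-finite deviance at draw(s): ",
         paste(utils::head(which(!is.finite(dev)), 5), collapse = ", "))
  dbar <- mean(dev)
  dhat <- -2 * sum(loglik_plugin)
  p_d <- dbar - dhat
  list(dic = dhat + 2 * p_d, p_d = p_d, mean_deviance = dbar, dhat = dhat)
}

#' DIC of a fitted model
#'
#' Uses the stored per-draw log-likelihood matrix and evaluates the plug-in
#' deviance at the posterior mean of every parameter, latent fields
#' included.
#'
#' @param fit a `bym_fit` fitted with `store_loglik = TRUE`.
#' @return list as in [dic_from_loglik()].
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  LL <- pool_chains(fit, "loglik")
  if (is.null(LL)) stop("fit was run with store_loglik = FALSE")
  ll_hat <- .plugin_loglik(fit)
  dic_from_loglik(LL, ll_hat)
}

# per-row log-likelihood at the posterior mean of all parameters
.plugin_loglik <- function(fit) {
  fixed <- pool_chains(fit, "fixed")
  hyper <- pool_chains(fit, "hyper")
  fm <- colMeans(fixed)
  nm <- colnames(fixed)
  beta <- vapply(paste0("Q", 2:5), function(cn)
    if (cn %in% nm) fm[[cn]] else 0, 0)
  gamma <- vapply(c("P4564", "P65M"), function(cn)
    if (cn %in% nm) fm[[cn]] else 0, 0)
  nchain <- length(fit$chains)
  avg <- function(what) Reduce(`+`, lapply(fit$chains,
    function(ch) ch$field_means[[what]])) / nchain
  params <- list(beta0 = fm[["beta0"]], beta = beta, gamma = gamma,
                 u = avg("u"), s = avg("s"), tau_t = avg("tt"),
                 eta = avg("eta"))
  lp <- linear_predictor(fit$panel, params, tract_ids = fit$tract_ids,
                         include_interaction = fit$spec$interaction)
  p0 <- if (fit$spec$family == "zip") mean(hyper[, "p_zero"]) else 0
  if (fit$mcmc$prior_only) return(numeric(nrow(fit$panel)))
  loglik(fit$panel$O, lp, family = fit$spec$family, p_zero = p0)$terms
}

#' Conditional predictive ordinates from per-draw log-likelihoods
#'
#' Harmonic-mean importance-sampling estimator from a single MCMC run:
#' `CPO_i = [ (1/S) sum_s 1 / p(y_i | theta_s) ]^{-1}`, computed stably in
#' log space.  Rows whose inverse-likelihood weights have relative Monte
#' Carlo error above 10% are flagged as unstable; a zero per-draw
#' likelihood makes the corresponding CPO exactly 0 (with a warning), and
#' the log-score is then infinite, surfaced rather than hidden.
#'
#' @param loglik_draws matrix, draws x observations.
#' @return list with `cpo` (per observation), `cv_ls`
#'   (`-mean(log(cpo))`), and `unstable` (logical flags).
#' @export
cpo_from_loglik <- function(loglik_draws) {
  S <- nrow(loglik_draws)
  log_cpo <- apply(loglik_draws, 2, function(l) {
    x <- -l  # log inverse likelihoods
    m <- max(x)
    if (!is.finite(m)) return(-Inf)  # some draw had zero likelihood
    -(m + log(mean(exp(x - m))))
  })
  cpo <- exp(log_cpo)
  if (any(cpo == 0))
    warning(sum(cpo == 0), " observation(s) with CPO = 0; cv.ls is infinite")
  unstable <- vapply(seq_len(ncol(loglik_draws)), function(i) {
    x <- -loglik_draws[, i]
    m <- max(x)
    if (!is.finite(m)) return(TRUE)
    w <- exp(x - m)
    stats::sd(w) / (sqrt(S) * mean(w)) > 0.1
  }, TRUE)
  list(cpo = cpo, cv_ls = -mean(log_cpo), unstable = unstable)
}

#' Conditional predictive ordinates of a fitted model
#' @param fit a `bym_fit` fitted with `store_loglik = TRUE`.
#' @return list as in [cpo_from_loglik()].
#' @export
cpo <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  LL <- pool_chains(fit, "loglik")
  if (is.null(LL)) stop("fit was run with store_loglik = FALSE")
  cpo_from_loglik(LL)
}

#' Compare fitted models by DIC and cv.ls
#'
#' One row per model with DIC, effective number of parameters and the
#' cross-validated log-score; the lower DIC and the lower cv.ls each flag
#' a preferred model, and agreement between the two is reported.
#'
#' @param ... named `bym_fit` or `bym_summary` objects (>= 1).
#' @return data frame of class `bym_comparison`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], c("bym_fit", "bym_summary")))
    fits <- fits[[1]]
  if (!length(fits)) stop("at least one fitted model required")
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    s <- if (inherits(f, "bym_summary")) f else summarize_fit(f)
    data.frame(model = nm,
               estimation = if (isTRUE(s$interaction)) "estimation 2" else "estimation 1",
               family = s$family, dic = s$dic, p_d = s$p_d, cv_ls = s$cv_ls)
  })
  out <- do.call(rbind, rows)
  out$preferred_dic <- seq_len(nrow(out)) == which.min(out$dic)
  out$preferred_cvls <- seq_len(nrow(out)) == which.min(out$cv_ls)
  structure(out, class = c("bym_comparison", "data.frame"))
}

#' Render a results table
#'
#' Mirrors the layout of a disease-mapping results table: relative-risk
#' rows per deprivation quintile, log-RR rows for the two age bands,
#' random-effect SDs, DIC and cv.ls, with an asterisk marking effects whose
#' 95% credible interval excludes the null (1 for RRs, 0 for log-RRs).
#'
#' @param ... named `bym_summary` (or `bym_fit`) objects, one column each.
#' @return data frame of formatted strings (class `bym_report`); also
#'   carries the comparison rows as attribute `comparison` when more than
#'   one model is given.
#' @export
render_report <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], c("bym_fit", "bym_summary")))
    fits <- fits[[1]]
  if (!length(fits)) stop("at least one fitted model required")
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  sums <- lapply(fits, function(f)
    if (inherits(f, "bym_summary")) f else summarize_fit(f))
  fmt <- function(m, l, u, sig)
    sprintf("%.4f (%.4f, %.4f)%s", m, l, u, ifelse(sig, " *", ""))
  cols <- lapply(sums, function(s) {
    rr <- s$rr
    v <- c(
      if (!is.null(rr)) stats::setNames(
        fmt(rr$mean, rr$lower, rr$upper, rr$significant),
        paste0("RR_", rownames(rr), "-deprivation")),
      if (!is.null(s$log_rr_age)) stats::setNames(
        fmt(s$log_rr_age$mean, s$log_rr_age$lower, s$log_rr_age$upper,
            s$log_rr_age$significant),
        paste0("logRR_", rownames(s$log_rr_age))),
      `SD temporal` = sprintf("%.5f", s$re_sd[["temporal"]]),
      `SD heterogeneity` = sprintf("%.5f", s$re_sd[["heterogeneity"]]),
      `SD spatial` = sprintf("%.5f", s$re_sd[["spatial"]]),
      `SD interaction` = sprintf("%.5f", s$re_sd[["interaction"]]),
      DIC = sprintf("%.2f", s$dic),
      `-log(mean(cpo))` = sprintf("%.4f", s$cv_ls)
    )
    v
  })
  rn <- names(cols[[1]])
  out <- data.frame(row.names = rn, lapply(cols, function(v) v[rn]),
                    check.names = FALSE)
  names(out) <- names(fits)
  if (length(sums) > 1)
    attr(out, "comparison") <- compare_models(sums)
  class(out) <- c("bym_report", "data.frame")
  out
}

#' @export
print.bym_report <- function(x, ...) {
  cat("Results of the Bayesian computation ('*' = 95% CrI excludes the null)\n")
  print.data.frame(x)
  cmp <- attr(x, "comparison")
  if (!is.null(cmp)) {
    cat("\nModel comparison:\n")
    print.data.frame(cmp)
  }
  invisible(x)
}
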