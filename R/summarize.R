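pool_chains <- function(fit, what) do.call(rbind, lapply(fit$chains, `[[`, what))

#' Posterior summary of a fitted model
#'
#' Relative risks are summarized on the exponential scale draw by draw
#' (posterior mean of `exp(beta)`, not `exp` of the posterior mean) with
#' equal-tailed 95% credible intervals; a quintile is flagged significant
#' when its interval excludes 1.  Random-effect summaries are the posterior
#' means of the heterogeneity and spatial SD hyperparameters and of the
#' empirical SDs of the temporal and interaction paths.  DIC/pD and the
#' cross-validated log-score are attached when the per-draw log-likelihood
#' was stored.
#'
#' @param fit a `bym_fit` with at least 100 retained draws.
#' @param prob credible-interval mass (default 0.95).
#' @param information_criteria compute DIC and cv.ls (default TRUE).
#' @return object of class `bym_summary`: `rr` (per-quintile data frame),
#'   `log_rr_age`, `re_sd`, `p_zero`, `dic`, `p_d`, `cv_ls`, `n_draws`.
#' @export
summarize_fit <- function(fit, prob = 0.95, information_criteria = TRUE) {
  stopifnot(inherits(fit, "bym_fit"))
  fixed <- pool_chains(fit, "fixed")
  if (nrow(fixed) < 100) stop("too few retained draws (< 100)")
  hyper <- pool_chains(fit, "hyper")
  path_sd <- pool_chains(fit, "path_sd")
  a <- (1 - prob) / 2
  qs <- c(a, 1 - a)

  summ_exp <- function(draws) {
    rr <- exp(draws)
    ci <- stats::quantile(rr, qs, names = FALSE)
    data.frame(mean = mean(rr), lower = ci[1], upper = ci[2],
               significant = ci[1] > 1 | ci[2] < 1)
  }
  rr <- NULL
  qcols <- intersect(paste0("Q", 2:5), colnames(fixed))
  if (length(qcols)) {
    rr <- do.call(rbind, lapply(qcols, function(cn) summ_exp(fixed[, cn])))
    rownames(rr) <- qcols
  }
  log_rr_age <- NULL
  acols <- intersect(c("P4564", "P65M"), colnames(fixed))
  if (length(acols)) {
    log_rr_age <- do.call(rbind, lapply(acols, function(cn) {
      ci <- stats::quantile(fixed[, cn], qs, names = FALSE)
      data.frame(mean = mean(fixed[, cn]), lower = ci[1], upper = ci[2],
                 significant = ci[1] > 0 | ci[2] < 0)
    }))
    rownames(log_rr_age) <- acols
  }
  b0ci <- stats::quantile(fixed[, "beta0"], qs, names = FALSE)
  re_sd <- c(
    heterogeneity = if (fit$spec$heterogeneity) mean(hyper[, "sigma_het"]) else NA,
    spatial = if (fit$spec$spatial) mean(hyper[, "sigma_sp"]) else NA,
    temporal = if (fit$spec$temporal) mean(path_sd[, "sd_temporal"]) else NA,
    interaction = if (fit$spec$interaction) mean(path_sd[, "sd_interaction"]) else NA
  )
  out <- list(
    rr = rr, log_rr_age = log_rr_age,
    beta0 = data.frame(mean = mean(fixed[, "beta0"]),
                       lower = b0ci[1], upper = b0ci[2]),
    re_sd = re_sd,
    p_zero = if (fit$spec$family == "zip") mean(hyper[, "p_zero"]) else NA,
    dic = NA_real_, p_d = NA_real_, cv_ls = NA_real_,
    n_draws = nrow(fixed), family = fit$spec$family,
    interaction = fit$spec$interaction
  )
  if (information_criteria && !is.null(fit$chains[[1]]$loglik)) {
    d <- dic(fit)
    out$dic <- d$dic; out$p_d <- d$p_d
    out$cv_ls <- cpo(fit)$cv_ls
  }
  structure(out, class = "bym_summary")
}

#' @export
print.bym_summary <- function(x, digits = 4, ...) {
  cat(sprintf("<bym_summary> family=%s, %s interaction, %d draws\n",
              x$family, if (x$interaction) "with" else "without", x$n_draws))
  if (!is.null(x$rr)) {
    cat("Relative risks, deprivation quintiles (Q1 = reference):\n")
    print(round(x$rr[1:3], digits))
  }
  if (!is.null(x$log_rr_age)) {
    cat("Log-RR, age structure:\n")
    print(round(x$log_rr_age[1:3], digits))
  }
  cat("Random-effect SDs (posterior means):\n")
  print(round(x$re_sd, 5))
  if (is.finite(x$dic))
    cat(sprintf("DIC %.2f (pD %.2f), cv.ls %.4f\n", x$dic, x$p_d, x$cv_ls))
  invisible(x)
}

# ---- convergence diagnostics ----------------------------------------------

# split potential-scale-reduction: each chain is halved, and Rhat is the
# ratio of pooled (biased) variance over the splits to the mean within-split
# (biased) variance, square-rooted.  Identical stationary chains give 1.
rhat_splits <- function(splits) {
  v <- vapply(splits, function(x) mean((x - mean(x))^2), 0)
  m <- vapply(splits, mean, 0)
  W <- mean(v)
  if (W == 0) return(1)
  sqrt(1 + mean((m - mean(m))^2) / W)
}

# Geyer initial-monotone-sequence effective sample size of one chain
ess_one <- function(x) {
  N <- length(x)
  if (stats::var(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(N - 1, 1000), plot = FALSE)$acf[, 1, 1]
  npair <- floor(length(ac) / 2)
  G <- ac[2 * seq_len(npair) - 1] + ac[2 * seq_len(npair)]
  pos <- which(G <= 0)
  if (length(pos)) G <- G[seq_len(pos[1] - 1)]
  if (length(G) > 1) G <- cummin(G)  # enforce monotone decrease
  tau <- max(2 * sum(G) - 1, 1e-8)
  min(N / tau, N)
}

#' Convergence diagnostics across chains
#'
#' Split potential-scale-reduction (each chain halved) and effective sample
#' size (Geyer initial monotone sequence, summed over chains) for every
#' scalar the posterior summary reports.  A warning is emitted when any
#' Rhat exceeds 1.05.
#'
#' @param x a `bym_fit` with >= 2 chains, or a list of equal-length numeric
#'   vectors / single-column matrices (one chain each).
#' @param split halve each chain before computing Rhat (default TRUE).
#' @return data frame with `parameter`, `rhat`, `ess`.
#' @export
convergence_report <- function(x, split = TRUE) {
  if (inherits(x, "bym_fit")) {
    if (length(x$chains) < 2) stop("need >= 2 chains")
    fx <- lapply(x$chains, `[[`, "fixed")
    hy <- lapply(x$chains, `[[`, "hyper")
    keep <- c("sigma_het", "sigma_sp", "kappa", "tau_rw", "tau_int", "p_zero")
    on <- c(x$spec$heterogeneity, x$spec$spatial, x$spec$spatial,
            x$spec$temporal, x$spec$interaction, x$spec$family == "zip")
    mats <- lapply(seq_along(fx), function(c)
      cbind(fx[[c]], hy[[c]][, keep[on], drop = FALSE]))
    chains <- lapply(colnames(mats[[1]]), function(cn)
      lapply(mats, function(m) m[, cn]))
    names(chains) <- colnames(mats[[1]])
  } else if (is.list(x)) {
    chains <- list(chain = lapply(x, as.numeric))
  } else stop("x must be a bym_fit or a list of chains")

  rows <- lapply(names(chains), function(nm) {
    ch <- chains[[nm]]
    if (length(unique(lengths(ch))) != 1) stop("mismatched chain lengths")
    splits <- if (split) {
      unlist(lapply(ch, function(v) {
        h <- floor(length(v) / 2)
        list(v[seq_len(h)], v[h + seq_len(h)])
      }), recursive = FALSE)
    } else ch
    data.frame(parameter = nm, rhat = rhat_splits(splits),
               ess = sum(vapply(ch, ess_one, 0)))
  })
  out <- do.call(rbind, rows)
  bad <- out$parameter[!is.na(out$rhat) & out$rhat > 1.05]
  if (length(bad))
    warning("Rhat > 1.05 for: ", paste(bad, collapse = ", "))
  out
}
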