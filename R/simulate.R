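#' Generating truth for the synthetic study
#'
#' Collects the parameters of the generative model.  Defaults are the
#' study-scale conditions the package emulates: quintile log-relative-risks
#' at the reported posterior means (RR 0.8592, 0.8129, 0.7315, 0.5768 for
#' Q2-Q5), age coefficients 3.8208 and 2.4520, random-effect standard
#' deviations 0.0295 (heterogeneity) and 0.0956 (spatial), RW1 precisions
#' matched to path SDs of ~0.03 (temporal) and ~0.002 (interaction), and an
#' intercept placing the crude rate near 1e-3 cases/person-year so that
#' tract-year means sit around 0.6 and zero counts land in the 40-70% band.
#'
#' @param beta0 intercept (log baseline rate).
#' @param beta length-4 quintile log-RRs (Q2..Q5 vs Q1).
#' @param gamma length-2 age coefficients (P4564, P65M).
#' @param sigma_het,sigma_sp random-effect SDs (>= 0).
#' @param kappa Matern scale (> 0); default gives a ~20 km practical range.
#' @param tau_rw,tau_int RW1 precisions (> 0).
#' @param p_zero ZIP structural-zero probability in `[0, 1]`.
#' @return object of class `bym_truth`; latent fields (`u`, `s`, `tau_t`,
#'   `eta`) are filled in by [simulate_fields()].
#' @export
bym_truth <- function(beta0 = -8.0,
                      beta = log(c(0.8592, 0.8129, 0.7315, 0.5768)),
                      gamma = c(3.8208, 2.4520),
                      sigma_het = 0.0295, sigma_sp = 0.0956,
                      kappa = sqrt(8) / 20,
                      tau_rw = 1100, tau_int = 250000,
                      p_zero = 0.3) {
  stopifnot(length(beta) == 4, length(gamma) == 2,
            sigma_het >= 0, sigma_sp >= 0, kappa > 0,
            tau_rw > 0, tau_int > 0, p_zero >= 0, p_zero <= 1)
  structure(
    list(beta0 = beta0, beta = beta, gamma = gamma,
         sigma_het = sigma_het, sigma_sp = sigma_sp, kappa = kappa,
         tau_rw = tau_rw, tau_int = tau_int, p_zero = p_zero,
         u = NULL, s = NULL, tau_t = NULL, eta = NULL),
    class = "bym_truth"
  )
}

#' Simulate the four latent random-effect fields
#'
#' Fills the latent fields of a [bym_truth()]: iid Gaussian heterogeneity
#' `u`, a zero-mean Matern (`nu = 1`) spatial field `s` on the tract
#' centroids, a temporal RW1 path `tau_t`, and independent per-tract RW1
#' interaction paths `eta` sharing one precision.  All fields are recentred
#' to sum to zero (per tract-path for `eta`) so the intercept stays
#' identifiable.
#'
#' @param geometry a `tract_geometry`.
#' @param n_years number of years (>= 2).
#' @param truth a `bym_truth` with hyperparameters set.
#' @param seed integer seed.
#' @return the `bym_truth` with `u`, `s` (length `n`), `tau_t` (length
#'   `n_years`) and `eta` (`n x n_years`) filled.
#' @export
simulate_fields <- function(geometry, n_years, truth = bym_truth(), seed = NULL) {
  if (n_years < 2) stop("n_years must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  n <- length(geometry$tract_id)
  u <- stats::rnorm(n, 0, truth$sigma_het)
  u <- u - mean(u)
  if (truth$sigma_sp > 0) {
    Sig <- matern_covariance(geometry, truth$sigma_sp^2, truth$kappa)
    s <- as.vector(crossprod(attr(Sig, "chol"), stats::rnorm(n)))
    s <- s - mean(s)
  } else {
    s <- numeric(n)
  }
  tau_t <- simulate_rw1(n_years, truth$tau_rw)
  eta <- t(replicate(n, simulate_rw1(n_years, truth$tau_int)))
  truth$u <- u; truth$s <- s; truth$tau_t <- tau_t; truth$eta <- eta
  truth
}

#' Simulate tract-year covariates
#'
#' Populations are log-normal (median `pop_median`, log-sd `pop_sdlog`,
#' constant over years); age fractions are truncated normals around typical
#' Spanish census-tract structure (26% aged 45-64, 16% aged 65+), with
#' `P4564 + P65M <= 0.9` enforced by rescaling.  Quintiles come either from
#' a supplied per-tract assignment or uniformly at random.
#'
#' @param geometry a `tract_geometry`.
#' @param years vector of calendar years (contiguous).
#' @param quintile optional per-tract quintile in 1..5.
#' @param pop_median,pop_sdlog log-normal population parameters.
#' @param seed integer seed.
#' @return a covariate panel (no `O` column yet), one row per tract-year,
#'   tract-major order.
#' @export
simulate_covariates <- function(geometry, years, quintile = NULL,
                                pop_median = 600, pop_sdlog = 0.4,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(geometry$tract_id)
  if (is.null(quintile)) quintile <- sample(1:5, n, replace = TRUE)
  stopifnot(length(quintile) == n, all(quintile %in% 1:5))
  pob <- stats::rlnorm(n, log(pop_median), pop_sdlog)
  p45 <- pmin(pmax(stats::rnorm(n, 0.26, 0.03), 0.10), 0.40)
  p65 <- pmin(pmax(stats::rnorm(n, 0.16, 0.04), 0.05), 0.35)
  tot <- p45 + p65
  over <- tot > 0.9
  p45[over] <- p45[over] * 0.9 / tot[over]
  p65[over] <- p65[over] * 0.9 / tot[over]
  ny <- length(years)
  data.frame(
    tract_id = rep(geometry$tract_id, each = ny),
    year = rep(years, times = n),
    Pob = rep(round(pob), each = ny),
    P4564 = rep(p45, each = ny),
    P65M = rep(p65, each = ny),
    quintile = rep(as.integer(quintile), each = ny)
  )
}

#' Simulate case counts under the generative model
#'
#' Computes `mu_it = Pob_it * exp(linear predictor)` and draws counts:
#' Poisson draws `O ~ Poisson(mu)`; ZIP replaces a draw by a structural
#' zero with probability `p_zero`; Bernoulli emits the at-least-one-case
#' indicator with `P(1) = 1 - exp(-mu)`.
#'
#' @param panel covariate panel (from [simulate_covariates()]).
#' @param truth a `bym_truth`, latent fields filled (or NULL fields = 0).
#' @param family `"poisson"`, `"zip"` or `"bernoulli"`.
#' @param seed integer seed.
#' @return the panel with an integer `O` column added, plus attribute
#'   `log_mu`.
#' @export
simulate_counts <- function(panel, truth, family = c("poisson", "zip", "bernoulli"),
                            seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  lp <- linear_predictor(panel, truth)
  if (any(lp > 30)) stop("linear predictor exceeds 30: mu would overflow; check beta0/populations")
  mu <- exp(lp)
  N <- nrow(panel)
  O <- switch(family,
    poisson = stats::rpois(N, mu),
    zip = ifelse(stats::runif(N) < truth$p_zero, 0L, stats::rpois(N, mu)),
    bernoulli = as.integer(stats::runif(N) < -expm1(-mu))
  )
  panel$O <- as.integer(O)
  panel <- panel[c("tract_id", "year", "O", "Pob", "P4564", "P65M", "quintile")]
  attr(panel, "log_mu") <- lp
  panel
}

#' Simulate a tract-level socioeconomic indicator table
#'
#' Sixteen indicators driven by one spatially smooth latent deprivation
#' field (Matern, nu = 1) plus indicator-specific noise; half the columns
#' are stored with reversed sign and flagged `orientation = -1`, to
#' exercise the orientation step of the DP2 construction.
#'
#' @param geometry a `tract_geometry`.
#' @param n_indicators number of indicators (default 16).
#' @param kappa Matern scale of the latent deprivation field.
#' @param seed integer seed.
#' @return list with `indicators` (tracts x indicators matrix),
#'   `orientation` (+1/-1 per column) and `latent` (the driving field).
#' @export
simulate_indicators <- function(geometry, n_indicators = 16,
                                kappa = sqrt(8) / 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(geometry$tract_id)
  Sig <- matern_covariance(geometry, 1, kappa)
  latent <- as.vector(crossprod(attr(Sig, "chol"), stats::rnorm(n)))
  load <- stats::runif(n_indicators, 0.5, 1.5)
  noise <- stats::runif(n_indicators, 0.5, 1.0)
  X <- sapply(seq_len(n_indicators), function(k)
    load[k] * latent + stats::rnorm(n, 0, noise[k]))
  colnames(X) <- sprintf("ind%02d", seq_len(n_indicators))
  orientation <- rep(c(1, -1), length.out = n_indicators)
  X <- sweep(X, 2, orientation, "*")  # store half reversed
  list(indicators = X, orientation = orientation, latent = latent)
}

#' Full synthetic study scenario
#'
#' End-to-end generator: geometry, a 16-indicator table, the DP2 index and
#' its quintiles, covariates, latent fields and counts.  The default shape
#' is the study scale the package emulates — 542 tracts x 14 years
#' (1993-2006) — with populations small enough that 40-70% of tract-year
#' counts are zero.
#'
#' @param seed integer seed.
#' @param n_tracts,n_years scenario size.
#' @param extent square study region side, km.
#' @param family observation family for the counts.
#' @param truth generating `bym_truth` (hyperparameters; fields are drawn).
#' @param interaction draw a nonzero interaction field (default TRUE).
#' @return list with `geometry`, `panel`, `truth` (fields filled),
#'   `indicators`, `dp2`.
#' @export
default_study_scenario <- function(seed = 1, n_tracts = 542, n_years = 14,
                                   extent = 50,
                                   family = c("poisson", "zip", "bernoulli"),
                                   truth = bym_truth(),
                                   interaction = TRUE) {
  family <- match.arg(family)
  set.seed(seed)
  geometry <- generate_geometry(n_tracts, extent = extent)
  ind <- simulate_indicators(geometry)
  dp2 <- dp2_index(ind$indicators, ind$orientation, tract_id = geometry$tract_id)
  quintile <- assign_quintiles(dp2$index)$quintile
  years <- seq(1993, length.out = n_years)
  panel <- simulate_covariates(geometry, years, quintile = quintile)
  truth <- simulate_fields(geometry, n_years, truth)
  if (!interaction) truth$eta <- matrix(0, n_tracts, n_years)
  panel <- simulate_counts(panel, truth, family = family)
  list(geometry = geometry, panel = panel, truth = truth,
       indicators = ind, dp2 = dp2)
}

#' Write / read the tract-year panel as CSV
#'
#' Header: `tract_id,year,O,Pob,P4564,P65M,quintile`.
#'
#' @param panel the panel data frame.
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  cols <- c("tract_id", "year", "O", "Pob", "P4564", "P65M", "quintile")
  utils::write.csv(panel[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path)
  need <- c("tract_id", "year", "O", "Pob", "P4564", "P65M", "quintile")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel file missing column(s): ", paste(miss, collapse = ", "))
  validate_panel(df)
  df
}

#' Validate a tract-year panel
#'
#' One row per tract-year, contiguous years, nonnegative integer counts,
#' positive populations, age fractions in `[0, 1]` with sum at most 1,
#' quintiles in 1..5.
#'
#' @param panel the panel data frame.
#' @export
validate_panel <- function(panel) {
  if (anyDuplicated(panel[c("tract_id", "year")]))
    stop("duplicate (tract, year) rows")
  yrs <- sort(unique(panel$year))
  if (length(yrs) > 1 && !all(diff(yrs) == 1))
    stop("years do not form a contiguous range")
  if (!is.null(panel$O) && (any(panel$O < 0) || any(panel$O != round(panel$O))))
    stop("counts O must be nonnegative integers")
  if (any(panel$Pob <= 0)) stop("populations must be positive")
  if (any(panel$P4564 < 0 | panel$P4564 > 1) || any(panel$P65M < 0 | panel$P65M > 1))
    stop("age fractions must lie in [0,1]")
  if (any(panel$P4564 + panel$P65M > 1)) stop("P4564 + P65M exceeds 1")
  if (!all(panel$quintile %in% 1:5)) stop("quintile outside {1..5}")
  invisible(TRUE)
}

#' Write / read a truth record as JSON
#' @param truth a `bym_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- bym_truth(beta0 = x$beta0, beta = x$beta, gamma = x$gamma,
                  sigma_het = x$sigma_het, sigma_sp = x$sigma_sp,
                  kappa = x$kappa, tau_rw = x$tau_rw, tau_int = x$tau_int,
                  p_zero = x$p_zero)
  tr$u <- x$u; tr$s <- x$s; tr$tau_t <- x$tau_t
  if (!is.null(x$eta)) tr$eta <- as.matrix(x$eta)
  tr
}
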