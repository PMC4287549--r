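#' Pena DP2 synthetic deprivation index
#'
#' Aggregates a tract-by-indicator table into a single deprivation score by
#' Pena's distance method.  Each indicator is first oriented so that larger
#' values mean more deprivation, standardized by its (population) standard
#' deviation, and measured as a distance from a fictitious "least deprived"
#' base tract holding every per-indicator minimum.  Indicators are then
#' ranked by the absolute correlation of each with the current index, and
#' re-aggregated with correction factors `1 - R^2` — the R-squared of
#' regressing each indicator on all higher-ranked ones — so that information
#' already carried by stronger indicators is not double counted.  The rank /
#' re-weight cycle iterates until the ordering (or the index) stabilizes.
#'
#' @param indicators numeric matrix or data frame, tracts x indicators;
#'   column names label the indicators.  No missing values; every indicator
#'   must have nonzero variance.
#' @param orientation per-indicator sign vector: `+1` if larger raw values
#'   mean more deprivation, `-1` if less.  Default all `+1`.
#' @param tract_id optional tract identifiers (defaults to row numbers).
#' @param tol convergence tolerance on the maximum absolute index change.
#' @param max_iter maximum number of rank / re-weight iterations.
#' @return An object of class `dp2_result`: list with `index` (one score per
#'   tract; higher = more deprived), `weights` (the `1 - R^2` correction
#'   factors, in the original column order; the first-ranked indicator has
#'   weight exactly 1), `order` (final indicator ranking, by column index),
#'   `iterations`, and `tract_id`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' dp2_index(X)
#' @export
dp2_index <- function(indicators, orientation = NULL, tract_id = NULL,
                      tol = 1e-8, max_iter = 100) {
  X <- as.matrix(indicators)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 tracts")
  if (p < 1) stop("need at least 1 indicator")
  if (anyNA(X)) stop("missing values in indicator table")
  if (is.null(orientation)) orientation <- rep(1, p)
  if (length(orientation) != p || !all(orientation %in% c(-1, 1)))
    stop("orientation must be a vector of +1/-1, one per indicator")
  if (is.null(tract_id)) tract_id <- seq_len(n)
  if (is.null(colnames(X))) colnames(X) <- paste0("ind", seq_len(p))

  # orient: larger oriented value = more deprived
  Xo <- sweep(X, 2, orientation, "*")

  # population standard deviation (convention: divisor n, documented)
  sds <- apply(Xo, 2, function(v) sqrt(mean((v - mean(v))^2)))
  if (any(sds <= .Machine$double.eps)) {
    stop(sprintf("constant indicator(s) rejected: %s",
                 paste(colnames(X)[sds <= .Machine$double.eps], collapse = ", ")))
  }

  # Frechet distances from the least-deprived base (per-indicator minimum)
  base <- apply(Xo, 2, min)
  D <- sweep(sweep(Xo, 2, base, "-"), 2, sds, "/")  # all >= 0

  index <- rowSums(D)  # Frechet initialization: all weights 1
  ord_prev <- NULL
  for (iter in seq_len(max_iter)) {
    r <- as.vector(stats::cor(Xo, index))
    ord <- order(abs(r), decreasing = TRUE)
    w <- numeric(p)
    w[ord[1]] <- 1
    if (p > 1) {
      for (k in 2:p) {
        higher <- ord[seq_len(k - 1)]
        fit <- stats::lm.fit(cbind(1, Xo[, higher, drop = FALSE]), Xo[, ord[k]])
        r2 <- 1 - sum(fit$residuals^2) / sum((Xo[, ord[k]] - mean(Xo[, ord[k]]))^2)
        w[ord[k]] <- 1 - min(max(r2, 0), 1)
      }
    }
    index_new <- as.vector(D %*% w)
    stable_order <- !is.null(ord_prev) && identical(ord, ord_prev)
    small_change <- max(abs(index_new - index)) < tol
    index <- index_new
    if (stable_order || small_change) {
      return(structure(
        list(index = index, weights = stats::setNames(w, colnames(X)),
             order = ord, iterations = iter, tract_id = tract_id),
        class = "dp2_result"
      ))
    }
    ord_prev <- ord
  }
  stop(sprintf(
    "DP2 did not converge in %d iterations; last two orderings: [%s] vs [%s]",
    max_iter, paste(ord_prev, collapse = " "), paste(ord, collapse = " ")
  ))
}

#' @export
print.dp2_result <- function(x, ...) {
  cat(sprintf("<dp2_result> %d tracts, %d indicators, %d iteration(s)\n",
              length(x$index), length(x$weights), x$iterations))
  cat("weights (1 - R^2):\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Assign deprivation quintiles and reference-coded dummies
#'
#' Quintile 1 is the least deprived fifth and is the reference category; the
#' dummy matrix therefore has exactly four columns (Q2-Q5).  Cutpoints are
#' the empirical 20/40/60/80 percentiles (unweighted over tracts,
#' `quantile type 7`); values tied with a cutpoint fall in the lower
#' quintile, so the assignment is a deterministic function of the values.
#'
#' @param index per-tract deprivation scores (>= 5 tracts).
#' @return list with `quintile` (integer in 1..5 per tract) and `dummies`
#'   (matrix with columns `Q2..Q5`; all-zero row means quintile 1).
#' @examples
#' assign_quintiles(1:10)$quintile  # 1 1 2 2 3 3 4 4 5 5
#' @export
assign_quintiles <- function(index) {
  index <- as.numeric(index)
  if (length(index) < 5) stop("need at least 5 tracts to form quintiles")
  if (anyNA(index)) stop("missing index values")
  cuts <- stats::quantile(index, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  q <- 1L + rowSums(outer(index, cuts, ">"))
  dummies <- matrix(0L, length(index), 4, dimnames = list(NULL, paste0("Q", 2:5)))
  for (j in 2:5) dummies[q == j, j - 1L] <- 1L
  list(quintile = as.integer(q), dummies = dummies)
}
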