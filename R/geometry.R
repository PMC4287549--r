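#' Generate synthetic tract geometry
#'
#' Samples census-tract centroids uniformly on the square `[0, extent]^2`
#' (planar km coordinates, no geodesy) and computes the full matrix of
#' pairwise Euclidean distances.  Stands in for real census-tract
#' centroids when no cartography is available.
#'
#' @param n_tracts number of tracts (>= 2).
#' @param extent side length of the square study region, km.
#' @param seed integer seed; the geometry is deterministic given the seed.
#' @return An object of class `tract_geometry`: a list with `tract_id`
#'   (integer ids `1:n_tracts`), `x`, `y` (centroid coordinates, km) and
#'   `dist` (symmetric `n_tracts x n_tracts` distance matrix, km).
#' @examples
#' g <- generate_geometry(25, extent = 10, seed = 1)
#' range(g$dist)
#' @export
generate_geometry <- function(n_tracts, extent = 50, seed = NULL) {
  if (!is.numeric(n_tracts) || length(n_tracts) != 1L || n_tracts < 2)
    stop("n_tracts must be a single number >= 2")
  n_tracts <- as.integer(n_tracts)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(n_tracts, 0, extent)
  y <- stats::runif(n_tracts, 0, extent)
  tract_geometry(tract_id = seq_len(n_tracts), x = x, y = y)
}

#' Construct a tract geometry from centroid coordinates
#'
#' @param tract_id unique tract identifiers.
#' @param x,y planar centroid coordinates (km).
#' @return A `tract_geometry` object (see [generate_geometry()]).
#' @export
tract_geometry <- function(tract_id, x, y) {
  if (anyDuplicated(tract_id)) stop("tract ids must be unique")
  if (length(x) != length(tract_id) || length(y) != length(tract_id))
    stop("tract_id, x, y must have equal length")
  d <- as.matrix(stats::dist(cbind(x, y)))
  dimnames(d) <- list(tract_id, tract_id)
  structure(
    list(tract_id = tract_id, x = as.numeric(x), y = as.numeric(y), dist = d),
    class = "tract_geometry"
  )
}

#' @export
print.tract_geometry <- function(x, ...) {
  cat(sprintf(
    "<tract_geometry> %d tracts, extent x [%.2f, %.2f] y [%.2f, %.2f] km\n",
    length(x$tract_id), min(x$x), max(x$x), min(x$y), max(x$y)
  ))
  invisible(x)
}

#' Validate a tract geometry
#'
#' Checks the distance-matrix invariants: symmetry, zero diagonal,
#' non-negativity and the triangle inequality (within numerical tolerance).
#'
#' @param geometry a `tract_geometry`.
#' @param tol numerical tolerance.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_geometry <- function(geometry, tol = 1e-8) {
  d <- geometry$dist
  if (!isSymmetric(unname(d), tol = tol)) stop("distance matrix not symmetric")
  if (any(abs(diag(d)) > tol)) stop("distance matrix diagonal not zero")
  if (any(d < -tol)) stop("negative distances")
  n <- nrow(d)
  # triangle inequality via one random third point per pair is too weak at
  # small n; check exhaustively (n here is at most a few hundred)
  for (k in seq_len(n)) {
    viol <- d - outer(d[, k], d[k, ], "+")
    if (any(viol > tol)) stop("triangle inequality violated")
  }
  invisible(TRUE)
}

#' Write / read tract geometry as CSV
#'
#' The on-disk format is `tract_id,x,y`; distances are recomputed on read.
#'
#' @param geometry a `tract_geometry`.
#' @param path file path.
#' @return `read_geometry` returns a `tract_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  utils::write.csv(
    data.frame(tract_id = geometry$tract_id, x = geometry$x, y = geometry$y),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("tract_id", "x", "y") %in% names(df)))
  tract_geometry(df$tract_id, df$x, df$y)
}
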