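#' Hip-to-origin distance series
#'
#' Scalar trajectory used to align two climbs of the same route: the
#' Euclidean distance of the hip centre `J8`, projected into the wall x-y
#' plane, from the wall origin, per route frame.
#'
#' @param seq wall-space [skeleton_sequence()].
#' @param limits route limits from [delimit_route()]; `NULL` uses the whole
#'   sequence.
#' @return Numeric vector (mm), length `re - rs`.
#' @export
hip_distance_series <- function(seq, limits = NULL) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (seq$space != "wall") ct_stop("space_error", "hip_distance_series requires wall coordinates")
  x <- seq$positions[, "J8", "x"]
  y <- seq$positions[, "J8", "y"]
  d <- sqrt(x^2 + y^2)
  if (!is.null(limits)) d <- d[(limits$start + 1):limits$end]
  d
}

#' Dynamic time warping of two scalar series
#'
#' Dynamic-programming optimum over all legal couplings with absolute
#' difference as the local cost: the coupling starts at `(0, 0)`, ends at
#' `(n-1, m-1)`, both index streams are monotonically non-decreasing and
#' each step advances at least one index by exactly 1. One optimal coupling
#' is returned, ties broken by preferring the diagonal step.
#'
#' @param a,b non-empty numeric vectors.
#' @return An object of class `dtw_coupling`: `pairs` (k x 2 matrix of
#'   0-based index pairs) and `distance` (minimal accumulated cost).
#' @export
dtw_align <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) ct_stop("empty_input", "dtw requires non-empty series")
  res <- .dtw_core(a, b)
  structure(list(pairs = res$pairs, distance = res$distance,
                 n = length(a), m = length(b)),
            class = "dtw_coupling")
}

#' @export
print.dtw_coupling <- function(x, ...) {
  cat(sprintf("<dtw_coupling> %d x %d, %d pairs, distance %.3f\n",
              x$n, x$m, nrow(x$pairs), x$distance))
  invisible(x)
}

# Coupling validity: boundary + monotone + unit steps (the alignment rules).
validate_coupling <- function(cp) {
  p <- cp$pairs
  stopifnot(all(p[1, ] == c(0, 0)),
            all(p[nrow(p), ] == c(cp$n - 1, cp$m - 1)))
  if (nrow(p) > 1) {
    d <- diff(p)
    stopifnot(all(d >= 0), all(d <= 1), all(rowSums(d) >= 1))
  }
  invisible(TRUE)
}

#' Align two climbs of the same route
#'
#' Composes [hip_distance_series()] on the reference and query climbs and
#' aligns them with [dtw_align()]. Pair indices are route-relative: row
#' `(i, j)` couples reference route frame `i` to query route frame `j`.
#'
#' @param reference,query wall-space [skeleton_sequence()]s of the same
#'   route (possibly from different camera setups - wall calibration makes
#'   them comparable).
#' @param ref_limits,query_limits route limits; computed with
#'   [delimit_route()] when `NULL`.
#' @return A `dtw_coupling` with extra fields `ref_limits`, `query_limits`.
#' @export
align_climbs <- function(reference, query, ref_limits = NULL, query_limits = NULL) {
  ref_limits <- ref_limits %||% delimit_route(reference)
  query_limits <- query_limits %||% delimit_route(query)
  cp <- dtw_align(hip_distance_series(reference, ref_limits),
                  hip_distance_series(query, query_limits))
  cp$ref_limits <- ref_limits
  cp$query_limits <- query_limits
  cp
}
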