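#' Sparse depth grid for 2-D to 3-D lifting
#'
#' The depth sensor delivers a rectangular lattice of depth samples over the
#' image, far sparser than the pixel raster. A 2-D keypoint is lifted to 3-D
#' by looking up its depth in this lattice ([lift_joint_depth()]).
#'
#' @param px numeric vector of lattice pixel x coordinates (columns),
#'   strictly increasing.
#' @param py numeric vector of lattice pixel y coordinates (rows),
#'   strictly increasing.
#' @param depth `length(py) x length(px)` matrix of depth samples (mm,
#'   positive; `NA` marks invalid nodes).
#' @return An object of class `depth_grid` with `dims = c(rows, cols)`.
#' @export
depth_grid <- function(px, py, depth) {
  depth <- as.matrix(depth)
  if (nrow(depth) != length(py) || ncol(depth) != length(px))
    ct_stop("schema_error", "depth must be length(py) x length(px)")
  if (any(diff(px) <= 0) || any(diff(py) <= 0))
    ct_stop("schema_error", "lattice coordinates must be strictly increasing")
  if (any(depth <= 0, na.rm = TRUE))
    ct_stop("schema_error", "depth values must be positive")
  structure(list(px = px, py = py, depth = depth,
                 dims = c(length(py), length(px))),
            class = "depth_grid")
}

#' Lift a 2-D keypoint to a depth value
#'
#' Selects the 3x3 block of lattice nodes surrounding the keypoint and
#' returns the mean depth of the 3 nodes nearest in pixel distance. Averaging
#' the nearest three smooths over single bad lattice samples while staying
#' local to the joint.
#'
#' @param joint2d numeric `(x, y)` pixel coordinates, inside the lattice
#'   extent.
#' @param grid a [depth_grid()].
#' @return Depth in millimetres.
#' @export
lift_joint_depth <- function(joint2d, grid) {
  stopifnot(inherits(grid, "depth_grid"), length(joint2d) == 2)
  x <- joint2d[1]; y <- joint2d[2]
  if (x < min(grid$px) || x > max(grid$px) || y < min(grid$py) || y > max(grid$py))
    ct_stop("out_of_bounds", "joint (%g, %g) outside the depth-grid extent", x, y)
  ci <- which.min(abs(grid$px - x))
  ri <- which.min(abs(grid$py - y))
  cs <- max(1, ci - 1):min(length(grid$px), ci + 1)
  rs <- max(1, ri - 1):min(length(grid$py), ri + 1)
  nb <- expand.grid(r = rs, c = cs)
  nb$depth <- grid$depth[cbind(nb$r, nb$c)]
  nb <- nb[is.finite(nb$depth), , drop = FALSE]
  if (nrow(nb) < 3)
    ct_stop("insufficient_depth", "fewer than 3 valid depth nodes near (%g, %g)", x, y)
  d2 <- (grid$px[nb$c] - x)^2 + (grid$py[nb$r] - y)^2
  mean(nb$depth[order(d2)[1:3]])
}
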