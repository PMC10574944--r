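#' Fit the climbing-wall plane with seeded RANSAC
#'
#' Repeatedly samples 3 points, counts points within `inlier_tol` of the
#' candidate plane, keeps the consensus winner and refines it by total least
#' squares on the inlier set. The returned normal is unit length and oriented
#' toward the camera origin (the sensor always sees the climbing face of the
#' wall).
#'
#' @param cloud numeric `n x 3` matrix of points (camera frame, mm).
#' @param iterations number of RANSAC hypotheses, default 500.
#' @param inlier_tol inlier distance threshold in mm, default 20.
#' @param seed integer seed making the fit deterministic; `NULL` leaves the
#'   RNG state alone.
#' @return List with `normal` (unit 3-vector), `offset` (mm, the plane is
#'   `normal . p + offset = 0`; positive when the normal points back toward
#'   the origin), and `inliers` (logical mask).
#' @export
fit_wall_plane <- function(cloud, iterations = 500, inlier_tol = 20, seed = NULL) {
  cloud <- as.matrix(cloud)
  if (nrow(cloud) < 3) ct_stop("fit_failure", "need at least 3 points to fit a plane")
  plane_from_3 <- function(p) {
    n <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
    if (vec_norm(n) < 1e-9) return(NULL)
    n <- unit(n)
    list(n = n, d = -sum(n * p[1, ]))
  }
  best <- NULL
  best_count <- -1
  with_local_seed(seed, {
    for (it in seq_len(iterations)) {
      idx <- sample.int(nrow(cloud), 3)
      pl <- plane_from_3(cloud[idx, , drop = FALSE])
      if (is.null(pl)) next
      dist <- abs(cloud %*% pl$n + pl$d)
      cnt <- sum(dist <= inlier_tol)
      if (cnt > best_count) {
        best_count <- cnt
        best <- pl
      }
    }
  })
  if (is.null(best) || best_count < 3)
    ct_stop("fit_failure", "RANSAC found no plane (degenerate cloud)")
  # least-squares refinement on the consensus set, then one re-selection
  mask <- abs(cloud %*% best$n + best$d) <= inlier_tol
  for (pass in 1:2) {
    pts <- cloud[mask, , drop = FALSE]
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    n <- sv$v[, 3]
    d <- -sum(n * ctr)
    mask <- abs(cloud %*% n + d) <= inlier_tol
  }
  # orient toward the camera origin: distance from origin along n is -d;
  # the origin-facing normal satisfies n . (0 - ctr) > 0.
  ctr <- colMeans(cloud[mask, , drop = FALSE])
  if (sum(n * (-ctr)) < 0) { n <- -n; d <- -d }
  list(normal = as.numeric(n), offset = as.numeric(d), inliers = as.vector(mask))
}

#' Rotation aligning the camera z-axis with a plane normal
#'
#' Evaluates `R = 2 (z+n)(z+n)^T / ((z+n)^T (z+n)) - I` with
#' `z = (0,0,1)`: a rotation by 180 degrees about the bisector of `z` and
#' `n`, which maps `z` onto `n` and is orthonormal with determinant +1.
#'
#' @param n unit 3-vector, not antiparallel to `(0,0,1)`.
#' @return 3x3 rotation matrix `R` with `R %*% c(0,0,1) == n`.
#' @export
rotation_from_normal <- function(n) {
  n <- as.numeric(n)
  stopifnot(length(n) == 3)
  if (abs(vec_norm(n) - 1) > 1e-6)
    ct_stop("degenerate_geometry", "normal must be unit length")
  z <- c(0, 0, 1)
  w <- z + n
  denom <- sum(w * w)
  if (denom < 1e-12)
    ct_stop("singular_configuration",
            "normal antiparallel to z: supply a pre-rotation first")
  2 * outer(w, w) / denom - diag(3)
}

#' Extract the wall rectangle from plane inliers
#'
#' Projects the inlier points into the fitted plane and computes the
#' minimum-area enclosing rectangle of their convex hull (rotating calipers).
#' Corners are returned in 3-D camera coordinates ordered upper-left,
#' upper-right, lower-right, lower-left in a gravity-aligned in-plane frame
#' (camera y taken as up); the first corner is the wall-coordinate origin.
#'
#' @param inliers numeric `n x 3` matrix of approximately planar points.
#' @param normal optional unit plane normal; refitted from the points when
#'   omitted.
#' @return `4 x 3` matrix of corner points (mm).
#' @export
extract_wall_rectangle <- function(inliers, normal = NULL) {
  inliers <- as.matrix(inliers)
  if (nrow(inliers) < 4) ct_stop("extraction_error", "need at least 4 boundary points")
  ctr <- colMeans(inliers)
  sv <- svd(sweep(inliers, 2, ctr))
  if (sv$d[2] < 1e-6 * sv$d[1])
    ct_stop("extraction_error", "points are collinear; no rectangle")
  n <- if (is.null(normal)) sv$v[, 3] else unit(as.numeric(normal))
  if (sum(n * (-ctr)) < 0) n <- -n
  # gravity-aligned in-plane basis: v ~ camera up projected into the plane
  up <- c(0, 1, 0)
  v <- up - sum(up * n) * n
  if (vec_norm(v) < 1e-9) v <- c(1, 0, 0) - sum(c(1, 0, 0) * n) * n
  v <- unit(v)
  u <- cross3(v, n) # right-pointing, so (u, v, n) is right-handed
  P <- sweep(inliers, 2, ctr) %*% cbind(u, v)
  hull <- grDevices::chull(P)
  H <- P[hull, , drop = FALSE]
  if (nrow(H) < 3) ct_stop("extraction_error", "degenerate hull; no rectangle")
  best <- NULL
  best_area <- Inf
  m <- nrow(H)
  for (i in seq_len(m)) {
    e <- H[(i %% m) + 1, ] - H[i, ]
    len <- vec_norm(e)
    if (len < 1e-9) next
    ex <- e / len
    ey <- c(-ex[2], ex[1])
    xs <- H %*% ex
    ys <- H %*% ey
    area <- (max(xs) - min(xs)) * (max(ys) - min(ys))
    if (area < best_area) {
      best_area <- area
      best <- list(ex = ex, ey = ey, x0 = min(xs), x1 = max(xs),
                   y0 = min(ys), y1 = max(ys))
    }
  }
  if (is.null(best) || best_area < 1e-6)
    ct_stop("extraction_error", "degenerate rectangle")
  corn2 <- rbind(
    best$x0 * best$ex + best$y0 * best$ey,
    best$x1 * best$ex + best$y0 * best$ey,
    best$x1 * best$ex + best$y1 * best$ey,
    best$x0 * best$ex + best$y1 * best$ey)
  # order UL, UR, LR, LL in the gravity frame (u right, v up)
  ang <- atan2(corn2[, 2] - mean(corn2[, 2]), corn2[, 1] - mean(corn2[, 1]))
  corn2 <- corn2[order(-ang), , drop = FALSE] # clockwise from the top
  score <- corn2[, 2] - corn2[, 1] # up-left corner maximises y - x
  ul <- which.max(score)
  corn2 <- corn2[((ul - 1 + 0:3) %% 4) + 1, , drop = FALSE]
  corners <- sweep(corn2 %*% rbind(u, v), 2, ctr, `+`)
  colnames(corners) <- c("x", "y", "z")
  corners
}

#' Build the wall model from a calibration point cloud
#'
#' Runs [fit_wall_plane()] and [extract_wall_rectangle()], then assembles the
#' rigid camera-to-wall transform: origin at the upper-left rectangle corner,
#' x along the top edge (rightward), y up the wall, z along the
#' origin-facing normal so the climber side of the wall has positive z.
#' Wall-interior points therefore have x in `[0, width]` and y in
#' `[-height, 0]`.
#'
#' @param cloud numeric `n x 3` point cloud (camera frame, mm).
#' @inheritParams fit_wall_plane
#' @return An object of class `wall_model`: `normal`, `origin`, `corners`
#'   (4x3, camera frame), `rotation` (3x3), `translation`, `width`, `height`.
#' @export
build_wall_model <- function(cloud, iterations = 500, inlier_tol = 20, seed = NULL) {
  fit <- fit_wall_plane(cloud, iterations, inlier_tol, seed)
  corners <- extract_wall_rectangle(cloud[fit$inliers, , drop = FALSE], fit$normal)
  wall_model_from_corners(corners, fit$normal)
}

# Assemble the model from ordered corners (UL, UR, LR, LL) and the normal.
wall_model_from_corners <- function(corners, normal) {
  n <- unit(as.numeric(normal))
  x_axis <- unit(corners[2, ] - corners[1, ])
  y_axis <- cross3(n, x_axis)
  R <- rbind(x_axis, y_axis, n)
  dimnames(R) <- NULL
  origin <- as.numeric(corners[1, ])
  t <- as.numeric(-R %*% origin)
  structure(list(normal = n, origin = origin, corners = corners,
                 rotation = R, translation = t,
                 width = vec_norm(corners[2, ] - corners[1, ]),
                 height = vec_norm(corners[4, ] - corners[1, ])),
            class = "wall_model")
}

#' @export
print.wall_model <- function(x, ...) {
  cat(sprintf("<wall_model> %.0f x %.0f mm, normal (%.3f, %.3f, %.3f)\n",
              x$width, x$height, x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Re-express a skeleton sequence in wall coordinates
#'
#' Applies the rigid transform `p_wall = R p_camera + t` to every joint.
#' Points on the wall plane map to z of roughly 0, the origin corner to
#' (0,0,0), and pairwise joint distances are preserved exactly.
#'
#' @param seq a camera-space [skeleton_sequence()].
#' @param wall a [build_wall_model()] result.
#' @return The sequence tagged `wall`; if already in wall space, returned
#'   unchanged with a warning.
#' @export
to_wall_coords <- function(seq, wall) {
  stopifnot(inherits(seq, "skeleton_sequence"), inherits(wall, "wall_model"))
  if (seq$space == "wall") {
    warning("sequence already in wall coordinates; returning unchanged")
    return(seq)
  }
  pos <- seq$positions
  flat <- matrix(pos, nrow = dim(pos)[1] * 13, ncol = 3)
  flat <- flat %*% t(wall$rotation)
  flat <- sweep(flat, 2, wall$translation, `+`)
  out <- array(flat, dim = dim(pos), dimnames = dimnames(pos))
  skeleton_sequence(out, fps = seq$fps, space = "wall", confidence = seq$confidence)
}

# Inverse transform: wall -> camera (used by the synthetic rig).
to_camera_coords <- function(seq, wall) {
  stopifnot(inherits(seq, "skeleton_sequence"), seq$space == "wall")
  pos <- seq$positions
  flat <- matrix(pos, nrow = dim(pos)[1] * 13, ncol = 3)
  flat <- sweep(flat, 2, wall$translation) %*% wall$rotation
  out <- array(flat, dim = dim(pos), dimnames = dimnames(pos))
  skeleton_sequence(out, fps = seq$fps, space = "camera", confidence = seq$confidence)
}

#' Save / load a wall model as JSON
#'
#' @param wall a `wall_model`.
#' @param path file path.
#' @export
write_wall_model <- function(wall, path) {
  stopifnot(inherits(wall, "wall_model"))
  jsonlite::write_json(list(normal = wall$normal, origin = wall$origin,
                            corners = unname(apply(wall$corners, 1, as.numeric, simplify = FALSE)),
                            rotation = unname(apply(wall$rotation, 1, as.numeric, simplify = FALSE)),
                            translation = wall$translation,
                            width = wall$width, height = wall$height),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wall_model
#' @export
read_wall_model <- function(path) {
  doc <- jsonlite::fromJSON(path) # row lists simplify to matrices row-wise
  corners <- doc$corners
  colnames(corners) <- c("x", "y", "z")
  structure(list(normal = as.numeric(doc$normal), origin = as.numeric(doc$origin),
                 corners = corners,
                 rotation = doc$rotation,
                 translation = as.numeric(doc$translation),
                 width = doc$width, height = doc$height),
            class = "wall_model")
}
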