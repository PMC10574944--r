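#' Joint identifiers of the 13-joint climbing skeleton
#'
#' The skeleton carries 13 named joints `J2`..`J14`. Left/right assignment
#' follows the arm chain wrist-elbow-shoulder-hip and the leg chain
#' hip-knee-ankle: `J7`/`J4` left/right wrist, `J6`/`J3` left/right elbow,
#' `J5`/`J2` left/right shoulder, `J12`/`J9` left/right hip, `J13`/`J10`
#' left/right knee, `J14`/`J11` left/right ankle, `J8` the hip centre (root,
#' used as the centre-of-mass proxy).
#'
#' @format Character vector of the 13 joint ids, in numeric order.
#' @export
JOINT_IDS <- paste0("J", 2:14)

#' Key joints driving motion segmentation and phase transitions
#'
#' Wrists, hip centre and ankles: the joints whose motion intervals feed the
#' phase state machine and the movement-based error rules.
#'
#' @format Character vector, subset of [JOINT_IDS].
#' @export
KEY_JOINTS <- c("J7", "J4", "J8", "J14", "J11")

# Symbolic roles, used throughout the detectors.
JOINT_ROLE <- c(
  J2 = "shoulder_right", J3 = "elbow_right", J4 = "wrist_right",
  J5 = "shoulder_left", J6 = "elbow_left", J7 = "wrist_left",
  J8 = "hip_center", J9 = "hip_right", J10 = "knee_right",
  J11 = "ankle_right", J12 = "hip_left", J13 = "knee_left",
  J14 = "ankle_left"
)

#' Construct a skeleton sequence
#'
#' A skeleton sequence is a fixed-rate stream of 13-joint 3-D poses stored as
#' a `frames x 13 x 3` numeric array (millimetres) with a coordinate-frame
#' tag: `"camera"` for raw recordings, `"wall"` after calibration
#' ([to_wall_coords()]).
#'
#' @param positions numeric array `n_frames x 13 x 3`; the joint dimension
#'   must be named with [JOINT_IDS] (any order) and the coordinate dimension
#'   with `c("x","y","z")`, or be unnamed in exactly that order.
#' @param fps frames per second, default 60.
#' @param space coordinate-frame tag, `"camera"` or `"wall"`.
#' @param confidence optional `n_frames x 13` matrix of per-joint scores in
#'   `[0,1]`; carried but not used by the analysis.
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(positions, fps = 60, space = c("camera", "wall"),
                              confidence = NULL) {
  space <- match.arg(space)
  if (length(dim(positions)) != 3 || dim(positions)[2] != 13 || dim(positions)[3] != 3)
    ct_stop("schema_error", "positions must be an n x 13 x 3 array")
  jn <- dimnames(positions)[[2]]
  if (!is.null(jn)) {
    missing <- setdiff(JOINT_IDS, jn)
    unknown <- setdiff(jn, JOINT_IDS)
    if (length(unknown) > 0)
      ct_stop("schema_error", "unknown joints: %s", paste(unknown, collapse = ", "))
    if (length(missing) > 0)
      ct_stop("schema_error", "missing joints: %s", paste(missing, collapse = ", "))
    positions <- positions[, JOINT_IDS, , drop = FALSE]
  }
  dimnames(positions) <- list(NULL, JOINT_IDS, c("x", "y", "z"))
  if (any(!is.finite(positions)))
    ct_stop("schema_error", "non-finite joint position encountered")
  if (!is.numeric(fps) || fps <= 0) ct_stop("schema_error", "fps must be > 0")
  if (!is.null(confidence)) {
    confidence <- as.matrix(confidence)
    stopifnot(nrow(confidence) == dim(positions)[1], ncol(confidence) == 13)
  }
  structure(list(positions = positions, fps = fps, space = space,
                 confidence = confidence),
            class = "skeleton_sequence")
}

#' @export
length.skeleton_sequence <- function(x) dim(x$positions)[1]

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence> %d frames @ %g fps, %s space\n",
              length(x), x$fps, x$space))
  invisible(x)
}

#' Extract one joint's per-frame positions
#'
#' @param seq a [skeleton_sequence()].
#' @param joint a joint id from [JOINT_IDS].
#' @return `n_frames x 3` matrix with columns x, y, z (mm).
#' @export
joint_track <- function(seq, joint) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (!joint %in% JOINT_IDS) ct_stop("schema_error", "unknown joint '%s'", joint)
  seq$positions[, joint, , drop = TRUE]
}

# Slice frames [start, end) (0-based) out of a sequence.
subset_sequence <- function(seq, start, end) {
  stopifnot(start >= 0, end <= length(seq), start < end)
  idx <- (start + 1):end
  skeleton_sequence(seq$positions[idx, , , drop = FALSE], fps = seq$fps,
                    space = seq$space,
                    confidence = if (!is.null(seq$confidence)) seq$confidence[idx, , drop = FALSE])
}

#' Interior angle at a joint
#'
#' Interior angle at `b` between the rays `b -> a` and `b -> c`, in degrees.
#' Used for the elbow angle (wrist, elbow, shoulder) and shoulder angle
#' (elbow, shoulder, hip) of the holding arm in the decoupling and
#' shoulder-relaxing rules.
#'
#' @param a,b,c numeric 3-vectors (mm).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
#' @examples
#' joint_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # 90
joint_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vec_norm(u)
  nv <- vec_norm(v)
  if (nu < .Machine$double.eps || nv < .Machine$double.eps)
    ct_stop("degenerate_geometry", "zero-length ray in joint_angle")
  ct <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ct))) * 180 / pi
}

# Vectorised angle over frame-wise point matrices (n x 3 each).
angle_series <- function(A, B, C) {
  U <- A - B
  V <- C - B
  nu <- sqrt(rowSums(U^2))
  nv <- sqrt(rowSums(V^2))
  ct <- rowSums(U * V) / pmax(nu * nv, .Machine$double.eps)
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Half-open frame interval
#'
#' Intervals are 0-based and half-open: `[start, end)` covers frames
#' `start, ..., end - 1`.
#'
#' @param start first frame (inclusive), `>= 0`.
#' @param end one past the last frame (exclusive), `> start`.
#' @return A one-row data frame with columns `start`, `end`.
#' @export
frame_interval <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0) || any(end <= start))
    ct_stop("invalid_interval", "frame interval requires 0 <= start < end")
  data.frame(start = start, end = end)
}

interval_length <- function(iv) iv$end - iv$start
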