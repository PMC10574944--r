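#' Per-joint speed series
#'
#' Speed of one joint from a wall-space sequence: centered finite difference
#' of the projected position scaled by fps, followed by a moving-average
#' smoothing. The first and last frames replicate their neighbour's value.
#' The `xy` axis projects the skeleton into the wall plane (the projection
#' used for all phase-driving joints); `y` isolates vertical hip travel;
#' `z` is the wall-normal component.
#'
#' @param seq a wall-space [skeleton_sequence()].
#' @param joint joint id.
#' @param axis `"xy"`, `"y"` or `"z"`.
#' @param smooth_window odd moving-average width in frames, default 9
#'   (0.15 s at 60 fps; curbs frame-to-frame jitter without blunting real
#'   speed peaks, which last tens of frames).
#' @return An object of class `speed_series`: `values` (mm/s, length equal
#'   to the sequence), `joint`, `axis`, `fps`.
#' @export
joint_speed <- function(seq, joint, axis = c("xy", "y", "z"), smooth_window = 9) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (seq$space != "wall") ct_stop("space_error", "joint_speed requires a wall-space sequence")
  axis <- match.arg(axis)
  stopifnot(smooth_window >= 1, smooth_window %% 2 == 1)
  n <- length(seq)
  if (n < 3) ct_stop("too_short", "need at least 3 frames for a speed series")
  P <- joint_track(seq, joint)
  comp <- switch(axis, xy = c("x", "y"), y = "y", z = "z")
  Q <- P[, comp, drop = FALSE]
  D <- (Q[c(2:n, n), , drop = FALSE] - Q[c(1, 1:(n - 1)), , drop = FALSE])
  # centered difference over 2 frames for interior, forward/backward at ends
  div <- c(1, rep(2, n - 2), 1)
  v <- sqrt(rowSums(D^2)) / div * seq$fps
  v[1] <- v[2]; v[n] <- v[n - 1]
  v <- roll_mean(v, smooth_window)
  structure(list(values = v, joint = joint, axis = axis, fps = seq$fps),
            class = "speed_series")
}

#' Standard score of a speed series
#'
#' `z = (v - mu) / sigma` with the mean and population standard deviation
#' taken over the whole series: the number of standard deviations each
#' frame's speed sits above or below the series mean.
#'
#' @param speed a [joint_speed()] result or plain numeric vector.
#' @return Numeric vector of z values.
#' @export
zscore_series <- function(speed) {
  v <- if (inherits(speed, "speed_series")) speed$values else as.numeric(speed)
  if (length(v) < 2) ct_stop("too_short", "need at least 2 values for a z-score")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) ct_stop("constant_signal", "constant series has no standard score")
  (v - mu) / sigma
}

#' Motion segmentation by standard-score envelope
#'
#' Builds the n-sigma envelope `g = rolling_mean(v) + n * rolling_sd(v)`
#' over a centered window, takes its global maximum `Ok`, and marks frames
#' where `g >= rho * Ok` (equivalently, where the envelope crosses its
#' complement `Ok - g` scaled by `rho`) as moving. Maximal runs shorter than
#' `min_len` (the minimum frame count for a valid movement) are discarded,
#' which suppresses short jitter-induced speed spikes.
#'
#' @param speed a [joint_speed()] result or numeric vector (mm/s).
#' @param n sigma multiplier, default 2.
#' @param window rolling-window width in frames (odd), default 15.
#' @param rho threshold fraction of the envelope maximum, default 0.5.
#' @param min_len minimum interval length in frames (K-mu), default 30.
#' @return An object of class `motion_intervals`: a data frame of disjoint
#'   sorted half-open intervals plus `joint`/`axis` tags.
#' @export
segment_motion <- function(speed, n = 2, window = 15, rho = 0.5, min_len = 30) {
  v <- if (inherits(speed, "speed_series")) speed$values else as.numeric(speed)
  joint <- if (inherits(speed, "speed_series")) speed$joint else NA_character_
  axis <- if (inherits(speed, "speed_series")) speed$axis else NA_character_
  stopifnot(window >= 3, rho > 0, rho < 1, min_len >= 1)
  if (window %% 2 == 0) window <- window + 1
  empty <- structure(list(intervals = data.frame(start = integer(0), end = integer(0)),
                          joint = joint, axis = axis, min_len = min_len),
                     class = "motion_intervals")
  if (length(v) < window || max(v) <= 0) return(empty)
  g <- roll_mean(v, window) + n * roll_sd(v, window)
  ok <- max(g)
  if (ok <= 0 || sqrt(mean((v - mean(v))^2)) == 0) return(empty)
  iv <- runs_to_intervals(g >= rho * ok)
  iv <- iv[interval_length(iv) >= min_len, , drop = FALSE]
  rownames(iv) <- NULL
  # warn when segment speeds are wildly uneven: the global Ok threshold can
  # then miss the slow movements
  if (nrow(iv) >= 2) {
    peaks <- vapply(seq_len(nrow(iv)),
                    function(i) max(v[(iv$start[i] + 1):iv$end[i]]), 0)
    if (max(peaks) > 4 * min(peaks))
      warning(sprintf("segment peak speeds differ by >4x for %s/%s; consider lowering rho",
                      joint, axis))
  }
  structure(list(intervals = iv, joint = joint, axis = axis, min_len = min_len),
            class = "motion_intervals")
}

#' @export
print.motion_intervals <- function(x, ...) {
  cat(sprintf("<motion_intervals> %s/%s: %d interval(s)\n",
              x$joint, x$axis, nrow(x$intervals)))
  if (nrow(x$intervals) > 0) print(x$intervals)
  invisible(x)
}

#' Segment motion for all phase-driving joints
#'
#' Convenience wrapper running [joint_speed()] + [segment_motion()] for the
#' wrists and ankles in the wall x-y plane and for the hip centre on the
#' vertical axis alone (the hip series that gates the reaching phase).
#'
#' @param seq wall-space [skeleton_sequence()].
#' @param config a [pipeline_config()] (threshold and window settings).
#' @return Named list of [segment_motion()] results: `J7`, `J4`, `J14`,
#'   `J11` (xy plane) and `J8y` (y axis).
#' @export
segment_key_joints <- function(seq, config = pipeline_config()) {
  out <- list()
  for (j in c("J7", "J4", "J14", "J11")) {
    sp <- joint_speed(seq, j, "xy", config$smooth_window)
    out[[j]] <- segment_motion(sp, config$n_sigma, config$window, config$rho, config$k_mu)
  }
  sp <- joint_speed(seq, "J8", "y", config$smooth_window)
  out$J8y <- segment_motion(sp, config$n_sigma, config$window, config$rho, config$k_mu)
  out
}

#' Automatic route delimitation
#'
#' Finds the analysed portion of a recording: the route starts at the first
#' frame of the first half where the hip centre `J8` is lowest (the climber
#' at the start hold) and ends at the last frame of the second half where
#' either wrist reaches its maximum height (the final grab). Frames after
#' the top-out - jumping off or down-climbing - are excluded.
#'
#' @param seq wall-space [skeleton_sequence()].
#' @return List with 0-based `start` (rs) and `end` (re) frame indices,
#'   `start < end`; downstream analysis covers the half-open `[rs, re)`.
#' @export
delimit_route <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (seq$space != "wall") ct_stop("space_error", "delimit_route requires wall coordinates")
  nf <- length(seq)
  if (nf < 2) ct_stop("too_short", "need at least 2 frames")
  half <- floor(nf / 2)
  hip_y <- seq$positions[, "J8", "y"]
  rs <- which.min(hip_y[1:half]) - 1L # first minimiser, 0-based
  w7 <- seq$positions[, "J7", "y"]
  w4 <- seq$positions[, "J4", "y"]
  idx2 <- (half + 1):nf
  last_at_max <- function(v) idx2[max(which(v[idx2] == max(v[idx2])))] - 1L
  re <- max(last_at_max(w7), last_at_max(w4))
  ascent <- max(max(w7[idx2]) - w7[rs + 1], max(w4[idx2]) - w4[rs + 1])
  if (ascent <= 0) ct_stop("delimitation_error", "no ascent found (wrists never rise)")
  if (rs >= re) ct_stop("delimitation_error", "no ascent found (rs >= re)")
  list(start = as.integer(rs), end = as.integer(re))
}
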