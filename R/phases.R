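#' Holding / supporting hand assignment
#'
#' The holding hand bears the body weight: the wrist in the higher position
#' (greater wall y). The other wrist is the supporting hand. Exact ties are
#' broken toward the previous assignment, or the left wrist `J7` when there
#' is none.
#'
#' @param frame either a 13 x 3 position matrix (one skeleton frame, wall
#'   space) or a [skeleton_sequence()] (then all frames are assigned).
#' @param previous previous holding wrist id, used only to break ties.
#' @return For a single frame, a list `holding`/`supporting`; for a
#'   sequence, a character vector of holding-wrist ids per frame.
#' @export
assign_hands <- function(frame, previous = NULL) {
  if (inherits(frame, "skeleton_sequence")) {
    y7 <- frame$positions[, "J7", "y"]
    y4 <- frame$positions[, "J4", "y"]
    holding <- character(length(y7))
    prev <- previous %||% "J7"
    for (i in seq_along(y7)) {
      holding[i] <- if (y7[i] > y4[i]) "J7" else if (y4[i] > y7[i]) "J4" else prev
      prev <- holding[i]
    }
    return(holding)
  }
  y7 <- frame["J7", "y"]
  y4 <- frame["J4", "y"]
  holding <- if (y7 > y4) "J7" else if (y4 > y7) "J4" else (previous %||% "J7")
  list(holding = holding, supporting = setdiff(c("J7", "J4"), holding))
}

#' Segment the route into climbing phases
#'
#' Classifies every route frame into the three-phase climbing cycle using
#' the key-joint motion intervals, with transition priority matching the
#' phase state machine: foot motion puts the climber in *preparation*; with
#' both feet static, hip-vertical or hand motion means *reaching*; with the
#' hands static and no reaching trigger the climber is in *stabilization*
#' (also the initial state - a climber hangs static at the start hold).
#' Runs shorter than `min_phase_frames` are absorbed into the preceding
#' phase to suppress single-frame flicker at transition boundaries.
#'
#' @param seq wall-space [skeleton_sequence()] (full recording).
#' @param motion named list from [segment_key_joints()] (`J7`, `J4`, `J14`,
#'   `J11`, `J8y`), intervals in full-recording frame indices.
#' @param limits route limits from [delimit_route()].
#' @param min_phase_frames minimum phase-instance length, default 5.
#' @return Data frame of phase instances with columns `id`, `kind`
#'   (`preparation`/`reaching`/`stabilization`), `start`, `end` (0-based
#'   half-open, full-recording frames); instances tile `[rs, re)` and
#'   consecutive instances differ in kind.
#' @export
segment_phases <- function(seq, motion, limits, min_phase_frames = 5) {
  stopifnot(all(c("J7", "J4", "J14", "J11", "J8y") %in% names(motion)))
  frames <- limits$start:(limits$end - 1L)
  if (length(frames) == 0 || limits$end <= limits$start)
    return(data.frame(id = integer(0), kind = character(0),
                      start = integer(0), end = integer(0)))
  foot <- frames_in_intervals(frames, motion$J14$intervals) |
    frames_in_intervals(frames, motion$J11$intervals)
  hand <- frames_in_intervals(frames, motion$J7$intervals) |
    frames_in_intervals(frames, motion$J4$intervals)
  hipy <- frames_in_intervals(frames, motion$J8y$intervals)
  kind <- ifelse(foot, "preparation", ifelse(hipy | hand, "reaching", "stabilization"))
  # absorb short runs into the previous phase (the leading run into the next)
  r <- rle(kind)
  while (length(r$lengths) > 1 && any(r$lengths < min_phase_frames)) {
    i <- which(r$lengths < min_phase_frames)[1]
    r$values[i] <- if (i == 1) r$values[2] else r$values[i - 1]
    r <- rle(inverse.rle(r))
  }
  kind <- inverse.rle(r)
  r <- rle(kind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(id = seq_along(r$values), kind = r$values,
             start = limits$start + starts, end = limits$start + ends)
}

# Frame-level phase kinds over [rs, re), from a segment_phases() result.
phase_kind_per_frame <- function(phases) {
  if (nrow(phases) == 0) return(character(0))
  rep(phases$kind, phases$end - phases$start)
}
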