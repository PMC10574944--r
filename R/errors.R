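# The six technique-error detectors. All detectors are phase-gated:
# decoupling fires only in preparation, shoulder relaxing only in
# stabilization, the remaining four only in reaching. Events are half-open
# frame intervals in full-recording indices, tagged with the phase instance
# they occur in.

ERROR_TYPES <- c("decoupling", "reaching_hand_supports", "weight_shift",
                 "both_feet_set", "hip_close_to_wall", "shoulder_relaxing")

empty_events <- function() {
  data.frame(type = character(0), start = integer(0), end = integer(0),
             phase_id = integer(0))
}

# Arm angles per frame for one side: phi = elbow interior angle
# (wrist, elbow, shoulder), theta = shoulder interior angle
# (elbow, shoulder, hip of the same side).
arm_angles <- function(seq, side = c("left", "right")) {
  side <- match.arg(side)
  j <- if (side == "left") c(wrist = "J7", elbow = "J6", shoulder = "J5", hip = "J12")
       else c(wrist = "J4", elbow = "J3", shoulder = "J2", hip = "J9")
  P <- seq$positions
  list(
    phi = angle_series(P[, j["wrist"], ], P[, j["elbow"], ], P[, j["shoulder"], ]),
    theta = angle_series(P[, j["elbow"], ], P[, j["shoulder"], ], P[, j["hip"], ])
  )
}

# Holding-arm angles per frame given per-frame holding wrist ids.
holding_arm_angles <- function(seq, holding) {
  L <- arm_angles(seq, "left")
  R <- arm_angles(seq, "right")
  left <- holding == "J7"
  list(phi = ifelse(left, L$phi, R$phi),
       theta = ifelse(left, L$theta, R$theta))
}

# Turn a per-frame flag (over full-recording frames `frames`) into events,
# clipped to one phase instance, dropping runs < min_len.
flag_events <- function(frames, flag, type, phase_id, min_len) {
  iv <- runs_to_intervals(flag)
  iv <- iv[interval_length(iv) >= min_len, , drop = FALSE]
  if (nrow(iv) == 0) return(empty_events())
  data.frame(type = type, start = frames[1] + iv$start, end = frames[1] + iv$end,
             phase_id = phase_id)
}

phase_frames <- function(ph) ph$start:(ph$end - 1L)

#' Decoupling detector (preparation phase)
#'
#' While the feet are being set, the holding arm should stay straight. A
#' frame is flagged when the holding arm's elbow angle falls below `k_phi`
#' or its shoulder angle below `k_theta`; maximal runs of at least
#' `min_event_frames` within a preparation instance become events.
#'
#' @param seq wall-space [skeleton_sequence()] (full recording).
#' @param phases phase table from [segment_phases()].
#' @param hands per-frame holding-wrist ids from [assign_hands()] (full
#'   recording length).
#' @param config a [pipeline_config()].
#' @return Event data frame (`type`, `start`, `end`, `phase_id`).
#' @export
detect_decoupling <- function(seq, phases, hands, config = pipeline_config()) {
  detect_arm_angle_error(seq, phases, hands, config, "preparation", "decoupling")
}

#' Shoulder-relaxing detector (stabilization phase)
#'
#' After gripping, the new holding arm should stretch again. Same angle
#' rule as [detect_decoupling()] but gated to stabilization instances.
#'
#' @inheritParams detect_decoupling
#' @return Event data frame.
#' @export
detect_shoulder_relaxing <- function(seq, phases, hands, config = pipeline_config()) {
  detect_arm_angle_error(seq, phases, hands, config, "stabilization", "shoulder_relaxing")
}

detect_arm_angle_error <- function(seq, phases, hands, config, phase_kind, type) {
  ang <- holding_arm_angles(seq, hands)
  bad <- ang$phi < config$k_phi | ang$theta < config$k_theta
  out <- empty_events()
  for (i in which(phases$kind == phase_kind)) {
    fr <- phase_frames(phases[i, ])
    out <- rbind(out, flag_events(fr, bad[fr + 1], type, phases$id[i],
                                  config$min_event_frames))
  }
  out
}

#' Reaching-hand-supports detector (reaching phase)
#'
#' The supporting hand should stay on its hold while the climber stands up.
#' Within each reaching instance the frames where the supporting hand is
#' inside one of its motion intervals are accumulated; when that time
#' exceeds `k_t` seconds the moving span becomes an event.
#'
#' @inheritParams detect_decoupling
#' @param motion key-joint motion list from [segment_key_joints()].
#' @return Event data frame.
#' @export
detect_reaching_hand_supports <- function(seq, phases, hands, motion,
                                          config = pipeline_config()) {
  out <- empty_events()
  m7 <- motion$J7$intervals
  m4 <- motion$J4$intervals
  for (i in which(phases$kind == "reaching")) {
    fr <- phase_frames(phases[i, ])
    support <- ifelse(hands[fr + 1] == "J7", "J4", "J7")
    moving <- ifelse(support == "J7",
                     frames_in_intervals(fr, m7),
                     frames_in_intervals(fr, m4))
    if (sum(moving) > config$k_t * seq$fps) {
      span <- range(fr[moving])
      out <- rbind(out, data.frame(type = "reaching_hand_supports",
                                   start = span[1], end = span[2] + 1L,
                                   phase_id = phases$id[i]))
    }
  }
  out
}

#' Weight-shift detector (reaching phase)
#'
#' During the stand-up the knee of the supporting-side leg should pass in
#' front of that foot. Evaluated over the middle half of each reaching
#' instance (the two central quartets - at the very start and end of the
#' reach the knee legitimately trails the foot): frames where the
#' knee-to-ankle x-distance, signed toward the direction of hip travel
#' within the phase, stays below `k_dknee` are flagged. The supporting hand
#' is the majority per-frame assignment over the instance; supporting hand
#' `J7` selects the left leg (knee `J13`, ankle `J14`), `J4` the right
#' (knee `J10`, ankle `J11`).
#'
#' @inheritParams detect_decoupling
#' @return Event data frame.
#' @export
detect_weight_shift <- function(seq, phases, hands, config = pipeline_config()) {
  out <- empty_events()
  P <- seq$positions
  for (i in which(phases$kind == "reaching")) {
    ph <- phases[i, ]
    len <- ph$end - ph$start
    mid <- (ph$start + floor(len / 4)):(ph$start + floor(3 * len / 4) - 1L)
    if (length(mid) < 1) next
    fr <- phase_frames(ph)
    support <- ifelse(hands[fr + 1] == "J7", "J4", "J7")
    sup <- names(which.max(table(support)))
    knee <- if (sup == "J7") "J13" else "J10"
    ankle <- if (sup == "J7") "J14" else "J11"
    travel <- P[ph$end, "J8", "x"] - P[ph$start + 1, "J8", "x"]
    dir <- if (travel < 0) -1 else 1
    dx <- dir * (P[mid + 1, knee, "x"] - P[mid + 1, ankle, "x"])
    out <- rbind(out, flag_events(mid, dx < config$k_dknee, "weight_shift",
                                  ph$id, config$min_event_frames))
  }
  out
}

#' Both-feet-set detector (reaching phase)
#'
#' During the stand-up both feet must rest on the wall (hold or smear). A
#' frame is flagged when either foot is inside one of its motion intervals
#' or further than `eps_contact` from the wall plane (dangling).
#'
#' @inheritParams detect_reaching_hand_supports
#' @return Event data frame.
#' @export
detect_both_feet_set <- function(seq, phases, motion, config = pipeline_config()) {
  out <- empty_events()
  z14 <- seq$positions[, "J14", "z"]
  z11 <- seq$positions[, "J11", "z"]
  for (i in which(phases$kind == "reaching")) {
    fr <- phase_frames(phases[i, ])
    bad <- frames_in_intervals(fr, motion$J14$intervals) |
      frames_in_intervals(fr, motion$J11$intervals) |
      z14[fr + 1] > config$eps_contact |
      z11[fr + 1] > config$eps_contact
    out <- rbind(out, flag_events(fr, bad, "both_feet_set", phases$id[i],
                                  config$min_event_frames))
  }
  out
}

#' Hip-close-to-the-wall detector (reaching phase, reference-based)
#'
#' Compares the climber's hip-to-wall distance against a reference climb of
#' the same route through the DTW frame coupling: a query reaching frame is
#' flagged when its hip z exceeds the coupled reference frame's hip z by at
#' least `k_dhip`. One-to-many couplings use the smallest coupled reference
#' z (the most pessimistic comparison). One-sided: being closer to the wall
#' than the reference is never an error.
#'
#' @param query wall-space query [skeleton_sequence()] (full recording).
#' @param reference wall-space reference sequence.
#' @param coupling [align_climbs()] result (reference vs query).
#' @param phases query phase table from [segment_phases()].
#' @param config a [pipeline_config()].
#' @return Event data frame.
#' @export
detect_hip_close_to_wall <- function(query, reference, coupling, phases,
                                     config = pipeline_config()) {
  validate_coupling(coupling)
  qlim <- coupling$query_limits
  rlim <- coupling$ref_limits
  qz <- query$positions[, "J8", "z"]
  rz <- reference$positions[, "J8", "z"]
  # per query route frame: minimum coupled reference hip z
  nq <- qlim$end - qlim$start
  ref_min <- rep(Inf, nq)
  p <- coupling$pairs
  for (r in seq_len(nrow(p))) {
    j <- p[r, 2] + 1L
    zval <- rz[rlim$start + p[r, 1] + 1L]
    if (zval < ref_min[j]) ref_min[j] <- zval
  }
  if (any(!is.finite(ref_min)))
    ct_stop("internal_error", "DTW coupling does not cover every query frame")
  torso_q <- median(abs(query$positions[, "J8", "y"] -
                          (query$positions[, "J5", "y"] + query$positions[, "J2", "y"]) / 2))
  torso_r <- median(abs(reference$positions[, "J8", "y"] -
                          (reference$positions[, "J5", "y"] + reference$positions[, "J2", "y"]) / 2))
  if (abs(torso_q - torso_r) > 0.1 * torso_r)
    warning("query and reference torso lengths differ by >10%; the hip-distance threshold assumes climbers of similar size")
  out <- empty_events()
  for (i in which(phases$kind == "reaching")) {
    fr <- phase_frames(phases[i, ])
    fr <- fr[fr >= qlim$start & fr < qlim$end]
    if (length(fr) == 0) next
    diffz <- qz[fr + 1] - ref_min[fr - qlim$start + 1]
    out <- rbind(out, flag_events(fr, diffz >= config$k_dhip, "hip_close_to_wall",
                                  phases$id[i], config$min_event_frames))
  }
  out
}

#' Run every error detector and assemble the report
#'
#' @param seq wall-space [skeleton_sequence()] (full recording).
#' @param phases phase table from [segment_phases()].
#' @param motion key-joint motion list from [segment_key_joints()].
#' @param limits route limits from [delimit_route()].
#' @param config a [pipeline_config()].
#' @param reference optional wall-space reference sequence enabling the
#'   hip-close-to-the-wall rule; when absent that rule is reported as not
#'   evaluated.
#' @param coupling optional precomputed [align_climbs()] coupling.
#' @return An `error_report`: `events` (all detectors pooled), `per_phase`
#'   counts from [aggregate_per_phase()], `totals` per type, and
#'   `evaluated` flags per type.
#' @export
detect_errors <- function(seq, phases, motion, limits, config = pipeline_config(),
                          reference = NULL, coupling = NULL) {
  hands <- assign_hands(seq)
  events <- rbind(
    detect_decoupling(seq, phases, hands, config),
    detect_reaching_hand_supports(seq, phases, hands, motion, config),
    detect_weight_shift(seq, phases, hands, config),
    detect_both_feet_set(seq, phases, motion, config),
    detect_shoulder_relaxing(seq, phases, hands, config)
  )
  evaluated <- setNames(rep(TRUE, length(ERROR_TYPES)), ERROR_TYPES)
  if (!is.null(reference)) {
    if (is.null(coupling))
      coupling <- align_climbs(reference, seq, query_limits = limits)
    events <- rbind(events,
                    detect_hip_close_to_wall(seq, reference, coupling, phases, config))
  } else {
    evaluated["hip_close_to_wall"] <- FALSE
  }
  events <- events[order(events$start, events$type), , drop = FALSE]
  rownames(events) <- NULL
  agg <- aggregate_per_phase(events, phases)
  structure(list(events = events, per_phase = agg$per_phase,
                 totals = agg$totals, evaluated = evaluated,
                 limits = limits),
            class = "error_report")
}

#' Per-phase, per-type error aggregation
#'
#' Multiple events of one type inside one phase instance count as a single
#' error for that phase; the totals per type count the phases affected.
#'
#' @param events event data frame (pooled detectors).
#' @param phases phase table from [segment_phases()].
#' @return List with `per_phase` (one row per phase instance, one column
#'   per error type, values 0/1) and `totals` (named integer vector).
#' @export
aggregate_per_phase <- function(events, phases) {
  per_phase <- matrix(0L, nrow = nrow(phases), ncol = length(ERROR_TYPES),
                      dimnames = list(NULL, ERROR_TYPES))
  if (nrow(events) > 0) {
    for (r in seq_len(nrow(events))) {
      i <- match(events$phase_id[r], phases$id)
      per_phase[i, events$type[r]] <- 1L
    }
  }
  per_phase <- cbind(data.frame(phase_id = phases$id, kind = phases$kind),
                     as.data.frame(per_phase))
  totals <- vapply(ERROR_TYPES, function(tp) sum(per_phase[[tp]]), integer(1))
  list(per_phase = per_phase, totals = totals)
}

#' @export
print.error_report <- function(x, ...) {
  cat("<error_report>\n totals per type (phases affected):\n")
  for (tp in ERROR_TYPES) {
    note <- if (!x$evaluated[tp]) " (not evaluated)" else ""
    cat(sprintf("  %-24s %d%s\n", tp, x$totals[tp], note))
  }
  cat(sprintf(" %d event(s) in total\n", nrow(x$events)))
  invisible(x)
}
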