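# Independent oracles and fixture builders used across the suite.

# Exhaustive DTW: branch-and-bound over ALL legal couplings (feasible for
# series of length <= 6). Independent of the dynamic-programming path.
brute_dtw <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) { best <<- acc; return(invisible()) }
    if (i < n) rec(i + 1, j, acc)
    if (j < m) rec(i, j + 1, acc)
    if (i < n && j < m) rec(i + 1, j + 1, acc)
  }
  rec(1, 1, 0)
  best
}

# Bit-set IoU oracle: materialise the frame sets and count.
bitset_iou <- function(a, b) {
  fa <- seq(a$start, a$end - 1)
  fb <- seq(b$start, b$end - 1)
  length(intersect(fa, fb)) / length(union(fa, fb))
}

# Random rigid transform (rotation via QR of a Gaussian matrix + translation).
random_rigid <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 500))
}

# A wall-space sequence with every joint static at a plausible hanging pose,
# optionally modified per frame by `mutate(pos, frame)` (pos is 13 x 3 with
# dimnames; frame is 1-based).
static_pose <- function() {
  p <- rbind(
    J2 = c(1700, -2600, 260), J3 = c(1730, -2350, 170), J4 = c(1750, -2250, 80),
    J5 = c(1300, -2600, 260), J6 = c(1270, -2300, 170), J7 = c(1250, -2050, 80),
    J8 = c(1500, -3100, 250), J9 = c(1650, -3100, 250), J10 = c(1900, -3470, 150),
    J11 = c(1700, -3850, 40), J12 = c(1350, -3100, 250), J13 = c(1100, -3470, 150),
    J14 = c(1300, -3850, 40))
  colnames(p) <- c("x", "y", "z")
  p
}

make_seq <- function(n, mutate = NULL, fps = 60, space = "wall") {
  base <- static_pose()
  pos <- array(NA_real_, c(n, 13, 3), dimnames = list(NULL, rownames(base), colnames(base)))
  for (f in seq_len(n)) {
    p <- base
    if (!is.null(mutate)) p <- mutate(p, f)
    pos[f, , ] <- p
  }
  skeleton_sequence(pos, fps = fps, space = space)
}

# One scripted injection per error type, cycle 2 of a 3-cycle climb.
injection_scripts <- function(sigma = 0, spike_prob = 0, seed = 1) {
  types <- c("decoupling", "reaching_hand_supports", "weight_shift",
             "both_feet_set", "hip_close_to_wall", "shoulder_relaxing")
  lapply(seq_along(types), function(i)
    climb_script(errors = list(list(type = types[i], cycle = 2)),
                 jitter_sigma = sigma, spike_prob = spike_prob,
                 seed = seed + i))
}

iou_of <- function(det_row, lab_row) {
  interval_iou(list(start = det_row$start, end = det_row$end),
               list(start = lab_row$start, end = lab_row$end))
}

# Run the analysis on a generated climb, wiring up a clean reference twin
# when the script injects the hip rule.
analyse_generated <- function(g, config = pipeline_config(), ref_seed = 999) {
  needs_ref <- "hip_close_to_wall" %in% g$labels$type
  ref <- NULL
  if (needs_ref) {
    rsc <- g$script
    ref <- generate_climb(climb_script(cycles = rsc$cycles, wall = rsc$wall,
                                       lead_in = rsc$lead_in,
                                       prep_frames = rsc$prep_frames,
                                       reach_frames = rsc$reach_frames,
                                       hand_frames = rsc$hand_frames,
                                       stab_frames = rsc$stab_frames,
                                       fps = rsc$fps,
                                       jitter_sigma = rsc$jitter_sigma,
                                       spike_prob = rsc$spike_prob,
                                       seed = ref_seed),
                          space = "wall")$sequence
  }
  run_pipeline(g$sequence, wall = g$wall, reference = ref, config = config)
}
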