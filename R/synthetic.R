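# Scripted synthetic climbing sequences with exact ground truth. The rig
# animates the 13 joints through preparation / reaching / stabilization
# cycles (feet set -> one hand + hip rise -> all static with the new holding
# arm stretched), optionally violating exactly one technique rule inside a
# known window per injected error, and adds Gaussian keypoint jitter plus
# occasional short spike artifacts. Joint positions are scripted directly
# (bone lengths are approximately, not exactly, constant), which is all the
# rule-based pipeline observes.

SYN_ERROR_PARAMS <- list(
  decoupling = list(phi = 110),              # bent holding arm in preparation
  shoulder_relaxing = list(phi = 110),       # arm stays locked after the grip
  reaching_hand_supports = list(len = 70, radius = 100, loops = 2),
  weight_shift = list(knee_pass = 100),      # knee stalls behind the foot
  both_feet_set = list(foot_z = 300),        # one foot dangles off the wall
  hip_close_to_wall = list(hip_dz = 100)     # hips sag away from the wall
)

#' Build a synthetic climb script
#'
#' Defines the study conditions of one scripted climb: wall geometry, cycle
#' structure (frames), injected errors, and noise. Defaults describe a
#' three-cycle novice boulder at 60 fps: 40-frame foot placements, a
#' 36-frame hand reach (peak speed about 1.5 m/s) inside a 55-frame hip
#' rise, and 120-frame stabilizations.
#'
#' @param cycles number of climbing cycles.
#' @param wall list with `width`, `height` (mm), `tilt_deg`, `distance`
#'   (camera-to-wall, mm).
#' @param lead_in frames of initial static hang.
#' @param prep_frames foot-placement (preparation) duration.
#' @param reach_frames hip-rise (reaching) duration.
#' @param hand_frames hand-reach duration inside the reach window.
#' @param stab_frames stabilization duration.
#' @param fps frames per second.
#' @param jitter_sigma per-coordinate Gaussian keypoint noise, mm.
#' @param spike_prob per-frame probability of starting a 5-frame, 60 mm
#'   spike artifact on a random joint (isolated; at least 60 frames apart).
#' @param errors list of injections, each `list(type =, cycle =)` with
#'   `type` one of the six error types and `cycle` in `1..cycles`.
#' @param seed integer seed (geometry is noise-free and seed-independent;
#'   the seed drives jitter and spikes only).
#' @return A validated `climb_script` list.
#' @export
climb_script <- function(cycles = 3,
                         wall = list(width = 3000, height = 4000,
                                     tilt_deg = 8, distance = 2800),
                         lead_in = 90, prep_frames = 40, reach_frames = 55,
                         hand_frames = 36, stab_frames = 120, fps = 60,
                         jitter_sigma = 0, spike_prob = 0,
                         errors = list(), seed = 1) {
  stopifnot(cycles >= 1, lead_in >= 0, prep_frames >= 1, reach_frames >= 1,
            hand_frames >= 1, hand_frames <= reach_frames, stab_frames >= 1,
            fps > 0, jitter_sigma >= 0, spike_prob >= 0)
  for (e in errors) {
    if (!e$type %in% ERROR_TYPES)
      ct_stop("script_error", "unknown error type '%s'", e$type)
    if (is.null(e$cycle) || e$cycle < 1 || e$cycle > cycles)
      ct_stop("script_error", "error cycle out of range for type '%s'", e$type)
  }
  structure(list(cycles = cycles, wall = wall, lead_in = lead_in,
                 prep_frames = prep_frames, reach_frames = reach_frames,
                 hand_frames = hand_frames, stab_frames = stab_frames,
                 fps = fps, jitter_sigma = jitter_sigma,
                 spike_prob = spike_prob, errors = errors, seed = seed),
            class = "climb_script")
}

smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  3 * u^2 - 2 * u^3
}

# Cumulative displacement profile: 0 before f0, smoothstep ramp to delta
# over [f0, f1), delta afterwards. Frames 0-based, n total.
move_profile <- function(n, f0, f1, delta) {
  f <- 0:(n - 1)
  delta * smoothstep((f - f0) / (f1 - f0))
}

# Edge-ramped window profile: 0 outside [f0, f1), ramping over `edge`
# frames inside both ends.
window_profile <- function(n, f0, f1, edge = 5) {
  f <- 0:(n - 1)
  inside <- f >= f0 & f < f1
  r <- pmin(1, (f - f0) / edge, (f1 - 1 - f) / edge)
  ifelse(inside, pmax(0, r), 0)
}

# The ground-truth wall model of a scripted climb in camera coordinates
# (y-up right-handed camera looking along +z; the wall leans back by tilt).
scripted_wall_model <- function(wall) {
  tau <- wall$tilt_deg * pi / 180
  y_w <- c(0, cos(tau), sin(tau))
  n <- c(0, sin(tau), -cos(tau)) # toward the camera
  x_w <- cross3(y_w, n)
  # horizontally centred in front of the camera, top edge above the optical
  # axis; x_w happens to be (-1, 0, 0) in this configuration
  ul <- -x_w * wall$width / 2 + c(0, wall$height * 0.45, wall$distance)
  corners <- rbind(ul,
                   ul + x_w * wall$width,
                   ul + x_w * wall$width - y_w * wall$height,
                   ul - y_w * wall$height)
  colnames(corners) <- c("x", "y", "z")
  wall_model_from_corners(corners, n)
}

#' Generate a scripted synthetic climb
#'
#' Animates a clean climb satisfying every technique rule with margin
#' (holding arm at 172 deg, supporting-hand motion about 0.4 s, knee passed
#' 300 mm in front of the foot, feet within 90 mm of the wall, hips at a
#' constant wall distance), then applies the script's injections, each
#' violating exactly one rule inside a recorded window, and finally adds
#' jitter and spike noise. Geometry is identical across seeds; only the
#' noise differs.
#'
#' @param script a [climb_script()].
#' @param space `"camera"` (default; the ground-truth wall model transform
#'   is applied, as recorded data would arrive) or `"wall"`.
#' @return List: `sequence` (a [skeleton_sequence()]), `wall` (ground-truth
#'   `wall_model`), `phases_gt` (data frame `kind`, `start`, `end` tiling
#'   the recording), `labels` (ground-truth error intervals), `script`.
#' @export
generate_climb <- function(script, space = c("camera", "wall")) {
  stopifnot(inherits(script, "climb_script"))
  space <- match.arg(space)
  P <- script$prep_frames; R <- script$reach_frames; S <- script$stab_frames
  H <- script$hand_frames
  err_of <- function(cyc) Filter(function(e) e$cycle == cyc, script$errors)
  has_err <- function(cyc, type)
    any(vapply(err_of(cyc), function(e) e$type == type, TRUE))
  # per-cycle reach window lengths (a supporting-hand wiggle prolongs the
  # hand-motion window beyond the hip rise)
  wig <- SYN_ERROR_PARAMS$reaching_hand_supports
  reach_len <- vapply(seq_len(script$cycles), function(c)
    if (has_err(c, "reaching_hand_supports")) max(R, 5 + wig$len) else R, 0)
  cyc_len <- P + reach_len + S
  n <- script$lead_in + sum(cyc_len)
  cyc_start <- script$lead_in + cumsum(c(0, head(cyc_len, -1)))

  wallw <- script$wall$width
  cx <- wallw / 2
  y0 <- -script$wall$height + 900 # hip start height above the mat
  hip_step <- 300; hand_step <- 600; lat_step <- 120; foot_lat <- 250

  zero <- rep(0, n)
  hip_x <- zero + cx; hip_y <- zero + y0; hip_z <- zero + 250
  wx <- list(J7 = zero + cx - 250, J4 = zero + cx + 250)
  wy <- list(J7 = zero + y0 + 1050, J4 = zero + y0 + 750) # left holds first
  wz <- list(J7 = zero + 80, J4 = zero + 80)
  ax <- list(J14 = zero + cx - 200, J11 = zero + cx + 200)
  ay <- list(J14 = zero + y0 - 750, J11 = zero + y0 - 750)
  az <- list(J14 = zero + 40, J11 = zero + 40)
  knee_dx <- zero
  phi_high <- zero + 172; phi_low <- zero + 150

  phases_gt <- data.frame(kind = "stabilization", start = 0L,
                          end = as.integer(script$lead_in))
  labels <- data.frame(type = character(0), start = integer(0), end = integer(0))
  add_label <- function(labels, type, f0, f1)
    rbind(labels, data.frame(type = type, start = as.integer(f0), end = as.integer(f1)))

  cur_knee <- 0
  for (c in seq_len(script$cycles)) {
    a <- cyc_start[c]; b <- a + P
    rl <- reach_len[c]
    reach_hand <- if (c %% 2 == 1) "J4" else "J7" # right reaches first
    dir <- if (reach_hand == "J4") 1 else -1
    # preparation: both feet step up and across, with a small lift
    for (j in c("J14", "J11")) {
      ax[[j]] <- ax[[j]] + move_profile(n, a, b, dir * foot_lat)
      ay[[j]] <- ay[[j]] + move_profile(n, a, b, hip_step)
      az[[j]] <- az[[j]] + 50 * window_profile(n, a, b, edge = P / 2)
    }
    # knees settle in front of the feet toward the travel direction
    pass <- if (has_err(c, "weight_shift")) SYN_ERROR_PARAMS$weight_shift$knee_pass else 300
    knee_dx <- knee_dx + move_profile(n, a, b, dir * pass - cur_knee)
    cur_knee <- dir * pass
    # reaching: the lower hand reaches past the other, the hips follow
    wx[[reach_hand]] <- wx[[reach_hand]] + move_profile(n, b, b + H, dir * 150)
    wy[[reach_hand]] <- wy[[reach_hand]] + move_profile(n, b, b + H, hand_step)
    hip_x <- hip_x + move_profile(n, b + 8, b + R, dir * lat_step)
    hip_y <- hip_y + move_profile(n, b + 8, b + R, hip_step)
    # injections -------------------------------------------------------
    if (has_err(c, "decoupling")) {
      phi_high[(a + 1):b] <- SYN_ERROR_PARAMS$decoupling$phi
      labels <- add_label(labels, "decoupling", a, b)
    }
    if (has_err(c, "shoulder_relaxing")) {
      s0 <- b + rl; s1 <- s0 + S
      phi_high[(s0 + 1):s1] <- SYN_ERROR_PARAMS$shoulder_relaxing$phi
      labels <- add_label(labels, "shoulder_relaxing", s0, s1)
    }
    if (has_err(c, "reaching_hand_supports")) {
      # the old holding hand (static, soon the supporting hand) circles its
      # hold at near-constant speed instead of gripping
      still <- setdiff(c("J7", "J4"), reach_hand)
      f0 <- b + 5; f1 <- f0 + wig$len
      tt <- pmin(pmax((0:(n - 1)) - f0, 0), wig$len)
      th <- 2 * pi * wig$loops * tt / wig$len
      inside <- (0:(n - 1)) >= f0 & (0:(n - 1)) < f1
      wx[[still]] <- wx[[still]] + ifelse(inside, wig$radius * (1 - cos(th)), 0)
      wy[[still]] <- wy[[still]] + ifelse(inside, wig$radius * sin(th), 0)
      labels <- add_label(labels, "reaching_hand_supports", f0, f1)
    }
    if (has_err(c, "weight_shift"))
      labels <- add_label(labels, "weight_shift",
                          b + floor(rl / 4), b + floor(3 * rl / 4))
    if (has_err(c, "both_feet_set")) {
      az$J14 <- az$J14 + SYN_ERROR_PARAMS$both_feet_set$foot_z *
        window_profile(n, b, b + rl)
      labels <- add_label(labels, "both_feet_set", b, b + rl)
    }
    if (has_err(c, "hip_close_to_wall")) {
      hip_z <- hip_z + SYN_ERROR_PARAMS$hip_close_to_wall$hip_dz *
        window_profile(n, b, b + rl)
      labels <- add_label(labels, "hip_close_to_wall", b, b + rl)
    }
    phases_gt <- rbind(phases_gt,
                       data.frame(kind = c("preparation", "reaching", "stabilization"),
                                  start = as.integer(c(a, b, b + rl)),
                                  end = as.integer(c(b, b + rl, b + rl + S))))
  }

  pos <- array(NA_real_, c(n, 13, 3), dimnames = list(NULL, JOINT_IDS, c("x", "y", "z")))
  pos[, "J8", ] <- cbind(hip_x, hip_y, hip_z)
  pos[, "J12", ] <- cbind(hip_x - 150, hip_y, hip_z)
  pos[, "J9", ] <- cbind(hip_x + 150, hip_y, hip_z)
  pos[, "J5", ] <- cbind(hip_x - 200, hip_y + 500, hip_z + 10)
  pos[, "J2", ] <- cbind(hip_x + 200, hip_y + 500, hip_z + 10)
  pos[, "J7", ] <- cbind(wx$J7, wy$J7, wz$J7)
  pos[, "J4", ] <- cbind(wx$J4, wy$J4, wz$J4)
  pos[, "J14", ] <- cbind(ax$J14, ay$J14, az$J14)
  pos[, "J11", ] <- cbind(ax$J11, ay$J11, az$J11)
  pos[, "J13", ] <- cbind(ax$J14 + knee_dx, ay$J14 + 380, az$J14 + 110)
  pos[, "J10", ] <- cbind(ax$J11 + knee_dx, ay$J11 + 380, az$J11 + 110)
  # elbows from the per-frame desired interior angle of each arm
  left_high <- wy$J7 >= wy$J4
  for (side in c("left", "right")) {
    wrist <- if (side == "left") "J7" else "J4"
    shoulder <- if (side == "left") "J5" else "J2"
    elbow <- if (side == "left") "J6" else "J3"
    phi <- if (side == "left") ifelse(left_high, phi_high, phi_low)
           else ifelse(left_high, phi_low, phi_high)
    Sm <- pos[, shoulder, ]; Wm <- pos[, wrist, ]
    U <- Wm - Sm
    d <- sqrt(rowSums(U^2))
    h <- (d / 2) / tan(phi / 2 * pi / 180)
    side_sign <- if (side == "left") -1 else 1
    refv <- cbind(rep(side_sign, n), 0, 0.6)
    Un <- U / d
    B <- refv - Un * rowSums(refv * Un)
    B <- B / sqrt(rowSums(B^2))
    pos[, elbow, ] <- (Sm + Wm) / 2 + B * h
  }

  with_local_seed(script$seed, {
    if (script$jitter_sigma > 0)
      pos <- pos + array(rnorm(length(pos), 0, script$jitter_sigma), dim(pos))
    if (script$spike_prob > 0) {
      f <- 0L
      while (f < n - 5L) {
        if (runif(1) < script$spike_prob * 60) { # thinned to isolated spikes
          j <- sample(JOINT_IDS, 1)
          off <- rnorm(3)
          off <- off / vec_norm(off) * 60
          idx <- (f + 1):(f + 5)
          for (k in 1:3) pos[idx, j, k] <- pos[idx, j, k] + off[k]
          f <- f + 65L
        } else f <- f + 60L
      }
    }
  })

  seq_wall <- skeleton_sequence(pos, fps = script$fps, space = "wall")
  wall <- scripted_wall_model(script$wall)
  seq_out <- if (space == "camera") to_camera_coords(seq_wall, wall) else seq_wall
  list(sequence = seq_out, wall = wall, phases_gt = phases_gt,
       labels = labels, script = script)
}

#' Generate a synthetic wall calibration cloud
#'
#' Samples the wall rectangle on a regular lattice (as the sensor's
#' reticular depth grid does), displaces each sample along the wall normal
#' by Gaussian noise, and adds clutter points floating in front of the wall
#' (holds, climber) as outliers.
#'
#' @param wall wall spec list (`width`, `height`, `tilt_deg`, `distance`).
#' @param n_points approximate number of lattice samples (>= 100).
#' @param noise_sigma normal-direction noise, mm.
#' @param outlier_fraction clutter points as a fraction of `n_points`.
#' @param seed integer seed.
#' @return List: `points` (camera-frame cloud), `wall` (ground-truth
#'   `wall_model`).
#' @export
generate_wall_cloud <- function(wall, n_points = 2000, noise_sigma = 0,
                                outlier_fraction = 0, seed = 1) {
  stopifnot(n_points >= 100)
  gt <- scripted_wall_model(wall)
  aspect <- wall$width / wall$height
  nc <- max(2, round(sqrt(n_points * aspect)))
  nr <- max(2, ceiling(n_points / nc))
  u <- seq(0, wall$width, length.out = nc)
  v <- seq(0, wall$height, length.out = nr)
  gridp <- expand.grid(u = u, v = v)
  x_w <- gt$rotation[1, ]; y_w <- gt$rotation[2, ]; nrm <- gt$rotation[3, ]
  base <- t(vapply(seq_len(nrow(gridp)),
                   function(i) gt$origin + x_w * gridp$u[i] - y_w * gridp$v[i],
                   numeric(3)))
  pts <- with_local_seed(seed, {
    if (noise_sigma > 0)
      base <- base + outer(rnorm(nrow(base), 0, noise_sigma), nrm)
    n_out <- round(outlier_fraction * nrow(base))
    if (n_out > 0) {
      ou <- runif(n_out, 0.1 * wall$width, 0.9 * wall$width)
      ov <- runif(n_out, 0.1 * wall$height, 0.9 * wall$height)
      oz <- runif(n_out, 120, 900)
      out <- t(vapply(seq_len(n_out),
                      function(i) gt$origin + x_w * ou[i] - y_w * ov[i] + nrm * oz[i],
                      numeric(3)))
      base <- rbind(base, out)
    }
    base
  })
  colnames(pts) <- c("x", "y", "z")
  list(points = pts, wall = gt)
}
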