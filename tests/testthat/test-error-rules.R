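# Direct unit tests drive each detector with hand-built phases and motion
# tables; integration tests use scripted injections with exact windows.

fake_motion <- function(...) {
  # named lists of interval data frames for J7/J4/J14/J11/J8y
  given <- list(...)
  out <- list()
  for (j in c("J7", "J4", "J14", "J11", "J8y")) {
    iv <- given[[j]] %||% data.frame(start = integer(0), end = integer(0))
    out[[j]] <- structure(list(intervals = iv, joint = j, axis = "xy", min_len = 30),
                          class = "motion_intervals")
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

phase_tab <- function(kinds, bounds) {
  data.frame(id = seq_along(kinds), kind = kinds,
             start = bounds[-length(bounds)], end = bounds[-1])
}

# Arm poses: holding arm (left, J7 higher) straight or bent at the elbow.
arm_seq <- function(n, phi_deg) {
  make_seq(n, mutate = function(p, f) {
    p["J7", ] <- c(1300, -2050, 80)  # left wrist high -> holding
    p["J4", ] <- c(1750, -2500, 80)
    p["J5", ] <- c(1300, -2600, 260)
    # elbow on the shoulder-wrist bisector at the angle phi
    s <- p["J5", ]; w <- p["J7", ]
    d <- sqrt(sum((w - s)^2))
    h <- (d / 2) / tan(phi_deg / 2 * pi / 180)
    u <- (w - s) / d
    b <- c(-1, 0, 0.4); b <- b - sum(b * u) * u; b <- b / sqrt(sum(b^2))
    p["J6", ] <- (s + w) / 2 + h * b
    p
  })
}

test_that("decoupling fires on a bent holding arm only inside preparation", {
  cfg <- pipeline_config()
  phases <- phase_tab(c("stabilization", "preparation", "reaching"), c(0, 60, 160, 220))

  straight <- arm_seq(220, 176)
  hands <- assign_hands(straight)
  expect_equal(nrow(detect_decoupling(straight, phases, hands, cfg)), 0)

  bent <- arm_seq(220, 120) # below the 130 deg elbow threshold
  hands_b <- assign_hands(bent)
  ev <- detect_decoupling(bent, phases, hands_b, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start, ev$end), c(60, 160)) # clipped to preparation
  expect_equal(ev$phase_id, 2)

  # same arm during reaching only: gated out
  phases_r <- phase_tab(c("reaching"), c(0, 220))
  expect_equal(nrow(detect_decoupling(bent, phases_r, hands_b, cfg)), 0)
})

test_that("shoulder relaxing is the same angle rule gated to stabilization", {
  cfg <- pipeline_config()
  phases <- phase_tab(c("reaching", "stabilization"), c(0, 100, 260))
  bent <- arm_seq(260, 100)
  hands <- assign_hands(bent)
  ev <- detect_shoulder_relaxing(bent, phases, hands, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start, ev$end), c(100, 260))
  expect_equal(nrow(detect_decoupling(bent, phases, hands, cfg)), 0)
})

test_that("short angle dips are suppressed by the minimum event length", {
  cfg <- pipeline_config()
  phases <- phase_tab("preparation", c(0, 100))
  n <- 100
  seqs <- make_seq(n, mutate = function(p, f) {
    p["J7", "y"] <- p["J4", "y"] + 300
    p
  })
  hands <- assign_hands(seqs)
  # fabricate a 3-frame dip by bending the elbow directly
  pos <- seqs$positions
  bent <- arm_seq(n, 100)$positions
  pos[50:52, , ] <- bent[50:52, , ]
  seq_dip <- skeleton_sequence(pos, fps = 60, space = "wall")
  ev <- detect_decoupling(seq_dip, phases, assign_hands(seq_dip), cfg)
  expect_equal(nrow(ev), 0)
})

test_that("reaching hand supports needs more than Kt seconds of supporting-hand motion", {
  cfg <- pipeline_config()
  phases <- phase_tab("reaching", c(0, 120))
  seq <- make_seq(120) # static pose: J4 lower -> supporting
  hands <- assign_hands(seq)

  m70 <- fake_motion(J4 = data.frame(start = 20, end = 90)) # 70 f = 1.17 s
  ev <- detect_reaching_hand_supports(seq, phases, hands, m70, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start, ev$end), c(20, 90))

  m30 <- fake_motion(J4 = data.frame(start = 20, end = 50)) # 0.5 s
  expect_equal(nrow(detect_reaching_hand_supports(seq, phases, hands, m30, cfg)), 0)

  # the holding hand moving does not count
  mh <- fake_motion(J7 = data.frame(start = 10, end = 110))
  expect_equal(nrow(detect_reaching_hand_supports(seq, phases, hands, mh, cfg)), 0)
})

test_that("weight shift checks the knee pass in the two central quartets only", {
  cfg <- pipeline_config()
  phases <- phase_tab("reaching", c(0, 120))
  # static pose has J4 lower (supporting) -> right leg J10/J11; hip travel 0
  # means positive x direction; knee_dx parameterises the pass distance
  knee_seq <- function(dx) make_seq(120, mutate = function(p, f) {
    p["J10", "x"] <- p["J11", "x"] + dx
    p
  })
  hands <- assign_hands(knee_seq(250))
  expect_equal(nrow(detect_weight_shift(knee_seq(250), phases, hands, cfg)), 0)

  ev <- detect_weight_shift(knee_seq(150), phases, hands, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start, ev$end), c(30, 90)) # the middle half

  # below threshold only in the first quartet: window rule keeps it clean
  seq_q1 <- make_seq(120, mutate = function(p, f) {
    p["J10", "x"] <- p["J11", "x"] + if (f <= 30) 150 else 250
    p
  })
  expect_equal(nrow(detect_weight_shift(seq_q1, phases, assign_hands(seq_q1), cfg)), 0)
})

test_that("both feet set flags dangling or moving feet during reaching", {
  cfg <- pipeline_config()
  phases <- phase_tab("reaching", c(0, 100))
  seq_on <- make_seq(100, mutate = function(p, f) {
    p["J14", "z"] <- 60; p["J11", "z"] <- 60; p
  })
  m0 <- fake_motion()
  expect_equal(nrow(detect_both_feet_set(seq_on, phases, m0, cfg)), 0)

  seq_dangle <- make_seq(100, mutate = function(p, f) {
    p["J14", "z"] <- 300; p
  })
  ev <- detect_both_feet_set(seq_dangle, phases, m0, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start, ev$end), c(0, 100))

  mfoot <- fake_motion(J11 = data.frame(start = 30, end = 70))
  ev2 <- detect_both_feet_set(seq_on, phases, mfoot, cfg)
  expect_equal(c(ev2$start, ev2$end), c(30, 70))
})

test_that("hip close to wall compares one-sidedly against the coupled reference", {
  cfg <- pipeline_config()
  n <- 120
  whole <- list(start = 0L, end = as.integer(n))
  phases <- phase_tab("reaching", c(0, n))
  ref <- make_seq(n, mutate = function(p, f) {
    p["J8", ] <- c(1000 + 5 * f, -3000, 250); p
  })
  shift_z <- function(dz) make_seq(n, mutate = function(p, f) {
    p["J8", ] <- c(1000 + 5 * f, -3000, 250 + dz); p
  })
  run_hip <- function(q) {
    cp <- align_climbs(ref, q, whole, whole)
    detect_hip_close_to_wall(q, ref, cp, phases, cfg)
  }
  ev <- run_hip(shift_z(60)) # 60 mm further out than the reference
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start, ev$end), c(0, n))
  expect_equal(nrow(run_hip(shift_z(0))), 0)
  expect_equal(nrow(run_hip(shift_z(-100))), 0) # closer is never an error
})

test_that("per-phase aggregation counts each type at most once per phase", {
  phases <- phase_tab(c("preparation", "reaching", "preparation"), c(0, 50, 100, 150))
  ev <- data.frame(type = rep("decoupling", 3),
                   start = c(5, 20, 40), end = c(10, 30, 45), phase_id = 1)
  agg <- aggregate_per_phase(ev, phases)
  expect_equal(agg$totals[["decoupling"]], 1)

  ev2 <- rbind(ev, data.frame(type = "decoupling", start = 110, end = 120, phase_id = 3))
  expect_equal(aggregate_per_phase(ev2, phases)$totals[["decoupling"]], 2)

  agg0 <- aggregate_per_phase(climbtech:::empty_events(), phases)
  expect_true(all(agg0$totals == 0))
})

test_that("noiseless clean climbs yield zero events of all six types", {
  for (seed in 1:3) {
    g <- generate_climb(climb_script(seed = seed), space = "wall")
    gref <- generate_climb(climb_script(seed = seed + 100), space = "wall")
    res <- run_pipeline(g$sequence, reference = gref$sequence)
    expect_equal(nrow(res$report$events), 0)
    expect_true(all(res$report$totals == 0))
    expect_true(all(res$report$evaluated))
  }
})

test_that("each injected error is recovered (IoU >= 0.5) with a diagonal cross-talk matrix", {
  scripts <- injection_scripts(sigma = 0, seed = 50)
  for (sc in scripts) {
    inj_type <- sc$errors[[1]]$type
    g <- generate_climb(sc, space = "wall")
    res <- analyse_generated(g)
    ev <- res$report$events
    # only the injected type fires
    expect_equal(unique(ev$type), inj_type)
    det <- ev[ev$type == inj_type, , drop = FALSE]
    expect_gte(nrow(det), 1)
    best <- max(vapply(seq_len(nrow(det)), function(i)
      iou_of(det[i, ], g$labels[1, ]), 0))
    expect_gte(best, 0.5)
  }
})

test_that("events always respect their phase gates", {
  gates <- c(decoupling = "preparation", shoulder_relaxing = "stabilization",
             reaching_hand_supports = "reaching", weight_shift = "reaching",
             both_feet_set = "reaching", hip_close_to_wall = "reaching")
  for (sc in injection_scripts(sigma = 5, seed = 70)) {
    g <- generate_climb(sc, space = "wall")
    res <- analyse_generated(g)
    ev <- res$report$events
    if (nrow(ev) == 0) next
    ph <- res$phases
    for (r in seq_len(nrow(ev))) {
      inst <- ph[match(ev$phase_id[r], ph$id), ]
      expect_equal(inst$kind, unname(gates[ev$type[r]]))
      expect_gte(ev$start[r], inst$start)
      expect_lte(ev$end[r], inst$end)
    }
  }
})

test_that("an absent reference marks the hip rule as not evaluated", {
  g <- generate_climb(climb_script(seed = 81), space = "wall")
  res <- run_pipeline(g$sequence)
  expect_false(res$report$evaluated[["hip_close_to_wall"]])
  expect_true(all(res$report$evaluated[setdiff(names(res$report$evaluated),
                                               "hip_close_to_wall")]))
})
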