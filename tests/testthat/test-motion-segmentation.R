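test_that("joint_speed projects, differentiates and smooths as specified", {
  seq_static <- make_seq(100)
  expect_true(all(joint_speed(seq_static, "J8", "xy")$values == 0))

  # constant 10 mm/frame in x at 60 fps -> 600 mm/s everywhere
  seq_move <- make_seq(100, mutate = function(p, f) { p["J8", "x"] <- p["J8", "x"] + 10 * f; p })
  expect_equal(joint_speed(seq_move, "J8", "xy")$values, rep(600, 100))

  # pure z motion is invisible in the x-y projection
  seq_z <- make_seq(100, mutate = function(p, f) { p["J8", "z"] <- p["J8", "z"] + 15 * f; p })
  expect_true(all(joint_speed(seq_z, "J8", "xy")$values == 0))
  expect_equal(joint_speed(seq_z, "J8", "z")$values, rep(900, 100))

  expect_error(joint_speed(make_seq(2), "J8"), class = "too_short")
  expect_error(joint_speed(make_seq(10, space = "camera"), "J8"), class = "space_error")
})

test_that("zscore_series is the population standard score", {
  expect_equal(zscore_series(c(0, 0, 10, 10)), c(-1, -1, 1, 1))
  expect_error(zscore_series(rep(3, 50)), class = "constant_signal")
  set.seed(9)
  for (k in 1:20) {
    v <- runif(sample(10:200, 1), 0, 1000)
    z <- zscore_series(v)
    expect_lt(abs(mean(z)), 1e-9)
    expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  }
})

test_that("segment_motion recovers a rectangular pulse within half a window", {
  v <- rep(0, 600)
  v[200:259] <- 800 # frames [199, 259)
  mi <- segment_motion(v, n = 2, window = 15, rho = 0.5, min_len = 30)
  expect_equal(nrow(mi$intervals), 1)
  expect_lte(abs(mi$intervals$start - 199), 8)
  expect_lte(abs(mi$intervals$end - 259), 8)
})

test_that("short spikes and short pulses are discarded by the K-mu rule", {
  # isolated 5-frame spikes on an otherwise static joint: zero intervals
  v <- rep(0, 600)
  for (s in c(100, 250, 400)) v[s:(s + 4)] <- 900
  expect_equal(nrow(segment_motion(v)$intervals), 0)

  # two 10-frame pulses, each below the 30-frame minimum movement: none kept
  v2 <- rep(0, 600)
  v2[100:109] <- 800
  v2[300:309] <- 800
  expect_equal(nrow(segment_motion(v2)$intervals), 0)

  expect_equal(nrow(segment_motion(rep(0, 300))$intervals), 0)
  expect_equal(nrow(segment_motion(rep(5, 300))$intervals), 0) # constant speed
})

test_that("segment_motion output intervals are disjoint, sorted and >= min_len", {
  set.seed(13)
  for (k in 1:20) {
    v <- pmax(0, rnorm(500, 0, 30))
    n_pulse <- sample(1:4, 1)
    for (p in seq_len(n_pulse)) {
      s <- sample(1:400, 1)
      v[s:min(500, s + sample(20:80, 1))] <- runif(1, 500, 1200)
    }
    iv <- suppressWarnings(segment_motion(v))$intervals
    if (nrow(iv) > 1) {
      expect_true(all(diff(iv$start) > 0))
      expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
    }
    if (nrow(iv) > 0) expect_true(all(iv$end - iv$start >= 30))
  }
})

test_that("route delimitation finds the lowest hip and the last wrist peak", {
  # monotone climb: hip rises, wrists peak at the last frame
  seq_up <- make_seq(200, mutate = function(p, f) {
    p[, "y"] <- p[, "y"] + 4 * f
    p
  })
  lim <- delimit_route(seq_up)
  expect_equal(lim$start, 0)
  expect_equal(lim$end, 199)

  # hip dips at frame 30; wrist max attained at frames 400 and 410:
  # the last frame at the maximum wins
  n <- 500
  hip_y <- c(seq(0, -60, length.out = 31), seq(-58, 900, length.out = n - 31))
  wr <- rep(0, n)
  wr[1:411] <- seq(0, 800, length.out = 411)
  wr[401:411] <- 800
  wr[412:n] <- 700
  seq_dip <- make_seq(n, mutate = function(p, f) {
    p["J8", "y"] <- p["J8", "y"] + hip_y[f]
    p["J7", "y"] <- p["J7", "y"] + wr[f]
    p["J4", "y"] <- p["J4", "y"] + wr[f] - 50
    p
  })
  lim2 <- delimit_route(seq_dip)
  expect_equal(lim2$start, 30)
  expect_equal(lim2$end, 410)

  expect_error(delimit_route(make_seq(100)), class = "delimitation_error")
})

test_that("scripted key-joint motion is recovered with high interval IoU", {
  for (sigma in c(0, 5)) {
    g <- generate_climb(climb_script(jitter_sigma = sigma, seed = 23), space = "wall")
    motion <- segment_key_joints(g$sequence)
    prep <- g$phases_gt[g$phases_gt$kind == "preparation", ]
    # each preparation window is a scripted foot-motion window
    for (j in c("J14", "J11")) {
      iv <- motion[[j]]$intervals
      expect_equal(nrow(iv), nrow(prep))
      for (r in seq_len(nrow(prep))) {
        iou <- max(vapply(seq_len(nrow(iv)), function(i)
          bitset_iou(iv[i, ], prep[r, ]), 0))
        expect_gte(iou, if (sigma == 0) 0.8 else 0.7)
      }
    }
  }
})
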