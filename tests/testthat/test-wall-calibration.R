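test_that("rotation_from_normal reproduces the closed-form matrices", {
  # n = z: the formula gives diag(-1,-1,1), which still maps z to z
  expect_equal(rotation_from_normal(c(0, 0, 1)), diag(c(-1, -1, 1)))
  # hand-evaluated case for n = x
  expect_equal(rotation_from_normal(c(1, 0, 0)),
               matrix(c(0, 0, 1, 0, -1, 0, 1, 0, 0), 3, byrow = TRUE))
  expect_error(rotation_from_normal(c(0, 0, -1)), class = "singular_configuration")
})

test_that("rotation_from_normal satisfies the rotation identities for random normals", {
  set.seed(5)
  for (k in 1:200) {
    n <- rnorm(3)
    n <- n / sqrt(sum(n^2))
    if (n[3] < -0.999) n <- -n
    R <- rotation_from_normal(n)
    expect_lt(max(abs(R %*% c(0, 0, 1) - n)), 1e-12)
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("RANSAC recovers a noiseless plane and shrugs off outliers", {
  set.seed(31)
  pts <- cbind(runif(500, -1000, 1000), runif(500, -1000, 1000), 2000)
  fit <- fit_wall_plane(pts, seed = 1)
  expect_equal(as.numeric(abs(fit$normal)), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fit$normal[3], -1) # oriented toward the camera origin
  expect_equal(fit$offset, 2000, tolerance = 1e-9)
  expect_true(all(fit$inliers))

  out <- cbind(runif(50, -1000, 1000), runif(50, -1000, 1000), runif(50, 100, 1800))
  fit2 <- fit_wall_plane(rbind(pts, out), seed = 2)
  expect_equal(fit2$normal[3], -1, tolerance = 1e-6)
  expect_gte(sum(fit2$inliers), 500)

  expect_error(fit_wall_plane(pts[1:2, ]), class = "fit_failure")
})

test_that("RANSAC is deterministic given the seed", {
  set.seed(7)
  pts <- cbind(runif(300, 0, 2000), runif(300, 0, 2000),
               3000 + rnorm(300, 0, 8))
  f1 <- fit_wall_plane(pts, seed = 42)
  f2 <- fit_wall_plane(pts, seed = 42)
  expect_identical(f1, f2)
})

test_that("rectangle extraction recovers known corners, also in-plane rotated", {
  w <- list(width = 3000, height = 4000, tilt_deg = 10, distance = 2800)
  cl <- generate_wall_cloud(w, n_points = 2500, seed = 3)
  corners <- extract_wall_rectangle(cl$points, cl$wall$normal)
  expect_lt(max(sqrt(rowSums((corners - cl$wall$corners)^2))), 10)

  # rotating the cloud in-plane about the wall centre keeps the rectangle
  ctr <- colMeans(cl$wall$corners)
  n <- cl$wall$normal
  th <- 25 * pi / 180
  K <- matrix(c(0, -n[3], n[2], n[3], 0, -n[1], -n[2], n[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K # Rodrigues, axis n
  rot <- sweep(sweep(cl$points, 2, ctr) %*% t(R), 2, ctr, `+`)
  corners_rot <- extract_wall_rectangle(rot, n)
  gt_rot <- sweep(sweep(cl$wall$corners, 2, ctr) %*% t(R), 2, ctr, `+`)
  err <- apply(corners_rot, 1, function(p)
    min(sqrt(rowSums(sweep(gt_rot, 2, p)^2))))
  expect_lt(max(err), 10) # same corners up to ordering

  line <- cbind(seq(0, 1000, 10), seq(0, 2000, 20), 1500)
  expect_error(extract_wall_rectangle(line), class = "extraction_error")
})

test_that("to_wall_coords is rigid, maps the wall to z=0 and round-trips", {
  w <- list(width = 3000, height = 4000, tilt_deg = 12, distance = 2600)
  cl <- generate_wall_cloud(w, n_points = 1200, seed = 4)
  wall <- build_wall_model(cl$points, seed = 9)

  g <- generate_climb(climb_script(cycles = 1, seed = 2), space = "camera")
  seq_cam <- skeleton_sequence(g$sequence$positions[1:50, , , drop = FALSE],
                               fps = 60, space = "camera")
  seq_wall <- to_wall_coords(seq_cam, wall)
  expect_equal(seq_wall$space, "wall")

  # pairwise joint distances preserved to 1e-6 mm
  for (f in c(1, 25, 50)) {
    d0 <- dist(seq_cam$positions[f, , ])
    d1 <- dist(seq_wall$positions[f, , ])
    expect_lt(max(abs(d0 - d1)), 1e-6)
  }

  # the origin corner maps to (0,0,0); an on-plane point 1 m right of the
  # origin keeps |z| below the inlier tolerance
  o <- as.numeric(wall$rotation %*% wall$origin + wall$translation)
  expect_lt(max(abs(o)), 1e-6)
  p <- wall$origin + (wall$corners[2, ] - wall$corners[1, ]) / wall$width * 1000
  pw <- as.numeric(wall$rotation %*% p + wall$translation)
  expect_lt(abs(pw[3]), 20)
  expect_equal(pw[1], 1000, tolerance = 1)

  # exact round-trip through the inverse transform
  back <- climbtech:::to_camera_coords(seq_wall, wall)
  expect_lt(max(abs(back$positions - seq_cam$positions)), 1e-6)

  expect_warning(again <- to_wall_coords(seq_wall, wall), "already")
  expect_equal(again$positions, seq_wall$positions)
})

test_that("full calibration recovers a tilted wall within tight tolerances", {
  w <- list(width = 2800, height = 3600, tilt_deg = 9, distance = 3000)
  cl <- generate_wall_cloud(w, n_points = 2000, noise_sigma = 5,
                            outlier_fraction = 0.1, seed = 17)
  m <- build_wall_model(cl$points, seed = 18)
  ang <- acos(min(1, abs(sum(m$normal * cl$wall$normal)))) * 180 / pi
  expect_lt(ang, 0.5)
  expect_lt(max(sqrt(rowSums((m$corners - cl$wall$corners)^2))), 10)
  expect_lt(max(abs(t(m$rotation) %*% m$rotation - diag(3))), 1e-9)
  expect_equal(det(m$rotation), 1, tolerance = 1e-9)
})

test_that("wall model JSON and PLY round-trips preserve the calibration", {
  w <- list(width = 3000, height = 4000, tilt_deg = 6, distance = 2700)
  cl <- generate_wall_cloud(w, n_points = 600, seed = 5)
  f_ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(cl$points, f_ply)
  back <- read_ply(f_ply)
  expect_equal(dim(back), dim(cl$points))
  expect_lt(max(abs(back - cl$points)), 1e-4)

  m <- build_wall_model(cl$points, seed = 6)
  f_json <- withr::local_tempfile(fileext = ".json")
  write_wall_model(m, f_json)
  m2 <- read_wall_model(f_json)
  expect_equal(m2$rotation, m$rotation, tolerance = 1e-12)
  expect_equal(m2$translation, m$translation, tolerance = 1e-12)
  expect_equal(m2$corners, m$corners, tolerance = 1e-12, ignore_attr = TRUE)
})
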