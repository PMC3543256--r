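test_that("renderer places scene components at the stated intensities", {
  sc <- scene_params(noise_sigma = 0, pupil_center = c(320, 240),
                     pupil_radius_px = 40)
  fr <- render_eye_frame(sc)
  expect_equal(dim(fr$pixels), c(480, 640))
  expect_identical(fr$pixels[240, 320], 20)   # pupil centre
  expect_identical(fr$pixels[10, 10], 180)    # far background
  # iris annulus between pupil and background
  expect_identical(fr$pixels[240, 320 + 60], 90)
  # exactly three strict local maxima above (glint + iris)/2
  thr <- (sc$glint_level + sc$iris_level) / 2
  px <- fr$pixels
  h <- nrow(px); w <- ncol(px)
  core <- px[2:(h - 1), 2:(w - 1)]
  ismax <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ismax <- ismax & core > px[2:(h - 1) + dy, 2:(w - 1) + dx]
  }
  expect_identical(sum(ismax), 3L)
})

test_that("rendering is bit-identical under a fixed seed", {
  sc <- small_scene(noise_sigma = 5, seed = 42L)
  expect_identical(render_eye_frame(sc)$pixels, render_eye_frame(sc)$pixels)
  sc2 <- small_scene(noise_sigma = 5, seed = 43L)
  expect_false(identical(render_eye_frame(sc)$pixels,
                         render_eye_frame(sc2)$pixels))
})

test_that("scene invariants are enforced", {
  expect_error(scene_params(pupil_center = c(-5, 10)), "outside")
  expect_error(scene_params(glint_centers = rbind(c(10, 10), c(20, 10),
                                                  c(30, 10))), "collinear")
  expect_error(scene_params(pupil_level = 100, iris_level = 90))
})

test_that("feature simulator hits the rest configuration at screen centre", {
  sim <- sim_preset(1, feature_noise_sigma_px = 0)
  ctr <- c((default_screen$width_px - 1) / 2, (default_screen$height_px - 1) / 2)
  s <- simulate_gaze_features(ctr, sim, default_screen)
  expect_equal(unname(s$features[1:2]), sim$pupil_rest, tolerance = 1e-12)
  expect_equal(matrix(s$features[3:8], 3, 2, byrow = TRUE), sim$glint_base,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(simulate_gaze_features(c(-10, 0), sim, default_screen),
               "outside")
})

test_that("zero nonlinearity makes the noise-free map affine", {
  sim <- sim_preset(1, feature_noise_sigma_px = 0, nonlinearity_scale = 0)
  pts <- expand.grid(x = seq(0, 1023, length.out = 9),
                     y = seq(0, 767, length.out = 7))
  F <- t(apply(pts, 1, function(p)
    simulate_gaze_features(as.numeric(p), sim, default_screen)$features))
  for (j in 1:8) {
    fit <- lm.fit(cbind(1, pts$x, pts$y), F[, j])
    expect_lt(max(abs(fit$residuals)), 1e-9)
  }
})

test_that("feature noise is reproducible by seed through a session", {
  grid <- make_calibration_grid(default_screen, cols = 2, rows = 2)
  sch <- schedule_config()
  sim <- sim_preset(1, feature_noise_sigma_px = 1)
  s1 <- simulate_session(grid, sch, sim, default_screen, seed = 7)
  s2 <- simulate_session(grid, sch, sim, default_screen, seed = 7)
  s3 <- simulate_session(grid, sch, sim, default_screen, seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1$pupil_x, s3$pupil_x))
})

test_that("session sizes follow the protocol schedule", {
  cal <- make_calibration_grid(default_screen)
  tst <- make_test_grid(cal)
  sch <- schedule_config()
  sim <- sim_preset(1)
  expect_identical(nrow(simulate_session(cal, sch, sim, default_screen, 1)),
                   600L)  # 20 points x 30 frames
  stest <- simulate_session(tst, sch, sim, default_screen, 1)
  expect_identical(nrow(stest), 900L)  # 12 points x 5 shows x 15 frames
  expect_true(all(table(stest$point_idx) == 75L))
  # single point, single frame
  g1 <- make_calibration_grid(default_screen, cols = 2, rows = 2)
  sch1 <- schedule_config(fps = 1, cal_dwell_ms = 1000)
  s1 <- simulate_session(g1, sch1, sim, default_screen, 1)
  expect_identical(nrow(s1), 4L)
  expect_error(simulate_session(g1[0, ], sch, sim, default_screen, 1))
})

test_that("noise-free feature map is injective over a dense gaze lattice", {
  sim <- sim_preset(1, feature_noise_sigma_px = 0)
  pts <- expand.grid(x = seq(0, 1023, length.out = 50),
                     y = seq(0, 767, length.out = 50))
  F <- t(apply(pts, 1, function(p)
    simulate_gaze_features(as.numeric(p), sim, default_screen)$features))
  # strictly monotone per-axis response => distinct x-columns and y-rows;
  # verify the full 8-vector separation on nearest lattice neighbours and
  # on a random sample of pairs
  d <- as.matrix(stats::dist(F[withr::with_seed(1, sample.int(nrow(F), 400)), ]))
  diag(d) <- Inf
  expect_gt(min(d), 1e-6)
  expect_gt(min(diff(sort(unique(F[, 1])))), 1e-6)
  expect_gt(min(diff(sort(unique(F[, 2])))), 1e-6)
})
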