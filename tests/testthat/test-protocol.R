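test_that("grids have the protocol sizes and uniform spacing", {
  cal <- make_calibration_grid(default_screen)
  expect_identical(nrow(cal), 20L)
  expect_identical(attr(cal, "cols"), 5L)
  tst <- make_test_grid(cal)
  expect_identical(nrow(tst), 12L)
  # uniform spacing on a 101-px screen with no margin
  scr <- screen_geometry(101, 101, viewing_distance_cm = 70)
  g <- make_calibration_grid(scr, cols = 5, rows = 5, margin_frac = 0)
  expect_identical(attr(g, "xs"), c(0, 25, 50, 75, 100))
  # margin arithmetic on the default screen
  g2 <- make_calibration_grid(default_screen, margin_frac = 0.1)
  expect_identical(min(g2$x), 102)
  expect_identical(max(g2$x), 921)  # round(0.9 * 1023)
  # halfway points, single rounding rule
  t2 <- make_test_grid(g)
  expect_identical(attr(t2, "xs"), c(13, 38, 63, 88))
  # test points never coincide with calibration points
  expect_identical(nrow(merge(as.data.frame(cal), as.data.frame(tst))), 0L)
  expect_error(make_calibration_grid(default_screen, cols = 1))
})

test_that("grids are mirror-symmetric about the screen centre", {
  for (m in c(0, 0.05, 0.1)) {
    cal <- make_calibration_grid(default_screen, margin_frac = m)
    for (g in list(cal, make_test_grid(cal))) {
      xs <- attr(g, "xs"); ys <- attr(g, "ys")
      expect_lte(max(abs((xs + rev(xs)) - (default_screen$width_px - 1))), 1)
      expect_lte(max(abs((ys + rev(ys)) - (default_screen$height_px - 1))), 1)
    }
  }
})

test_that("schedule derives the protocol frame counts", {
  sch <- schedule_config()
  expect_identical(sch$frames_per_cal_point, 30L)
  expect_identical(sch$frames_per_test_show, 15L)
  expect_identical(sch$test_repetitions, 5L)
  # conservation: every test point appears exactly test_repetitions times
  tst <- make_test_grid(make_calibration_grid(default_screen))
  ses <- simulate_session(tst, sch, sim_preset(1), default_screen, 9)
  shows <- rle(ses$point_idx)
  expect_identical(sum(shows$lengths), 12L * 5L * 15L)
  expect_true(all(table(shows$values) == 5))
  # pseudo-random order: no immediate repeats, reproducible by seed
  expect_false(any(diff(shows$values) == 0))
  ses2 <- simulate_session(tst, sch, sim_preset(1), default_screen, 9)
  expect_identical(ses$point_idx, ses2$point_idx)
})

test_that("calibration collects 600 feature rows and drops rejected frames", {
  grid <- make_calibration_grid(default_screen)
  ses <- simulate_session(grid, schedule_config(), sim_preset(1),
                          default_screen, 4)
  tr <- run_calibration(ses, grid)
  expect_identical(nrow(tr$inputs), 600L)
  expect_identical(ncol(tr$inputs), 8L)
  expect_identical(unname(tr$targets[1, ]),
                   as.numeric(c(grid$x[1], grid$y[1])))
})

test_that("frame-level calibration rejects artifact frames and flags empty points", {
  scr <- default_screen
  grid <- make_calibration_grid(scr, cols = 2, rows = 2)
  sch <- schedule_config(fps = 5, cal_dwell_ms = 1000)  # 5 frames/point
  sim <- sim_preset(1, feature_noise_sigma_px = 0)
  ses <- simulate_session(grid, sch, sim, scr, 6)
  base <- small_scene()
  # scale simulated features into the small frame
  shrink <- function(v) {
    v[c(1, 3, 5, 7)] <- (v[c(1, 3, 5, 7)] - 200) * 0.4 + 95
    v[2] <- (v[2] - 150) * 0.4 + 79          # pupil y
    v[c(4, 6, 8)] <- (v[c(4, 6, 8)] - 117) * 0.4 + 56  # glints above the pupil
    v
  }
  frames <- lapply(seq_len(nrow(ses)), function(i) {
    v <- shrink(unlist(ses[i, neurogaze:::feature_names()]))
    render_eye_frame(scene_for_features(v, base), index = i)
  })
  # corrupt two frames of point 2: paint out all glints
  corrupt <- which(ses$point_idx == 2)[1:2]
  for (i in corrupt) frames[[i]]$pixels[frames[[i]]$pixels > 180] <- 120
  attr(ses, "frames") <- frames
  cfg <- small_detector(side_range = c(5, 30))
  expect_message(tr <- run_calibration(ses, grid, cfg), "2 of 20 frames")
  expect_identical(nrow(tr$inputs), 18L)
  expect_true(all(1:4 %in% tr$point_idx))
  # occlude every frame of point 3 -> error naming the point
  for (i in which(ses$point_idx == 3))
    frames[[i]]$pixels[frames[[i]]$pixels > 180] <- 120
  attr(ses, "frames") <- frames
  expect_error(run_calibration(ses, grid, cfg), "point 3")
})

test_that("sessions round-trip through CSV", {
  grid <- make_calibration_grid(default_screen, cols = 2, rows = 2)
  ses <- simulate_session(grid, schedule_config(), sim_preset(1),
                          default_screen, 11)
  path <- tempfile(fileext = ".csv")
  write_session(ses, path)
  back <- read_session(path)
  expect_equal(as.data.frame(back), as.data.frame(ses), tolerance = 1e-12)
  expect_identical(attr(back, "phase"), "calibration")
  unlink(path)
})

test_that("frames round-trip through PNG and PGM", {
  fr <- render_eye_frame(small_scene(noise_sigma = 3))
  for (ext in c(".png", ".pgm")) {
    path <- tempfile(fileext = ext)
    write_frame(fr, path)
    back <- read_frame(path)
    expect_equal(back$pixels, round(fr$pixels), tolerance = 1e-12)
    unlink(path)
  }
})
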