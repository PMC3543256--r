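test_that("binarisation uses strict inequalities in both polarities", {
  fr <- uniform_frame(100)
  expect_false(any(binarize(fr, 100, "dark")))
  fr2 <- uniform_frame(200)
  fr2$pixels[10, 20] <- 0
  m <- binarize(fr2, 50, "dark")
  expect_identical(sum(m), 1L)
  expect_true(m[10, 20])
  expect_identical(sum(binarize(fr2, 150, "bright")), 64L * 48L - 1L)
  expect_false(any(binarize(uniform_frame(100), 150, "bright")))
})

test_that("Hough detection recovers planted circles to subpixel accuracy", {
  # integer-centred pupil in the default 640x480 scene
  fr <- render_eye_frame(scene_params())
  p <- detect_pupil(fr)
  expect_lt(max(abs(p$center - c(320, 240))), 1.0)
  expect_lt(abs(p$radius_px - 40), 2)
  # subpixel centre, cross-checked against the centroid-of-mask oracle
  sc <- scene_params(pupil_center = c(100.5, 80.5), pupil_radius_px = 20,
                     iris_radius_px = 50,
                     glint_centers = rbind(c(300, 300), c(330, 300),
                                           c(315, 274)))
  fr2 <- render_eye_frame(sc)
  p2 <- detect_pupil(fr2)
  expect_lt(max(abs(p2$center - c(100.5, 80.5))), 1.0)
  mask <- binarize(fr2, detector_config()$pupil_threshold, "dark")
  id <- which(mask, arr.ind = TRUE)
  oracle <- c(mean(id[, 2]), mean(id[, 1]))  # exact for a full disk
  expect_lt(max(abs(p2$center - oracle)), 0.5)
  # all-bright frame has no dark region
  expect_null(detect_pupil(uniform_frame(250)))
})

test_that("ROI tracking reproduces the full-frame detection", {
  fr <- render_eye_frame(small_scene())
  cfg <- small_detector()
  p_full <- detect_pupil(fr, cfg)
  p_roi <- detect_pupil(fr, cfg, prev = p_full)
  expect_lt(max(abs(p_roi$center - p_full$center)), 0.5)
  # stale previous detection far away: ROI fails, full-frame retry succeeds
  stale <- p_full
  stale$center <- c(185, 15)
  p_retry <- detect_pupil(fr, cfg, prev = stale)
  expect_false(is.null(p_retry))
  expect_lt(max(abs(p_retry$center - p_full$center)), 0.5)
})

test_that("glint candidates report area-filtered weighted centroids", {
  px <- matrix(10, 40, 40)
  px[10:12, 9:11] <- 240          # 3x3 blob centred at (10, 11)
  px[30, 30] <- 250               # single-pixel blob
  fr <- raw_frame(px)
  cfg <- detector_config(glint_threshold = 200, min_blob_area = 2)
  g <- detect_glint_candidates(fr, cfg)
  expect_length(g, 1)             # area-1 blob excluded
  expect_equal(g[[1]]$centroid, c(10, 11), tolerance = 1e-12)
  expect_identical(g[[1]]$area_px, 9L)
  # weighted-mean arithmetic of the centre of mass
  expect_equal(blob_centroid(c(10, 11), c(5, 5), c(100, 200))[1],
               (10 * 100 + 11 * 200) / 300, tolerance = 1e-12)
  # diagonal-only contact is one 8-connected component
  px2 <- matrix(0, 10, 10)
  px2[3, 3] <- 255; px2[4, 4] <- 255
  g2 <- detect_glint_candidates(raw_frame(px2),
                                detector_config(glint_threshold = 100,
                                                min_blob_area = 2))
  expect_length(g2, 1)
  expect_identical(g2[[1]]$area_px, 2L)
})

test_that("centroids of planted Gaussian spots are subpixel accurate", {
  cfg <- detector_config()
  errs <- withr::with_seed(11, replicate(100, {
    gx <- 15 + runif(1); gy <- 15 + runif(1)
    xs <- 1:31; ys <- 1:31
    px <- 90 + (255 - 90) *
      exp(-outer((ys - gy)^2, (xs - gx)^2, "+") / (2 * 2.5^2))
    g <- detect_glint_candidates(raw_frame(px), cfg)
    expect_length(g, 1)
    sqrt(sum((g[[1]]$centroid - c(gx, gy))^2))
  }))
  expect_lt(max(errs), 0.1)
})

test_that("triangle validator accepts the 0/60/120 pattern and rejects others", {
  cfg <- detector_config(side_range = c(5, 20), angle_tol_deg = 5)
  tri <- list(cand(0, 0), cand(10, 0), cand(5, 8.660))
  ok <- validate_triangle(tri, cfg)
  expect_s3_class(ok, "glint_triple")
  expect_setequal(round(sort(ok$side_directions)), c(0, 60, 120))
  # canonical order: horizontal side left-to-right, then apex
  expect_equal(ok$glints[, 1], c(0, 10, 5), ignore_attr = TRUE)
  # collinear points: all directions 0
  expect_true(is_rejection(validate_triangle(
    list(cand(0, 0), cand(10, 0), cand(20, 0)), cfg)))
  # correct shape, sides too short
  tiny <- list(cand(0, 0), cand(2, 0), cand(1, 1.732))
  expect_true(is_rejection(validate_triangle(tiny, cfg)))
  # fewer than three candidates
  expect_true(is_rejection(validate_triangle(tri[1:2], cfg)))
})

test_that("validator decision is order- and translation-invariant", {
  cfg <- detector_config()
  base <- list(cand(50, 60), cand(80, 60), cand(65, 34.02), cand(120, 90))
  ref <- validate_triangle(base, cfg)
  expect_s3_class(ref, "glint_triple")
  for (perm in list(c(2, 4, 1, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    r <- validate_triangle(base[perm], cfg)
    expect_equal(r$glints, ref$glints, tolerance = 1e-12)
  }
  shifted <- lapply(base, function(g) cand(g$centroid[1] + 31.7,
                                           g$centroid[2] - 12.3))
  r2 <- validate_triangle(shifted, cfg)
  expect_equal(r2$glints, ref$glints + rep(c(31.7, -12.3), each = 3),
               tolerance = 1e-9)
})

test_that("tightening tolerances never turns a rejection into an acceptance", {
  tols <- c(20, 15, 10, 6, 3, 1)
  ranges <- list(c(5, 80), c(8, 60), c(12, 45), c(20, 40))
  cases <- withr::with_seed(5, replicate(40, {
    n <- sample(3:5, 1)
    lapply(seq_len(n), function(i) cand(runif(1, 0, 100), runif(1, 0, 100)))
  }, simplify = FALSE))
  # planted valid triangles among the random cases
  cases <- c(cases, list(
    list(cand(10, 10), cand(40, 10), cand(25, 10 - 25.98)),
    list(cand(10, 10), cand(40, 10), cand(25, 35.98), cand(90, 90))))
  for (cs in cases) {
    accepted_prev <- TRUE
    for (k in seq_along(tols)) {
      cfg <- detector_config(angle_tol_deg = tols[k], side_range = ranges[[min(k, 4)]])
      acc <- !is_rejection(validate_triangle(cs, cfg))
      if (!accepted_prev) expect_false(acc)
      accepted_prev <- acc
    }
  }
})

test_that("feature extraction recovers planted geometry and tags rejections", {
  sim <- sim_preset(1, feature_noise_sigma_px = 0)
  base <- scene_params()
  pts <- list(c(100, 100), c(511.5, 383.5), c(900, 700))
  for (p in pts) {
    s <- simulate_gaze_features(p, sim, default_screen)
    fr <- render_eye_frame(scene_for_features(s$features, base))
    ef <- extract_features(fr)
    expect_s3_class(ef, "eye_features")
    expect_lt(max(abs(ef$vector[1:2] - s$features[1:2])), 1.0)   # pupil
    expect_lt(max(abs(ef$vector[3:8] - s$features[3:8])), 0.2)   # glints
  }
  # a fourth spurious bright blob far from the triangle is ignored
  sc <- scene_params()
  fr <- render_eye_frame(sc)
  fr$pixels[400:403, 550:553] <- 250
  ef <- extract_features(fr)
  expect_s3_class(ef, "eye_features")
  expect_equal(matrix(ef$vector[3:8], 3, 2, byrow = TRUE), sc$glint_centers,
               tolerance = 0.2, ignore_attr = TRUE)
  # only two glints visible -> triangle-stage rejection
  sc2 <- scene_params(glint_centers = rbind(c(305, 250), c(335, 250),
                                            c(320, 224.02)))
  fr2 <- render_eye_frame(sc2)
  fr2$pixels[215:233, 311:329] <- 90  # paint out the apex glint
  rej <- extract_features(fr2)
  expect_true(is_rejection(rej))
  expect_identical(rej$stage, "triangle")
  # all-bright frame fails at the pupil stage
  rej2 <- extract_features(uniform_frame(250))
  expect_true(is_rejection(rej2))
  expect_identical(rej2$stage, "pupil")
})
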