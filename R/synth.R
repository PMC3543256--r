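#' Scene description for the synthetic eye-frame renderer
#'
#' Parameters of a rendered infrared eye image: a uniform background, a
#' brighter iris disk, a dark pupil disk (the dark-pupil effect produced by
#' off-axis infrared lighting) and three small Gaussian glints arranged in
#' a triangle, as produced by three infrared sources reflecting off the
#' cornea. Intensity levels are 8-bit (0-255). Image coordinates are
#' 1-based pixel centres, `x` rightward (column), `y` downward (row).
#'
#' @param image_width_px,image_height_px Raster size in pixels.
#' @param background_level,iris_level,pupil_level,glint_level Intensities
#'   of the four scene components; must satisfy
#'   `pupil_level < iris_level < glint_level`.
#' @param pupil_center Numeric `(x, y)`, subpixel.
#' @param pupil_radius_px Pupil disk radius.
#' @param iris_radius_px Iris disk radius (drawn beneath the pupil).
#' @param glint_centers 3x2 matrix of subpixel glint centres; must be
#'   non-collinear and inside the image.
#' @param glint_sigma_px Gaussian width of each glint spot.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise.
#' @param seed Integer seed driving the noise; rendering is bit-identical
#'   for identical `(scene, seed)`.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_width_px = 640L, image_height_px = 480L,
                         background_level = 180, iris_level = 90,
                         pupil_level = 20, glint_level = 255,
                         pupil_center = c(320, 240), pupil_radius_px = 40,
                         iris_radius_px = 2.5 * pupil_radius_px,
                         glint_centers = rbind(c(305, 250), c(335, 250),
                                               c(320, 224.02)),
                         glint_sigma_px = 2.5, noise_sigma = 0,
                         seed = 1L) {
  glint_centers <- as.matrix(glint_centers)
  stopifnot(pupil_level < iris_level, iris_level < glint_level,
            pupil_radius_px > 0, glint_sigma_px > 0, noise_sigma >= 0,
            nrow(glint_centers) == 3, ncol(glint_centers) == 2)
  inside <- function(p) p[1] >= 1 && p[1] <= image_width_px &&
    p[2] >= 1 && p[2] <= image_height_px
  if (!inside(pupil_center))
    stop("pupil_center lies outside the image")
  if (!all(apply(glint_centers, 1, inside)))
    stop("glint_centers must lie inside the image")
  # collinearity check via twice the triangle area
  a2 <- abs((glint_centers[2, 1] - glint_centers[1, 1]) *
              (glint_centers[3, 2] - glint_centers[1, 2]) -
              (glint_centers[3, 1] - glint_centers[1, 1]) *
              (glint_centers[2, 2] - glint_centers[1, 2]))
  if (a2 < 1e-9) stop("glint_centers are collinear")
  s <- list(image_width_px = as.integer(image_width_px),
            image_height_px = as.integer(image_height_px),
            background_level = background_level, iris_level = iris_level,
            pupil_level = pupil_level, glint_level = glint_level,
            pupil_center = pupil_center, pupil_radius_px = pupil_radius_px,
            iris_radius_px = iris_radius_px, glint_centers = glint_centers,
            glint_sigma_px = glint_sigma_px, noise_sigma = noise_sigma,
            seed = as.integer(seed))
  class(s) <- "scene_params"
  s
}

# area-coverage anti-aliased disk: blends `level` into img with per-pixel
# coverage; boundary pixels are 4x4 supersampled
draw_disk <- function(img, cx, cy, r, level) {
  h <- nrow(img); w <- ncol(img)
  x0 <- max(1L, floor(cx - r - 2)); x1 <- min(w, ceiling(cx + r + 2))
  y0 <- max(1L, floor(cy - r - 2)); y1 <- min(h, ceiling(cy + r + 2))
  xs <- x0:x1; ys <- y0:y1
  dx <- xs - cx; dy <- ys - cy
  d <- sqrt(outer(dy^2, dx^2, "+"))
  alpha <- matrix(0, length(ys), length(xs))
  alpha[d <= r - 0.75] <- 1
  edge <- which(d > r - 0.75 & d < r + 0.75, arr.ind = TRUE)
  if (nrow(edge) > 0) {
    off <- seq(-0.375, 0.375, by = 0.25)
    sub <- expand.grid(ox = off, oy = off)
    ex <- xs[edge[, 2]]; ey <- ys[edge[, 1]]
    cov <- numeric(nrow(edge))
    for (k in seq_len(nrow(sub))) {
      cov <- cov + ((ex + sub$ox[k] - cx)^2 + (ey + sub$oy[k] - cy)^2 <= r^2)
    }
    alpha[edge] <- cov / nrow(sub)
  }
  img[ys, xs] <- img[ys, xs] + alpha * (level - img[ys, xs])
  img
}

#' Render a synthetic infrared eye frame
#'
#' Draws the dark-pupil scene described by a [scene_params()] object:
#' uniform background, iris disk, anti-aliased pupil disk and three
#' Gaussian glint spots, plus optional additive Gaussian noise. The pupil
#' edge uses area coverage on a supersampled disk so that subpixel pupil
#' centres remain recoverable by the detector.
#'
#' @param scene A [scene_params()].
#' @param index Frame index stored in the result.
#' @return An `eye_frame`: list with `pixels` (numeric matrix, rows = y,
#'   columns = x, values in 0-255), `width_px`, `height_px`, `index`.
#' @examples
#' fr <- render_eye_frame(scene_params())
#' fr$pixels[240, 320] # pupil level
#' @export
render_eye_frame <- function(scene, index = 0L) {
  stopifnot(inherits(scene, "scene_params"))
  w <- scene$image_width_px; h <- scene$image_height_px
  img <- matrix(scene$background_level, h, w)
  img <- draw_disk(img, scene$pupil_center[1], scene$pupil_center[2],
                   scene$iris_radius_px, scene$iris_level)
  img <- draw_disk(img, scene$pupil_center[1], scene$pupil_center[2],
                   scene$pupil_radius_px, scene$pupil_level)
  s2 <- 2 * scene$glint_sigma_px^2
  ext <- ceiling(4 * scene$glint_sigma_px) + 1
  for (i in 1:3) {
    gx <- scene$glint_centers[i, 1]; gy <- scene$glint_centers[i, 2]
    xs <- max(1L, floor(gx - ext)):min(w, ceiling(gx + ext))
    ys <- max(1L, floor(gy - ext)):min(h, ceiling(gy + ext))
    g <- exp(-outer((ys - gy)^2, (xs - gx)^2, "+") / s2)
    img[ys, xs] <- img[ys, xs] + g * (scene$glint_level - img[ys, xs])
  }
  if (scene$noise_sigma > 0) {
    img <- withr::with_seed(scene$seed, {
      img + matrix(stats::rnorm(h * w, 0, scene$noise_sigma), h, w)
    })
    img <- pmin(pmax(img, 0), 255)
  }
  structure(list(pixels = img, width_px = w, height_px = h,
                 index = as.integer(index)),
            class = "eye_frame")
}

#' Feature-level gaze simulator parameters
#'
#' Forward model from an on-screen point of gaze (POG) to the eight image
#' features (pupil centre and three glint centroids). The pupil follows the
#' eye rotation through a smooth saturating response (tanh-type), while the
#' corneal glints stay nearly fixed, drifting only slightly with gaze. The
#' pupil centroid and the glint centroids carry independent Gaussian
#' position noise; glints are noisier than the pupil because a small bright
#' blob yields a less stable centroid than a large dark disk. This forward
#' model is a test oracle for the mapping stage, never part of the
#' estimator, which remains free of any eye or geometry model.
#'
#' @param pupil_rest Image position `(x, y)` of the pupil when the gaze is
#'   at the screen centre.
#' @param pupil_gain Image px of pupil motion per screen px of gaze,
#'   per axis; components must be nonzero.
#' @param nonlinearity_scale Strength of the saturating response; `0` gives
#'   an affine feature map. See [saturate()].
#' @param glint_base 3x2 matrix: canonical glint triangle at screen-centre
#'   gaze (near-equilateral with one near-horizontal side).
#' @param glint_drift_gain 3x2 matrix of image px per screen px of small
#'   POG-dependent glint motion.
#' @param feature_noise_sigma_px Pupil centroid noise SD (image px),
#'   non-negative.
#' @param glint_noise_ratio Glint noise SD as a multiple of
#'   `feature_noise_sigma_px`.
#' @param setting Label of the geometric setting the parameters represent.
#' @return An object of class `sim_params`.
#' @seealso [sim_preset()] for the three geometric-setting presets.
#' @export
sim_params <- function(pupil_rest = c(200, 150),
                       pupil_gain = c(0.06, 0.06),
                       nonlinearity_scale = 0.7,
                       glint_base = rbind(c(185, 130), c(215, 130),
                                          c(200, 104)),
                       glint_drift_gain = rbind(c(0.010, 0.013),
                                                c(0.014, 0.011),
                                                c(0.012, 0.012)),
                       feature_noise_sigma_px = 0.45,
                       glint_noise_ratio = 8 / 3,
                       setting = "setting1") {
  glint_base <- as.matrix(glint_base)
  glint_drift_gain <- as.matrix(glint_drift_gain)
  stopifnot(length(pupil_gain) == 2, all(pupil_gain != 0),
            feature_noise_sigma_px >= 0, glint_noise_ratio >= 0,
            nonlinearity_scale >= 0,
            dim(glint_base) == c(3, 2), dim(glint_drift_gain) == c(3, 2))
  structure(list(pupil_rest = pupil_rest, pupil_gain = pupil_gain,
                 nonlinearity_scale = nonlinearity_scale,
                 glint_base = glint_base,
                 glint_drift_gain = glint_drift_gain,
                 feature_noise_sigma_px = feature_noise_sigma_px,
                 glint_noise_ratio = glint_noise_ratio,
                 setting = setting),
            class = "sim_params")
}

#' Simulator presets for the three geometric settings
#'
#' The experimental protocol places the infrared sources at an angular
#' separation of 0, 30 or 60 degrees from the camera. The presets encode
#' the resulting appearance differences: the eye image (pupil rest position
#' and glint triangle) shifts with the camera placement, and the saturation
#' of the pupil response grows with the camera-light separation as the view
#' of the cornea becomes more oblique. The mapping estimator never sees
#' these parameters; they exist only in the forward simulator.
#'
#' @param setting 1, 2 or 3 (0, 30, 60 degrees between lights and camera).
#' @param ... Overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
sim_preset <- function(setting = 1, ...) {
  setting <- as.integer(setting)
  stopifnot(setting %in% 1:3)
  shift <- switch(setting, c(0, 0), c(25, 6), c(50, 12))
  nl <- switch(setting, 0.7, 1.0, 1.2)
  defaults <- list(
    pupil_rest = c(200, 150) + shift,
    nonlinearity_scale = nl,
    glint_base = rbind(c(185, 130), c(215, 130), c(200, 104)) +
      rep(shift, each = 3),
    setting = paste0("setting", setting)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

#' Smooth saturating response
#'
#' `saturate(u, a, half)` equals `(half / a) * tanh(a * u / half)`; it is
#' odd, strictly increasing, has unit slope at the origin and approaches
#' `half / a` for large `u`. With `a = 0` it degenerates to the identity,
#' making the feature map affine.
#'
#' @param u Displacement (vectorised).
#' @param a Dimensionless saturation strength.
#' @param half Half-extent of the input range (sets where saturation bites).
#' @return Saturated displacement, same shape as `u`.
#' @export
saturate <- function(u, a, half) {
  if (a == 0) return(u)
  (half / a) * tanh(a * u / half)
}

# screen centre in 0-based pixel coordinates
screen_center <- function(screen) {
  c((screen$width_px - 1) / 2, (screen$height_px - 1) / 2)
}

#' Simulate the eye features for one fixated screen point
#'
#' Applies the forward model of [sim_params()]: the pupil centre moves from
#' its rest position by `pupil_gain * saturate(pog - centre)`, each glint
#' moves from its canonical position by `glint_drift_gain * (pog - centre)`,
#' and independent Gaussian noise is added to every coordinate (pupil SD
#' `feature_noise_sigma_px`, glint SD `glint_noise_ratio` times that).
#' Noise is drawn from the current RNG stream; wrap calls in
#' [withr::with_seed()] (as [simulate_session()] does) for reproducibility.
#' The noise-free map is injective over the screen because the pupil
#' response is strictly monotone in each gaze coordinate.
#'
#' @param pog Numeric `(X, Y)` screen point, inside the screen.
#' @param sim A [sim_params()].
#' @param screen A [screen_geometry()].
#' @return A list with `true_pog` and `features`, the named 8-vector
#'   `(pupil_x, pupil_y, g1x, g1y, g2x, g2y, g3x, g3y)`.
#' @export
simulate_gaze_features <- function(pog, sim, screen) {
  stopifnot(inherits(sim, "sim_params"), inherits(screen, "screen_geometry"),
            length(pog) == 2)
  if (pog[1] < 0 || pog[1] > screen$width_px - 1 ||
      pog[2] < 0 || pog[2] > screen$height_px - 1)
    stop("pog lies outside the screen")
  ctr <- screen_center(screen)
  u <- pog - ctr
  s <- c(saturate(u[1], sim$nonlinearity_scale, ctr[1]),
         saturate(u[2], sim$nonlinearity_scale, ctr[2]))
  pupil <- sim$pupil_rest + sim$pupil_gain * s
  glints <- sim$glint_base + sim$glint_drift_gain *
    matrix(u, 3, 2, byrow = TRUE)
  feat <- c(pupil[1], pupil[2], t(glints))
  sig <- c(rep(sim$feature_noise_sigma_px, 2),
           rep(sim$feature_noise_sigma_px * sim$glint_noise_ratio, 6))
  if (sim$feature_noise_sigma_px > 0)
    feat <- feat + stats::rnorm(8) * sig
  names(feat) <- feature_names()
  list(true_pog = pog, features = feat)
}

feature_names <- function() {
  c("pupil_x", "pupil_y", "g1x", "g1y", "g2x", "g2y", "g3x", "g3y")
}

#' Simulate a full calibration or test session at feature level
#'
#' Produces one simulated sample per scheduled frame. For a calibration
#' grid the points are visited in grid order, each for
#' `frames_per_cal_point` frames (30 at the default 25 fps and 1200 ms
#' dwell). For a test grid each point is shown `test_repetitions` times in
#' a seeded pseudo-random order with no immediate repeats, each show
#' lasting `frames_per_test_show` frames (15 at the defaults). All
#' randomness (show order and feature noise) derives from `seed`.
#'
#' @param grid A [make_calibration_grid()] or [make_test_grid()] grid.
#' @param schedule A [schedule_config()].
#' @param sim A [sim_params()].
#' @param screen A [screen_geometry()].
#' @param seed Integer seed for the session.
#' @return A data frame of class `gaze_session` with columns `frame_idx`,
#'   `point_idx`, `true_x`, `true_y` and the eight feature columns; the
#'   grid kind is stored in attribute `phase`.
#' @export
simulate_session <- function(grid, schedule, sim, screen, seed = 1L) {
  stopifnot(inherits(grid, "gaze_grid"), inherits(schedule, "schedule_config"))
  if (nrow(grid) == 0) stop("grid is empty")
  kind <- attr(grid, "kind")
  withr::with_seed(as.integer(seed), {
    if (identical(kind, "test")) {
      shows <- make_test_order(nrow(grid), schedule$test_repetitions)
      fpp <- schedule$frames_per_test_show
    } else {
      shows <- seq_len(nrow(grid))
      fpp <- schedule$frames_per_cal_point
    }
    point_idx <- rep(shows, each = fpp)
    n <- length(point_idx)
    feats <- matrix(NA_real_, n, 8)
    for (i in seq_len(n)) {
      p <- c(grid$x[point_idx[i]], grid$y[point_idx[i]])
      feats[i, ] <- simulate_gaze_features(p, sim, screen)$features
    }
    out <- data.frame(frame_idx = seq_len(n), point_idx = point_idx,
                      true_x = grid$x[point_idx], true_y = grid$y[point_idx])
    colnames(feats) <- feature_names()
    out <- cbind(out, as.data.frame(feats))
    attr(out, "phase") <- if (identical(kind, "test")) "test" else "calibration"
    attr(out, "setting") <- sim$setting
    class(out) <- c("gaze_session", "data.frame")
    out
  })
}

# seeded pseudo-random sequence of (point, repetition) shows with no
# immediate repeats; draws from the current RNG stream
make_test_order <- function(n_points, repetitions) {
  shows <- rep(seq_len(n_points), repetitions)
  for (try in 1:100) {
    ord <- sample(shows)
    for (i in which(diff(ord) == 0)) {
      cand <- which(ord != ord[i] & c(ord[-1], -1) != ord[i] &
                      c(-1, ord[-length(ord)]) != ord[i])
      cand <- cand[abs(cand - i) > 1]
      if (length(cand) > 0) {
        j <- cand[1]
        tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
      }
    }
    if (!any(diff(ord) == 0)) return(ord)
  }
  stop("could not construct a repeat-free show order")
}

#' Build a scene whose rendered frame carries the given features
#'
#' Places the pupil and glints of a base [scene_params()] at the positions
#' of a simulated feature vector, so that image-level processing can be
#' exercised on frames with known ground truth.
#'
#' @param features Named 8-vector as produced by [simulate_gaze_features()].
#' @param base A [scene_params()] supplying all remaining scene parameters.
#' @param seed Noise seed for the scene.
#' @return A `scene_params` object.
#' @export
scene_for_features <- function(features, base = scene_params(), seed = base$seed) {
  scene_params(image_width_px = base$image_width_px,
               image_height_px = base$image_height_px,
               background_level = base$background_level,
               iris_level = base$iris_level, pupil_level = base$pupil_level,
               glint_level = base$glint_level,
               pupil_center = c(features[["pupil_x"]], features[["pupil_y"]]),
               pupil_radius_px = base$pupil_radius_px,
               iris_radius_px = base$iris_radius_px,
               glint_centers = rbind(
                 c(features[["g1x"]], features[["g1y"]]),
                 c(features[["g2x"]], features[["g2y"]]),
                 c(features[["g3x"]], features[["g3y"]])),
               glint_sigma_px = base$glint_sigma_px,
               noise_sigma = base$noise_sigma, seed = seed)
}
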