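#' Build the calibration grid
#'
#' A rectangular grid of uniformly spaced points (5 columns by 4 rows by
#' default), matching the 4:3 aspect of the screen so that the screen is
#' sampled uniformly. Positions span the screen with a fractional margin on
#' each side and are rounded to integer pixels; points are ordered
#' row-major (left to right, top to bottom).
#'
#' @param screen A [screen_geometry()].
#' @param cols,rows Grid size, at least 2 each.
#' @param margin_frac Fraction of the screen kept clear on each edge,
#'   in `[0, 0.25)`.
#' @return A `gaze_grid` data frame with columns `x`, `y` and attributes
#'   `rows`, `cols`, `kind = "calibration"`, `xs`, `ys`.
#' @export
make_calibration_grid <- function(screen, cols = 5L, rows = 4L,
                                  margin_frac = 0.05) {
  stopifnot(inherits(screen, "screen_geometry"), cols >= 2, rows >= 2,
            margin_frac >= 0, margin_frac < 0.25)
  xs <- round_half_up(seq(margin_frac * (screen$width_px - 1),
                          (1 - margin_frac) * (screen$width_px - 1),
                          length.out = cols))
  ys <- round_half_up(seq(margin_frac * (screen$height_px - 1),
                          (1 - margin_frac) * (screen$height_px - 1),
                          length.out = rows))
  g <- expand.grid(x = xs, y = ys)[, c("x", "y")]  # x fastest: row-major
  rownames(g) <- NULL
  structure(g, rows = as.integer(rows), cols = as.integer(cols),
            kind = "calibration", xs = xs, ys = ys,
            class = c("gaze_grid", "data.frame"))
}

#' Build the test grid of halfway points
#'
#' Each test point is the midpoint of a 2x2 cell of calibration points,
#' rounded to integer pixels (round half up), giving a
#' `(cols-1) x (rows-1)` grid. The user's gaze never crosses these points
#' during calibration, so accuracy there measures interpolation between
#' calibration points, not recall.
#'
#' @param cal A calibration `gaze_grid`.
#' @return A `gaze_grid` with `kind = "test"`.
#' @export
make_test_grid <- function(cal) {
  stopifnot(inherits(cal, "gaze_grid"),
            identical(attr(cal, "kind"), "calibration"))
  xs <- attr(cal, "xs"); ys <- attr(cal, "ys")
  if (length(xs) < 2 || length(ys) < 2) stop("calibration grid too small")
  mx <- round_half_up((xs[-1] + xs[-length(xs)]) / 2)
  my <- round_half_up((ys[-1] + ys[-length(ys)]) / 2)
  g <- expand.grid(x = mx, y = my)[, c("x", "y")]
  rownames(g) <- NULL
  structure(g, rows = length(my), cols = length(mx), kind = "test",
            xs = mx, ys = my, class = c("gaze_grid", "data.frame"))
}

#' Session schedule
#'
#' Fixation timing of the protocol: every calibration point is fixated
#' once for `cal_dwell_ms` (30 frames at 25 fps and 1200 ms); every test
#' point is shown `test_repetitions` times in pseudo-random order, each
#' show lasting `test_dwell_ms` (15 frames at the defaults). Frame counts
#' are derived from the frame rate and dwell times.
#'
#' @param fps Capture rate, frames per second.
#' @param cal_dwell_ms Calibration dwell per point (ms).
#' @param test_dwell_ms Test dwell per show (ms).
#' @param test_repetitions Shows per test point.
#' @return A `schedule_config` with derived `frames_per_cal_point` and
#'   `frames_per_test_show`.
#' @export
schedule_config <- function(fps = 25, cal_dwell_ms = 1200,
                            test_dwell_ms = 600, test_repetitions = 5L) {
  stopifnot(fps > 0, cal_dwell_ms > 0, test_dwell_ms > 0,
            test_repetitions >= 1)
  structure(list(fps = fps, cal_dwell_ms = cal_dwell_ms,
                 test_dwell_ms = test_dwell_ms,
                 test_repetitions = as.integer(test_repetitions),
                 frames_per_cal_point = as.integer(round(fps * cal_dwell_ms / 1000)),
                 frames_per_test_show = as.integer(round(fps * test_dwell_ms / 1000))),
            class = "schedule_config")
}

# extract per-frame feature rows from a session: either ready-made feature
# columns (feature-level simulation) or rendered frames re-processed by the
# detection chain; returns features matrix plus logical validity
session_features <- function(session, cfg = NULL) {
  n <- nrow(session)
  frames <- attr(session, "frames")
  if (!is.null(frames)) {
    if (is.null(cfg)) cfg <- detector_config()
    feats <- matrix(NA_real_, n, 8)
    valid <- logical(n)
    stages <- character(n)
    prev <- NULL
    for (i in seq_len(n)) {
      ef <- extract_features(frames[[i]], cfg, prev)
      if (is_rejection(ef)) {
        stages[i] <- ef$stage
        prev <- NULL
      } else {
        feats[i, ] <- ef$vector
        valid[i] <- TRUE
        prev <- ef$pupil
      }
    }
    list(features = feats, valid = valid, stages = stages)
  } else {
    feats <- as.matrix(session[, feature_names()])
    list(features = feats, valid = rep(TRUE, n),
         stages = character(n))
  }
}

#' Run the calibration phase
#'
#' Consumes a calibration session (simulated features, or rendered frames
#' processed through [extract_features()]) and assembles the training set:
#' each valid frame contributes its 8-vector paired with the coordinates of
#' the fixated calibration point. Rejected frames are dropped with a
#' message; a calibration point with no valid frame at all aborts with an
#' error naming the point, since the mapping would be unconstrained there.
#' No image data is retained.
#'
#' @param session A `gaze_session` over the calibration grid.
#' @param grid The calibration `gaze_grid`.
#' @param cfg Optional [detector_config()] used when the session carries
#'   rendered frames.
#' @return A [training_set()].
#' @export
run_calibration <- function(session, grid, cfg = NULL) {
  stopifnot(inherits(session, "gaze_session"), inherits(grid, "gaze_grid"))
  sf <- session_features(session, cfg)
  if (any(!sf$valid))
    message(sprintf("calibration: %d of %d frames rejected (%s)",
                    sum(!sf$valid), nrow(session),
                    paste(sprintf("%s: %d", names(table(sf$stages[!sf$valid])),
                                  table(sf$stages[!sf$valid])), collapse = ", ")))
  present <- unique(session$point_idx[sf$valid])
  missing <- setdiff(seq_len(nrow(grid)), present)
  if (length(missing) > 0)
    stop(sprintf("calibration point %d has no valid frames", missing[1]))
  training_set(sf$features[sf$valid, , drop = FALSE],
               cbind(session$true_x, session$true_y)[sf$valid, , drop = FALSE],
               session$point_idx[sf$valid])
}

#' Run the test phase
#'
#' Predicts the POG for every valid frame of a test session and pairs it
#' with the true fixated point, recording the signed pixel errors
#' `e_x = est_X - true_X` and `e_y = est_Y - true_Y`.
#'
#' @param model A fitted `gaze_model`.
#' @param session A `gaze_session` (test or calibration phase).
#' @param cfg Optional [detector_config()] for frame-carrying sessions.
#' @param metadata Optional named list (user, session, setting tags).
#' @return A `session_result` data frame with columns `n`, `true_x`,
#'   `true_y`, `est_x`, `est_y`, `e_x`, `e_y`, `valid`; attributes `phase`
#'   and `metadata`.
#' @export
run_test <- function(model, session, cfg = NULL, metadata = list()) {
  stopifnot(inherits(model, "gaze_model"), inherits(session, "gaze_session"))
  sf <- session_features(session, cfg)
  n <- nrow(session)
  est <- matrix(NA_integer_, n, 2)
  if (any(sf$valid))
    est[sf$valid, ] <- predict_pog(model, sf$features[sf$valid, , drop = FALSE])
  res <- data.frame(n = session$frame_idx,
                    true_x = session$true_x, true_y = session$true_y,
                    est_x = est[, 1], est_y = est[, 2],
                    e_x = est[, 1] - session$true_x,
                    e_y = est[, 2] - session$true_y,
                    valid = sf$valid)
  attr(res, "phase") <- attr(session, "phase")
  attr(res, "metadata") <- metadata
  class(res) <- c("session_result", "data.frame")
  res
}
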