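#' Run one simulated calibration-and-test experiment
#'
#' End-to-end feature-level run of the protocol: build the calibration and
#' halfway test grids, simulate the calibration session, assemble the
#' training set, fit the neural mapping (and optionally the linear
#' baseline), simulate the test session, and score both phases. All
#' randomness derives from `seed`; the calibration and test sessions use
#' distinct seeds derived from it.
#'
#' @param setting Geometric setting 1, 2 or 3; selects [sim_preset()]
#'   unless `sim` is given.
#' @param seed Integer master seed.
#' @param screen A [screen_geometry()].
#' @param sim Optional [sim_params()] overriding the preset.
#' @param schedule A [schedule_config()].
#' @param train_cfg A [train_config()]; its seed is replaced by `seed`.
#' @param margin_frac Calibration grid margin.
#' @param include_linear Also fit and score the linear baseline.
#' @return A list with the grids, sessions, `training`, `model`,
#'   `linear_model` (or NULL), and `stats`: per-phase [error_stats()] for
#'   the neural model (and `linear_*` when requested).
#' @export
run_experiment <- function(setting = 1, seed = 1L,
                           screen = screen_geometry(), sim = NULL,
                           schedule = schedule_config(),
                           train_cfg = train_config(),
                           margin_frac = 0.05, include_linear = FALSE) {
  seed <- as.integer(seed)
  if (is.null(sim)) sim <- sim_preset(setting)
  train_cfg$seed <- seed
  cal_grid <- make_calibration_grid(screen, margin_frac = margin_frac)
  test_grid <- make_test_grid(cal_grid)
  cal_session <- simulate_session(cal_grid, schedule, sim, screen, seed)
  test_session <- simulate_session(test_grid, schedule, sim, screen,
                                   seed + 1000003L)
  training <- run_calibration(cal_session, cal_grid)
  model <- fit_gaze_model(training, screen, train_cfg)
  meta <- list(setting = sim$setting, seed = seed)
  cal_result <- run_test(model, cal_session, metadata = meta)
  test_result <- run_test(model, test_session, metadata = meta)
  stats <- list(calibration = error_stats(cal_result, screen),
                test = error_stats(test_result, screen))
  linear_model <- NULL
  if (include_linear) {
    linear_model <- fit_linear_baseline(training, screen)
    stats$linear_calibration <-
      error_stats(run_test(linear_model, cal_session, metadata = meta), screen)
    stats$linear_test <-
      error_stats(run_test(linear_model, test_session, metadata = meta), screen)
  }
  list(setting = setting, seed = seed, screen = screen, sim = sim,
       schedule = schedule, cal_grid = cal_grid, test_grid = test_grid,
       cal_session = cal_session, test_session = test_session,
       training = training, model = model, linear_model = linear_model,
       cal_result = cal_result, test_result = test_result, stats = stats)
}

#' Run an experiment and write all artifacts to disk
#'
#' Wraps [run_experiment()] and persists the model (JSON), the two
#' sessions (CSV), a per-phase accuracy report (CSV) and a manifest
#' recording the seed and configuration, so that every artifact is
#' reproducible from `(config, seed)` alone. On error all partial outputs
#' are removed.
#'
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [run_experiment()].
#' @return Invisibly, the named list of written paths.
#' @export
end_to_end <- function(out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(model = file.path(out_dir, "model.json"),
                calibration = file.path(out_dir, "calibration_session.csv"),
                test = file.path(out_dir, "test_session.csv"),
                report = file.path(out_dir, "report.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(unlist(paths)))
  exp <- run_experiment(...)
  write_gaze_model(exp$model, paths$model)
  write_session(exp$cal_session, paths$calibration)
  write_session(exp$test_session, paths$test)
  report <- do.call(rbind, lapply(names(exp$stats), function(nm) {
    s <- exp$stats[[nm]]
    data.frame(phase = nm, n = s$n,
               rmse_x_px = s$rmse_x, rmse_y_px = s$rmse_y,
               rmse_rho_px = s$rmse_rho,
               rmse_x_deg = s$deg_rmse_x, rmse_y_deg = s$deg_rmse_y,
               rmse_rho_deg = s$deg_rmse_rho)
  }))
  utils::write.csv(report, paths$report, row.names = FALSE)
  jsonlite::write_json(list(seed = exp$seed, setting = exp$setting,
                            sim = unclass(exp$sim),
                            schedule = unclass(exp$schedule),
                            train = unclass(exp$model$config)),
                       paths$manifest, digits = NA, auto_unbox = TRUE)
  ok <- TRUE
  invisible(paths)
}
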