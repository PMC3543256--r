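#' Per-phase error statistics
#'
#' Mean squared error and root-mean-square error of the POG estimate over
#' the valid frames of one phase, per coordinate and radial:
#' `MSE_x = sum(e_x^2)/N`, `MSE_y = sum(e_y^2)/N`,
#' `MSE_rho = MSE_x + MSE_y` (the Euclidean error identity, exact by
#' construction) and `RMSE = sqrt(MSE)`. Pixel RMSE values are converted
#' to degrees of visual angle after aggregation, via
#' [pixels_to_degrees()]. The radial RMSE is the single most representative
#' accuracy figure: per-coordinate values mask diagonal errors.
#'
#' @param result A `session_result` from [run_test()].
#' @param screen A [screen_geometry()].
#' @return An `error_stats` object with fields `n`, `mse_x`, `mse_y`,
#'   `mse_rho`, `rmse_x`, `rmse_y`, `rmse_rho` (pixels) and `deg_rmse_x`,
#'   `deg_rmse_y`, `deg_rmse_rho` (degrees).
#' @export
error_stats <- function(result, screen) {
  stopifnot(inherits(result, "session_result"),
            inherits(screen, "screen_geometry"))
  ok <- result$valid & is.finite(result$e_x) & is.finite(result$e_y)
  if (!any(ok)) stop("no valid records to evaluate")
  ex <- result$e_x[ok]; ey <- result$e_y[ok]
  mse_x <- mean(ex^2); mse_y <- mean(ey^2)
  s <- list(n = sum(ok),
            mse_x = mse_x, mse_y = mse_y, mse_rho = mse_x + mse_y,
            rmse_x = sqrt(mse_x), rmse_y = sqrt(mse_y),
            rmse_rho = sqrt(mse_x + mse_y),
            phase = attr(result, "phase"),
            metadata = attr(result, "metadata"))
  s$deg_rmse_x <- pixels_to_degrees(s$rmse_x, screen)
  s$deg_rmse_y <- pixels_to_degrees(s$rmse_y, screen)
  s$deg_rmse_rho <- pixels_to_degrees(s$rmse_rho, screen)
  class(s) <- "error_stats"
  s
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("%s: N=%d  RMSE x/y/rho = %.2f/%.2f/%.2f px = %.3f/%.3f/%.3f deg\n",
              if (is.null(x$phase)) "session" else x$phase, x$n,
              x$rmse_x, x$rmse_y, x$rmse_rho,
              x$deg_rmse_x, x$deg_rmse_y, x$deg_rmse_rho))
  invisible(x)
}

#' Radial RMSE from per-coordinate RMSE values
#'
#' `RMSE_rho = sqrt(RMSE_x^2 + RMSE_y^2)`, valid in any unit (pixels or
#' degrees) since it just undoes the square roots of the component MSEs.
#'
#' @param rmse_x,rmse_y Component RMSE values (vectorised).
#' @return Radial RMSE.
#' @export
euclidean_rmse <- function(rmse_x, rmse_y) sqrt(rmse_x^2 + rmse_y^2)

#' Aggregate a metric across users or sessions
#'
#' Mean, population standard deviation (divisor `N`, matching the
#' convention of the reference accuracy tables) and relative standard
#' deviation `RSD% = 100 * SD / mean`.
#'
#' @param values Numeric vector of per-user (or per-session) metric values.
#' @return An `aggregate_stats` list with `mean`, `sd`, `rsd_pct`, `n`.
#' @export
aggregate_stats <- function(values) {
  stopifnot(length(values) > 0, all(is.finite(values)))
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  rsd <- if (m == 0) {
    if (s > 0) { warning("RSD undefined: zero mean with nonzero SD"); NA_real_ }
    else 0
  } else 100 * s / m
  structure(list(mean = m, sd = s, rsd_pct = rsd, n = length(values)),
            class = "aggregate_stats")
}

#' Tabulate per-user accuracy with aggregate footer rows
#'
#' Builds the standard report layout: one row per user and phase with
#' RMSE x / y / radial in degrees, plus `mean`, `SD` and `RSD%` footer
#' rows computed per session and phase (and a combined block across
#' sessions when more than one is present). Population SD is used
#' throughout.
#'
#' @param df Data frame with columns `user`, `session`, `phase`,
#'   `rmse_x_deg`, `rmse_y_deg`, `rmse_rho_deg`.
#' @return A data frame in the same column layout, with footer rows
#'   identified by `user` values `"mean"`, `"SD"`, `"RSD%"` (and
#'   `session = "all"` for the combined block).
#' @export
session_report <- function(df) {
  need <- c("user", "session", "phase", "rmse_x_deg", "rmse_y_deg",
            "rmse_rho_deg")
  stopifnot(all(need %in% names(df)))
  metric_cols <- c("rmse_x_deg", "rmse_y_deg", "rmse_rho_deg")
  footer <- function(block, session_label) {
    rows <- lapply(unique(block$phase), function(ph) {
      sub <- block[block$phase == ph, ]
      ag <- lapply(sub[metric_cols], aggregate_stats)
      data.frame(user = c("mean", "SD", "RSD%"), session = session_label,
                 phase = ph,
                 rmse_x_deg = c(ag$rmse_x_deg$mean, ag$rmse_x_deg$sd,
                                ag$rmse_x_deg$rsd_pct),
                 rmse_y_deg = c(ag$rmse_y_deg$mean, ag$rmse_y_deg$sd,
                                ag$rmse_y_deg$rsd_pct),
                 rmse_rho_deg = c(ag$rmse_rho_deg$mean, ag$rmse_rho_deg$sd,
                                  ag$rmse_rho_deg$rsd_pct))
    })
    do.call(rbind, rows)
  }
  out <- list()
  sessions <- unique(df$session)
  for (s in sessions) {
    block <- df[df$session == s, ]
    block$user <- as.character(block$user)
    out[[length(out) + 1]] <- block[, need]
    out[[length(out) + 1]] <- footer(block, s)
  }
  if (length(sessions) > 1)
    out[[length(out) + 1]] <- footer(df, "all")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Published per-user accuracy tables
#'
#' Per-user RMSE values in degrees (x, y and radial, calibration and test
#' phases) reported for the original six-subject evaluation of this
#' gaze-tracking design: two consecutive sessions at each of three
#' geometric settings (0, 30 and 60 degrees between the infrared lights
#' and the camera) for the neural mapping, plus the linear-regression
#' baseline at the 60-degree setting. These published numbers serve as
#' regression oracles for the error arithmetic (the radial identity and
#' the mean/SD/RSD aggregation), not as values the synthetic pipeline is
#' fitted to.
#'
#' @return A data frame with columns `setting_deg`, `model`, `session`,
#'   `user`, `phase`, `rmse_x_deg`, `rmse_y_deg`, `rmse_rho_deg`.
#' @export
reference_accuracy <- function() {
  path <- system.file("extdata", "reference_accuracy.csv",
                      package = "neurogaze", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published aggregate accuracy rows
#'
#' The mean, population-SD and RSD% rows printed alongside the per-user
#' accuracy tables of [reference_accuracy()], per session and combined
#' across the two sessions (`session = "all"`).
#'
#' @return A data frame with columns `setting_deg`, `model`, `session`,
#'   `phase`, `stat` (`mean`, `sd`, `rsd_pct`) and the three metric
#'   columns.
#' @export
reference_aggregates <- function() {
  path <- system.file("extdata", "reference_aggregates.csv",
                      package = "neurogaze", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(session = "character"))
}
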