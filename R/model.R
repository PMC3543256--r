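#' Assemble a training set
#'
#' Pairs the extracted 8-feature vectors with the known screen coordinates
#' of the fixated calibration points. Only feature vectors are retained;
#' no image data enters the training set.
#'
#' @param inputs Matrix `N x 8` of feature vectors (image px).
#' @param targets Matrix `N x 2` of screen coordinates (px).
#' @param point_idx Optional integer vector: source grid point per row.
#' @return A `training_set`.
#' @export
training_set <- function(inputs, targets, point_idx = NULL) {
  inputs <- as.matrix(inputs); targets <- as.matrix(targets)
  stopifnot(nrow(inputs) > 0, nrow(inputs) == nrow(targets),
            ncol(targets) == 2)
  if (!all(is.finite(inputs)) || !all(is.finite(targets)))
    stop("training set contains non-finite values")
  structure(list(inputs = inputs, targets = targets,
                 point_idx = point_idx), class = "training_set")
}

#' Fit the neural gaze-mapping model
#'
#' Trains two independent single-output networks on the same eight inputs,
#' one per screen coordinate, which keeps each network parsimonious (10
#' hidden units by default). The input normaliser is built from the
#' per-feature min/max of the calibration data; the output normaliser maps
#' the screen rectangle `[0, W-1] x [0, H-1]` to `[-1, 1]`. The Y network
#' is seeded with `cfg$seed + 1` so the two networks start independently.
#'
#' @param train A [training_set()].
#' @param screen A [screen_geometry()].
#' @param cfg A [train_config()].
#' @return A `gaze_model` (kind `"mfnn"`) holding both networks, the
#'   normalisers and the training loss histories.
#' @export
fit_gaze_model <- function(train, screen, cfg = train_config()) {
  stopifnot(inherits(train, "training_set"),
            inherits(screen, "screen_geometry"),
            inherits(cfg, "train_config"))
  X <- train$inputs
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  if (any(hi - lo <= 0)) {
    bad <- which(hi - lo <= 0)[1]
    stop(sprintf("feature %d is constant over the training set", bad))
  }
  input_norm <- make_normalizer(lo, hi)
  output_norm <- make_normalizer(c(0, 0),
                                 c(screen$width_px - 1, screen$height_px - 1))
  Z <- normalize(input_norm, X)
  Tn <- normalize(output_norm, train$targets)
  mk_net <- function(seed) {
    if (cfg$init == "nguyen-widrow")
      init_mfnn_nw(ncol(X), cfg$n_hidden, cfg$init_scale, cfg$w2_scale, seed)
    else
      init_mfnn(ncol(X), cfg$n_hidden, cfg$init_scale, seed)
  }
  fit_x <- train_backprop(mk_net(cfg$seed), Z, Tn[, 1], cfg)
  fit_y <- train_backprop(mk_net(cfg$seed + 1L), Z, Tn[, 2], cfg)
  structure(list(kind = "mfnn", net_x = fit_x$net, net_y = fit_y$net,
                 input_norm = input_norm, output_norm = output_norm,
                 screen = screen, config = cfg,
                 loss_history = list(x = fit_x$loss_history,
                                     y = fit_y$loss_history)),
            class = "gaze_model")
}

#' Fit the linear-regression baseline
#'
#' Ordinary least squares per screen coordinate on the eight features plus
#' an intercept, sharing the normalisers and the prediction path of the
#' neural model so that the comparison isolates the mapping function.
#'
#' @param train A [training_set()] with at least 9 rows.
#' @param screen A [screen_geometry()].
#' @return A `gaze_model` of kind `"linear"`.
#' @export
fit_linear_baseline <- function(train, screen) {
  stopifnot(inherits(train, "training_set"),
            inherits(screen, "screen_geometry"))
  X <- train$inputs
  if (nrow(X) < ncol(X) + 1)
    stop(sprintf("underdetermined: %d samples for %d coefficients",
                 nrow(X), ncol(X) + 1))
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  if (any(hi - lo <= 0)) {
    bad <- which(hi - lo <= 0)[1]
    stop(sprintf("feature %d is constant over the training set", bad))
  }
  input_norm <- make_normalizer(lo, hi)
  output_norm <- make_normalizer(c(0, 0),
                                 c(screen$width_px - 1, screen$height_px - 1))
  Z <- cbind(1, normalize(input_norm, X))
  Tn <- normalize(output_norm, train$targets)
  fit <- stats::lm.fit(Z, Tn)
  if (fit$rank < ncol(Z))
    stop(sprintf("rank-deficient design (rank %d < %d)", fit$rank, ncol(Z)))
  structure(list(kind = "linear", coef_x = fit$coefficients[, 1],
                 coef_y = fit$coefficients[, 2],
                 input_norm = input_norm, output_norm = output_norm,
                 screen = screen),
            class = "gaze_model")
}

# normalised forward pass of either model kind over a feature matrix
model_forward <- function(model, Z) {
  if (model$kind == "mfnn") {
    cbind(mfnn_forward(model$net_x, Z), mfnn_forward(model$net_y, Z))
  } else {
    cbind(drop(cbind(1, Z) %*% model$coef_x),
          drop(cbind(1, Z) %*% model$coef_y))
  }
}

# round half away from zero toward the nearest integer (half-up for the
# non-negative screen coordinates used here); one rounding rule everywhere
round_half_up <- function(x) floor(x + 0.5)

#' Predict the on-screen point of gaze
#'
#' Normalises the feature vector, runs both sub-models, denormalises and
#' quantises the outputs to the screen-pixel lattice: the discrete POG is
#' the rounded prediction clamped to `[0, W-1] x [0, H-1]`.
#'
#' @param model A fitted `gaze_model`.
#' @param features An `eye_features` object, a named 8-vector, or a matrix
#'   with one feature vector per row.
#' @return Integer matrix `N x 2` of screen coordinates (or a length-2
#'   vector for a single input).
#' @export
predict_pog <- function(model, features) {
  stopifnot(inherits(model, "gaze_model"))
  if (inherits(features, "eye_features")) features <- features$vector
  single <- is.vector(features)
  X <- if (single) matrix(features, nrow = 1) else as.matrix(features)
  if (!all(is.finite(X))) stop("non-finite features")
  Z <- normalize(model$input_norm, X)
  out <- denormalize(model$output_norm, model_forward(model, Z))
  out[, 1] <- pmin(pmax(round_half_up(out[, 1]), 0), model$screen$width_px - 1)
  out[, 2] <- pmin(pmax(round_half_up(out[, 2]), 0), model$screen$height_px - 1)
  storage.mode(out) <- "integer"
  colnames(out) <- c("X", "Y")
  if (single) out[1, ] else out
}

#' @export
print.gaze_model <- function(x, ...) {
  cat(sprintf("Gaze model (%s): 8 features -> POG on %dx%d screen\n",
              x$kind, x$screen$width_px, x$screen$height_px))
  if (x$kind == "mfnn")
    cat(sprintf("  two networks, %d tanh hidden units each; final training MSE %.3g / %.3g\n",
                nrow(x$net_x$W1), utils::tail(x$loss_history$x, 1),
                utils::tail(x$loss_history$y, 1)))
  invisible(x)
}

#' Save or load a gaze model as JSON
#'
#' The persisted document carries the model kind, all weights or
#' coefficients, both normalisers, the screen geometry and the training
#' configuration, so a saved model reproduces predictions exactly.
#'
#' @param model A `gaze_model`.
#' @param path File path.
#' @return `write_gaze_model` returns `path` invisibly; `read_gaze_model`
#'   returns the restored `gaze_model`.
#' @export
write_gaze_model <- function(model, path) {
  stopifnot(inherits(model, "gaze_model"))
  doc <- list(kind = model$kind,
              input_norm = list(center = model$input_norm$center,
                                half = model$input_norm$half),
              output_norm = list(center = model$output_norm$center,
                                 half = model$output_norm$half),
              screen = unclass(model$screen))
  if (model$kind == "mfnn") {
    doc$net_x <- lapply(unclass(model$net_x), unname)
    doc$net_y <- lapply(unclass(model$net_y), unname)
    doc$config <- unclass(model$config)
  } else {
    doc$coef_x <- model$coef_x
    doc$coef_y <- model$coef_y
  }
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gaze_model
#' @export
read_gaze_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  scr <- screen_geometry(doc$screen$width_px, doc$screen$height_px,
                         doc$screen$diagonal_cm, doc$screen$viewing_distance_cm)
  nrm <- function(n) make_normalizer(n$center - n$half, n$center + n$half)
  m <- list(kind = doc$kind, input_norm = nrm(doc$input_norm),
            output_norm = nrm(doc$output_norm), screen = scr)
  if (doc$kind == "mfnn") {
    as_net <- function(n) structure(list(
      W1 = matrix(unlist(n$W1), nrow = length(n$b1), byrow = FALSE),
      b1 = as.numeric(n$b1),
      W2 = matrix(unlist(n$W2), nrow = 1),
      b2 = as.numeric(n$b2)), class = "mfnn")
    m$net_x <- as_net(doc$net_x)
    m$net_y <- as_net(doc$net_y)
  } else {
    m$coef_x <- as.numeric(doc$coef_x)
    m$coef_y <- as.numeric(doc$coef_y)
  }
  structure(m, class = "gaze_model")
}
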