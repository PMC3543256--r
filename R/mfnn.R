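#' Training configuration for the mapping networks
#'
#' The networks train for exactly `epochs` full-batch passes of
#' backpropagation on mean squared error. The learning-rate policy is the
#' classical adaptive schedule used with batch backpropagation: a step that
#' would raise the loss by more than 4% is rejected and the rate shrinks
#' (`lr_dec`), otherwise the step is kept and the rate grows slowly
#' (`lr_inc`) while the loss decreases. Momentum is reset after a rejected
#' step. Initialisation is Nguyen-Widrow by default, which spreads the
#' active regions of the tanh units over the input range and noticeably
#' improves how much of the mapping's curvature is learned within the
#' fixed epoch budget; plain uniform initialisation is available via
#' `init = "uniform"`.
#'
#' @param epochs Number of full-batch epochs (default 1000).
#' @param learning_rate Initial learning rate.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param adaptive Use the adaptive learning-rate schedule (default TRUE).
#' @param lr_inc,lr_dec,max_perf_inc Adaptive schedule constants.
#' @param init `"nguyen-widrow"` or `"uniform"`.
#' @param init_scale Scale of the initialisation: half-range of the uniform
#'   draw, or the layer-magnitude factor of Nguyen-Widrow.
#' @param w2_scale Half-range of the uniform output-weight draw.
#' @param n_hidden Hidden units per network (default 10).
#' @param seed Integer seed; the Y network uses `seed + 1` so the two
#'   networks start independently.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 1000L, learning_rate = 0.05,
                         momentum = 0.9, adaptive = TRUE,
                         lr_inc = 1.05, lr_dec = 0.7, max_perf_inc = 1.04,
                         init = c("nguyen-widrow", "uniform"),
                         init_scale = 0.45, w2_scale = 0.4,
                         n_hidden = 10L, seed = 1L) {
  init <- match.arg(init)
  stopifnot(epochs >= 1, learning_rate > 0, momentum >= 0, momentum < 1,
            n_hidden >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 momentum = momentum, adaptive = adaptive, lr_inc = lr_inc,
                 lr_dec = lr_dec, max_perf_inc = max_perf_inc, init = init,
                 init_scale = init_scale, w2_scale = w2_scale,
                 n_hidden = as.integer(n_hidden), seed = as.integer(seed)),
            class = "train_config")
}

#' Initialise a single-output feed-forward network
#'
#' One hidden layer of `n_hidden` tanh units and a linear output unit.
#' Weights are drawn uniformly in `[-init_scale, init_scale]`, biases start
#' at zero. Deterministic given the seed.
#'
#' @param n_in Number of inputs.
#' @param n_hidden Number of hidden units.
#' @param init_scale Half-range of the uniform draw.
#' @param seed Integer seed.
#' @return An `mfnn` object with fields `W1` (`n_hidden x n_in`), `b1`,
#'   `W2` (`1 x n_hidden`), `b2`.
#' @export
init_mfnn <- function(n_in, n_hidden = 10L, init_scale = 0.5, seed = 1L) {
  stopifnot(n_in >= 1, n_hidden >= 1, init_scale >= 0)
  withr::with_seed(as.integer(seed), {
    structure(list(
      W1 = matrix(stats::runif(n_hidden * n_in, -init_scale, init_scale),
                  n_hidden, n_in),
      b1 = numeric(n_hidden),
      W2 = matrix(stats::runif(n_hidden, -init_scale, init_scale),
                  1, n_hidden),
      b2 = 0), class = "mfnn")
  })
}

#' Nguyen-Widrow initialisation
#'
#' Hidden weight vectors are drawn as random directions scaled to magnitude
#' `mag_factor * n_hidden^(1/n_in)` and the hidden biases are spaced
#' uniformly across `[-mag, mag]` with signs matched to the first weight
#' component, so that the linear regions of the tanh units tile the
#' normalised input range instead of piling up at the origin. Output
#' weights are uniform in `[-w2_scale, w2_scale]`, output bias zero.
#'
#' @param n_in Number of inputs.
#' @param n_hidden Number of hidden units.
#' @param mag_factor Layer magnitude factor.
#' @param w2_scale Half-range of the output-weight draw.
#' @param seed Integer seed.
#' @return An `mfnn` object.
#' @export
init_mfnn_nw <- function(n_in, n_hidden = 10L, mag_factor = 0.45,
                         w2_scale = 0.4, seed = 1L) {
  stopifnot(n_in >= 1, n_hidden >= 1)
  withr::with_seed(as.integer(seed), {
    W <- matrix(stats::rnorm(n_hidden * n_in), n_hidden, n_in)
    W <- W / sqrt(rowSums(W^2))
    mag <- mag_factor * n_hidden^(1 / n_in)
    W <- W * mag
    b <- mag * seq(-1, 1, length.out = n_hidden) * sign(W[, 1])
    structure(list(W1 = W, b1 = b,
                   W2 = matrix(stats::runif(n_hidden, -w2_scale, w2_scale),
                               1, n_hidden),
                   b2 = 0), class = "mfnn")
  })
}

#' Forward pass of the network
#'
#' Computes `W2 %*% tanh(W1 %*% x + b1) + b2` for one input vector or for
#' each row of an input matrix.
#'
#' @param net An `mfnn`.
#' @param x Numeric vector of length `n_in` or matrix `N x n_in`.
#' @return Scalar or numeric vector of length `N`.
#' @export
mfnn_forward <- function(net, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(net$W1))
    stop(sprintf("input has %d columns, network expects %d",
                 ncol(x), ncol(net$W1)))
  if (!all(is.finite(x))) stop("non-finite network input")
  H <- tanh(x %*% t(net$W1) + matrix(net$b1, nrow(x), length(net$b1),
                                     byrow = TRUE))
  drop(H %*% t(net$W2)) + net$b2
}

# gradients of the batch MSE loss for a single-output tanh network
mfnn_gradients <- function(net, X, target, H, y) {
  n <- nrow(X)
  dy <- 2 * (y - target) / n
  dH <- outer(dy, drop(net$W2)) * (1 - H^2)
  list(W1 = t(dH) %*% X, b1 = colSums(dH),
       W2 = matrix(dy %*% H, 1), b2 = sum(dy))
}

#' Train a network by full-batch backpropagation
#'
#' Gradient descent with momentum on the mean squared error, for exactly
#' `cfg$epochs` epochs, optionally with the adaptive learning-rate schedule
#' of [train_config()]. Inputs and targets are expected in normalised
#' `[-1, 1]` units. Deterministic given the starting network and data.
#'
#' @param net An `mfnn` starting point.
#' @param inputs Matrix `N x n_in` of normalised inputs.
#' @param targets Numeric vector of length `N`, normalised.
#' @param cfg A [train_config()].
#' @return A list with `net` (trained `mfnn`) and `loss_history`
#'   (per-epoch training MSE, length `cfg$epochs`).
#' @export
train_backprop <- function(net, inputs, targets, cfg = train_config()) {
  stopifnot(inherits(net, "mfnn"), nrow(inputs) == length(targets),
            nrow(inputs) > 0)
  if (!all(is.finite(inputs)) || !all(is.finite(targets)))
    stop("non-finite training data")
  lr <- cfg$learning_rate
  vel <- lapply(net, function(w) w * 0)
  loss_history <- numeric(cfg$epochs)
  H <- tanh(inputs %*% t(net$W1) +
              matrix(net$b1, nrow(inputs), length(net$b1), byrow = TRUE))
  y <- drop(H %*% t(net$W2)) + net$b2
  loss <- mean((y - targets)^2)
  for (ep in seq_len(cfg$epochs)) {
    g <- mfnn_gradients(net, inputs, targets, H, y)
    old <- net; vold <- vel
    for (k in names(net)) {
      vel[[k]] <- cfg$momentum * vel[[k]] - lr * g[[k]]
      net[[k]] <- net[[k]] + vel[[k]]
    }
    H <- tanh(inputs %*% t(net$W1) +
                matrix(net$b1, nrow(inputs), length(net$b1), byrow = TRUE))
    y <- drop(H %*% t(net$W2)) + net$b2
    new_loss <- mean((y - targets)^2)
    if (!is.finite(new_loss))
      stop(sprintf("training diverged (learning rate %.4g)", lr))
    if (cfg$adaptive) {
      if (new_loss > loss * cfg$max_perf_inc) {
        net <- old
        vel <- lapply(vel, function(w) w * 0)
        lr <- lr * cfg$lr_dec
        H <- tanh(inputs %*% t(net$W1) +
                    matrix(net$b1, nrow(inputs), length(net$b1), byrow = TRUE))
        y <- drop(H %*% t(net$W2)) + net$b2
        new_loss <- loss
      } else if (new_loss < loss) {
        lr <- lr * cfg$lr_inc
      }
    }
    loss <- new_loss
    loss_history[ep] <- loss
  }
  list(net = net, loss_history = loss_history, final_lr = lr)
}

#' Linear rescaling between raw and normalised units
#'
#' Maps each feature from `[lo, hi]` to `[-1, 1]` and back. Stored with a
#' fitted model so that prediction applies exactly the normalisation seen
#' during training.
#'
#' @param lo,hi Per-dimension lower and upper bounds; `hi > lo` everywhere.
#' @return A `normalizer` with fields `center` and `half`.
#' @export
make_normalizer <- function(lo, hi) {
  stopifnot(length(lo) == length(hi))
  if (any(hi <= lo)) {
    bad <- which(hi <= lo)[1]
    stop(sprintf("degenerate range in dimension %d (zero spread)", bad))
  }
  structure(list(center = (lo + hi) / 2, half = (hi - lo) / 2),
            class = "normalizer")
}

#' @rdname make_normalizer
#' @param nrm A `normalizer`.
#' @param v Vector or matrix of raw (or normalised) values, one dimension
#'   per column.
#' @export
normalize <- function(nrm, v) {
  if (is.vector(v)) (v - nrm$center) / nrm$half
  else sweep(sweep(v, 2, nrm$center), 2, nrm$half, "/")
}

#' @rdname make_normalizer
#' @export
denormalize <- function(nrm, v) {
  if (is.vector(v)) v * nrm$half + nrm$center
  else sweep(sweep(v, 2, nrm$half, "*"), 2, nrm$center, "+")
}
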