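# From-scratch multilayer sigmoid perceptron: forward pass, squared-error
# loss, exact backpropagated gradients, and batch gradient descent with
# momentum and bold-driver learning-rate adaptation.

#' Logistic sigmoid
#'
#' `1 / (1 + exp(-x))`; strictly increasing, range (0, 1),
#' `sigmoid(x) + sigmoid(-x) = 1`.
#'
#' @param x Numeric vector/matrix.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training configuration for a sigmoid perceptron
#'
#' Defaults follow the reported operating ranges: initial weights drawn
#' uniformly from \[0, 0.5), initial learning rates 0.9 (adapted
#' automatically by the bold driver, floor `rate_floor`), momentum
#' ("dynamic coefficient") in \[0.6, 0.8\] with default 0.7, and allowed
#' error (tolerance) in \[1e-5, 1e-3\] with default 1e-4.
#'
#' @param layer_sizes Integer vector, input size through hidden layers to
#'   the single output (last entry must be 1).
#' @param eta_w,eta_b Initial learning rates for weights and biases.
#' @param momentum Momentum coefficient, in \[0.6, 0.8\].
#' @param tolerance Stop when the batch error E drops to this value;
#'   in \[1e-5, 1e-3\].
#' @param init_low,init_high Support of the uniform weight initialiser;
#'   must lie within \[0, 0.5\].
#' @param max_epochs Maximum number of update attempts.
#' @param rate_floor Smallest learning rate before training stalls out.
#' @param seed Integer seed for the initialiser.
#' @return Named list of class `"network_config"`.
#' @export
network_config <- function(layer_sizes, eta_w = 0.9, eta_b = 0.9,
                           momentum = 0.7, tolerance = 1e-4,
                           init_low = 0, init_high = 0.5,
                           max_epochs = 20000L, rate_floor = 1e-4,
                           seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2) stop("need at least input and output layers")
  if (any(layer_sizes < 1)) stop("layer sizes must be >= 1")
  if (layer_sizes[length(layer_sizes)] != 1) stop("output layer size must be 1")
  if (momentum < 0.6 || momentum > 0.8)
    stop("momentum (dynamic coefficient) must be in [0.6, 0.8]")
  if (tolerance < 1e-5 || tolerance > 1e-3)
    stop("tolerance (allowed error) must be in [1e-5, 1e-3]")
  if (init_low < 0 || init_high > 0.5 || init_low >= init_high)
    stop("initialiser support must lie within [0, 0.5]")
  if (eta_w <= 0 || eta_b <= 0) stop("learning rates must be positive")
  structure(list(layer_sizes = layer_sizes, eta_w = as.numeric(eta_w),
                 eta_b = as.numeric(eta_b),
                 momentum = as.numeric(momentum),
                 tolerance = as.numeric(tolerance),
                 init_low = as.numeric(init_low),
                 init_high = as.numeric(init_high),
                 max_epochs = as.integer(max_epochs),
                 rate_floor = as.numeric(rate_floor),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Initialise a network with uniform random weights
#'
#' Every weight and bias is drawn uniformly from
#' \[`init_low`, `init_high`) (default \[0, 0.5)). The same seed always
#' produces the same network.
#'
#' @param config A [network_config()].
#' @return List of class `"perceptron"` with `weights` (list of matrices,
#'   `W[[m]]` is layer m's `n_m x n_{m-1}` matrix), `biases` (list of
#'   vectors) and `config`.
#' @export
init_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  ls <- config$layer_sizes
  set.seed(config$seed)
  M <- length(ls) - 1L
  weights <- vector("list", M); biases <- vector("list", M)
  for (m in seq_len(M)) {
    weights[[m]] <- matrix(
      stats::runif(ls[m + 1] * ls[m], config$init_low, config$init_high),
      nrow = ls[m + 1], ncol = ls[m])
    biases[[m]] <- stats::runif(ls[m + 1], config$init_low, config$init_high)
  }
  structure(list(weights = weights, biases = biases, config = config),
            class = "perceptron")
}

#' Forward pass through the network
#'
#' Applies `a^{m+1} = sigmoid(W^{m+1} a^m + b^{m+1})` layer by layer
#' (sigmoid at every layer, including the output).
#'
#' @param net A `"perceptron"`.
#' @param x Input: a numeric vector (one sample) or a matrix with one
#'   sample per row and one column per input feature.
#' @return List with `output` (numeric vector, one value per sample in
#'   (0, 1)) and `activations` (list of matrices, features x samples,
#'   starting with the input).
#' @export
net_forward <- function(net, x) {
  stopifnot(inherits(net, "perceptron"))
  a <- if (is.matrix(x)) t(x) else matrix(x, ncol = 1)
  if (nrow(a) != ncol(net$weights[[1]]))
    stop("input length ", nrow(a), " does not match network input size ",
         ncol(net$weights[[1]]))
  acts <- vector("list", length(net$weights) + 1L)
  acts[[1]] <- a
  for (m in seq_along(net$weights)) {
    a <- sigmoid(net$weights[[m]] %*% a + net$biases[[m]])
    acts[[m + 1]] <- a
  }
  list(output = as.vector(a), activations = acts)
}

#' Squared-error loss
#'
#' `E = 1/2 * sum((desired - actual)^2)`.
#'
#' @param actual,desired Equal-length numeric vectors.
#' @return Non-negative scalar, 0 iff the vectors are equal.
#' @export
net_loss <- function(actual, desired) {
  if (length(actual) != length(desired)) stop("length mismatch")
  0.5 * sum((desired - actual)^2)
}

#' Backpropagated gradients of the batch loss
#'
#' Exact gradients of [net_loss()] with respect to every weight and bias,
#' summed over the batch.
#'
#' @param net A `"perceptron"`.
#' @param x Input matrix (samples in rows) or vector.
#' @param desired Target vector, one value per sample, in (0, 1).
#' @return List with `dW` and `db` (same shapes as the network), plus the
#'   batch `loss` and `output`.
#' @export
net_gradients <- function(net, x, desired) {
  fw <- net_forward(net, x)
  acts <- fw$activations
  M <- length(net$weights)
  if (length(fw$output) != length(desired)) stop("target length mismatch")
  dW <- vector("list", M); db <- vector("list", M)
  aM <- acts[[M + 1]]
  delta <- (aM - matrix(desired, nrow = 1)) * aM * (1 - aM)
  for (m in M:1) {
    dW[[m]] <- delta %*% t(acts[[m]])
    db[[m]] <- rowSums(delta)
    if (m > 1) {
      am <- acts[[m]]
      delta <- (t(net$weights[[m]]) %*% delta) * am * (1 - am)
    }
  }
  list(dW = dW, db = db, loss = net_loss(fw$output, desired),
       output = fw$output)
}

#' Train a network by batch gradient descent with momentum
#'
#' Full-batch updates `w <- w - eta1 * dE/dw + momentum * previous_step`
#' (and `eta2` for biases), with bold-driver rate adaptation: a step that
#' does not increase E is accepted and both rates grow by 1.05; a step
#' that increases E is rejected (weights restored, momentum cleared) and
#' the rates are halved. Training stops when E reaches `tolerance`, after
#' `max_epochs` attempts, or when both rates fall below `rate_floor`.
#' The recorded error trajectory (accepted steps) is non-increasing.
#'
#' @param net A `"perceptron"` (e.g. from [init_network()]).
#' @param x Training inputs, samples in rows, values in \[0, 1\].
#' @param desired Targets in (0, 1), one per sample.
#' @param config Optional [network_config()]; defaults to `net$config`.
#' @return List with `net` (trained network) and `result` (class
#'   `"train_result"`: `final_error`, `epochs_run`, `error_trajectory`).
#' @export
train_network <- function(net, x, desired, config = net$config) {
  stopifnot(inherits(net, "perceptron"))
  if (is.null(dim(x))) x <- matrix(x, nrow = length(desired))
  if (nrow(x) == 0) stop("empty training set")
  if (any(desired <= 0 | desired >= 1))
    stop("targets must lie strictly inside (0, 1)")
  eta_w <- config$eta_w; eta_b <- config$eta_b
  mom <- config$momentum
  g <- net_gradients(net, x, desired)
  E <- g$loss
  traj <- E
  if (E <= config$tolerance) {
    return(list(net = net,
                result = structure(list(final_error = E, epochs_run = 0L,
                                        error_trajectory = traj),
                                   class = "train_result")))
  }
  M <- length(net$weights)
  vW <- lapply(net$weights, function(w) w * 0)
  vb <- lapply(net$biases, function(b) b * 0)
  epochs <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    epochs <- epoch
    oldW <- net$weights; oldb <- net$biases
    for (m in seq_len(M)) {
      vW[[m]] <- mom * vW[[m]] - eta_w * g$dW[[m]]
      vb[[m]] <- mom * vb[[m]] - eta_b * g$db[[m]]
      net$weights[[m]] <- net$weights[[m]] + vW[[m]]
      net$biases[[m]] <- net$biases[[m]] + vb[[m]]
    }
    g_new <- net_gradients(net, x, desired)
    if (g_new$loss <= E) {
      E <- g_new$loss
      traj <- c(traj, E)
      g <- g_new
      eta_w <- eta_w * 1.05
      eta_b <- eta_b * 1.05
      if (E <= config$tolerance) break
    } else {
      net$weights <- oldW
      net$biases <- oldb
      for (m in seq_len(M)) { vW[[m]] <- vW[[m]] * 0; vb[[m]] <- vb[[m]] * 0 }
      eta_w <- eta_w / 2
      eta_b <- eta_b / 2
      if (eta_w < config$rate_floor && eta_b < config$rate_floor) break
    }
  }
  list(net = net,
       result = structure(list(final_error = E, epochs_run = epochs,
                               error_trajectory = traj),
                          class = "train_result"))
}

#' Network score for one input
#'
#' Deterministic forward-pass output in (0, 1).
#'
#' @param net A `"perceptron"`.
#' @param x Input vector (or matrix of samples in rows).
#' @return Numeric score(s) in (0, 1).
#' @export
predict_score <- function(net, x) net_forward(net, x)$output

#' Serialise / restore a network as JSON
#'
#' Full double precision is kept so that `load_network(save_network(net))`
#' reproduces the network bit for bit.
#'
#' @param net A `"perceptron"`.
#' @param path JSON output path.
#' @return `path` invisibly (`save_network`); a `"perceptron"`
#'   (`load_network`).
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "perceptron"))
  obj <- list(layer_sizes = net$config$layer_sizes,
              weights = lapply(net$weights, function(w)
                list(nrow = nrow(w), ncol = ncol(w), data = as.vector(t(w)))),
              biases = net$biases,
              config = unclass(net$config))
  # I(17) = 17 significant digits, enough to reproduce every double exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfgl <- lapply(obj$config, unlist)
  cfg <- network_config(layer_sizes = cfgl$layer_sizes, eta_w = cfgl$eta_w,
                        eta_b = cfgl$eta_b, momentum = cfgl$momentum,
                        tolerance = cfgl$tolerance, init_low = cfgl$init_low,
                        init_high = cfgl$init_high,
                        max_epochs = cfgl$max_epochs,
                        rate_floor = cfgl$rate_floor, seed = cfgl$seed)
  weights <- lapply(obj$weights, function(wl)
    matrix(unlist(wl$data), nrow = unlist(wl$nrow), ncol = unlist(wl$ncol),
           byrow = TRUE))
  biases <- lapply(obj$biases, function(b) as.numeric(unlist(b)))
  structure(list(weights = weights, biases = biases, config = cfg),
            class = "perceptron")
}

#' @export
print.perceptron <- function(x, ...) {
  cat("Sigmoid perceptron:", paste(x$config$layer_sizes, collapse = "-"),
      "architecture\n")
  invisible(x)
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("Training: %d epochs, E %.3g -> %.3g\n", x$epochs_run,
              x$error_trajectory[1], x$final_error))
  invisible(x)
}
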