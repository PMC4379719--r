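# Single-hidden-layer feed-forward network. The hidden layer computes
#   z[t] = f(a_t + sum_j w1[t, j] x_j),   t = 1..s,
# with f either tanh or the identity, and the output neuron returns
#   yhat = g(b + sum_t w2[t] z[t])
# with g the identity. Training minimizes the averaged mean squared error
# plus an L2 weight-decay penalty on the connection weights (biases are not
# penalized) by full-batch gradient descent with momentum.

#' Network architecture
#'
#' @param n_inputs Number of covariates per individual.
#' @param n_hidden Number of hidden neurons s (>= 1; grids up to 20 are the
#'   usual search range).
#' @param hidden_activation `"tanh"` (non-linear) or `"identity"` (the
#'   network then performs a multiple linear regression).
#' @return Object of class `ann_architecture`.
#' @export
ann_architecture <- function(n_inputs, n_hidden = 1L,
                             hidden_activation = c("tanh", "identity")) {
  hidden_activation <- match.arg(hidden_activation)
  structure(
    list(
      n_inputs = assert_count(n_inputs, "n_inputs", 1L),
      n_hidden = assert_count(n_hidden, "n_hidden", 1L),
      hidden_activation = hidden_activation,
      output_activation = "identity"
    ),
    class = "ann_architecture"
  )
}

#' Training configuration
#'
#' Defaults: learning rate 0.01, momentum 0.9, weight decay 0.01, at most
#' 1000 iterations, stop early once the training aMSE drops to 1e-3 (on the
#' normalized phenotype scale), weights initialized uniformly on
#' \[-0.1, 0.1\].
#'
#' @param learning_rate Positive step size of gradient descent.
#' @param momentum Momentum coefficient in \[0, 1).
#' @param weight_decay Non-negative L2 penalty on connection weights.
#' @param max_iterations Iteration cap (the "early stopping" rule).
#' @param amse_tolerance Training-error threshold that also stops training.
#' @param init_range Half-width of the symmetric uniform init interval.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.01, momentum = 0.9,
                            weight_decay = 0.01, max_iterations = 1000L,
                            amse_tolerance = 1e-3, init_range = 0.1,
                            seed = 1L) {
  assert_scalar_number(learning_rate, "learning_rate", lower = 1e-300)
  assert_scalar_number(momentum, "momentum", 0, 1 - 1e-12)
  assert_scalar_number(weight_decay, "weight_decay", 0)
  assert_scalar_number(amse_tolerance, "amse_tolerance", lower = 1e-300)
  assert_scalar_number(init_range, "init_range", lower = 0)
  structure(
    list(
      learning_rate = learning_rate, momentum = momentum,
      weight_decay = weight_decay,
      max_iterations = assert_count(max_iterations, "max_iterations", 0L),
      amse_tolerance = amse_tolerance, init_range = init_range,
      seed = as.integer(seed)
    ),
    class = "training_config"
  )
}

#' Random weight initialization
#'
#' Every weight and bias is drawn i.i.d. uniform on
#' \[-init_range, init_range\] under the config seed, so runs are exactly
#' reproducible and different seeds give the distinct initializations that
#' repeated cross-validation runs rely on.
#'
#' @param arch An [ann_architecture()].
#' @param config A [training_config()].
#' @return Object of class `ann_weights`: list with `w1` (s x n_inputs),
#'   `a` (s), `w2` (s), `b` (scalar).
#' @export
init_weights <- function(arch, config) {
  stopifnot(inherits(arch, "ann_architecture"), inherits(config, "training_config"))
  s <- arch$n_hidden
  p <- arch$n_inputs
  r <- config$init_range
  withr::with_seed(config$seed, {
    list(
      w1 = matrix(runif(s * p, -r, r), s, p),
      a = runif(s, -r, r),
      w2 = runif(s, -r, r),
      b = runif(1, -r, r)
    )
  }) -> w
  structure(w, class = "ann_weights")
}

activation_fun <- function(name) {
  switch(name, tanh = tanh, identity = identity,
         stop_gpnet(sprintf("unknown activation '%s'.", name), "gpnet_validation_error"))
}

check_input_matrix <- function(x, arch) {
  x <- as.matrix(x)
  if (ncol(x) != arch$n_inputs) {
    stop_gpnet(sprintf("input has %d columns but the architecture expects %d.",
                       ncol(x), arch$n_inputs), "gpnet_validation_error")
  }
  storage.mode(x) <- "double"
  x
}

# Batch forward pass; returns hidden activations Z (n x s) and predictions.
forward_batch <- function(weights, arch, x) {
  f <- activation_fun(arch$hidden_activation)
  h <- sweep(x %*% t(weights$w1), 2L, weights$a, `+`)
  z <- f(h)
  list(z = z, yhat = as.numeric(z %*% weights$w2 + weights$b))
}

#' Forward pass for a single individual
#'
#' @param weights An `ann_weights`.
#' @param arch The matching [ann_architecture()].
#' @param x Covariate vector of length `n_inputs`.
#' @return The predicted (normalized-scale) phenotype, a single number.
#' @export
ann_forward <- function(weights, arch, x) {
  if (length(x) != arch$n_inputs) {
    stop_gpnet("covariate vector length does not match the architecture.",
               "gpnet_validation_error")
  }
  forward_batch(weights, arch, matrix(as.numeric(x), nrow = 1))$yhat
}

#' Averaged mean squared error
#'
#' Mean over samples of the squared difference between predicted and
#' observed values — the training criterion and stopping quantity,
#' evaluated on the normalized phenotype scale during training.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return A single non-negative number.
#' @export
amse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 1) {
    stop_gpnet("predicted and observed must have equal length >= 1.",
               "gpnet_validation_error")
  }
  mean((predicted - observed)^2)
}

#' Exact gradient of the regularized training objective
#'
#' Reverse-mode (back-propagation) gradient of
#' aMSE(forward(X), y) + lambda * (||w1||^2 + ||w2||^2)
#' with respect to all weights and biases; biases are excluded from the
#' decay term. Matches central finite differences to high accuracy.
#'
#' @param weights An `ann_weights`.
#' @param arch The matching [ann_architecture()].
#' @param x Covariate matrix (batch x n_inputs).
#' @param y Observed values, length = batch size.
#' @param lambda Non-negative weight-decay coefficient.
#' @return List with the same shapes as `weights`.
#' @export
backprop_gradient <- function(weights, arch, x, y, lambda = 0) {
  x <- check_input_matrix(x, arch)
  if (nrow(x) != length(y) || length(y) < 1) {
    stop_gpnet("batch size mismatch between x and y.", "gpnet_validation_error")
  }
  n <- nrow(x)
  fwd <- forward_batch(weights, arch, x)
  dyhat <- 2 * (fwd$yhat - y) / n                    # d aMSE / d yhat
  dz <- outer(dyhat, weights$w2)                     # n x s
  dh <- if (arch$hidden_activation == "tanh") dz * (1 - fwd$z^2) else dz
  list(
    w1 = crossprod(dh, x) + 2 * lambda * weights$w1, # s x p
    a = colSums(dh),
    w2 = as.numeric(crossprod(fwd$z, dyhat)) + 2 * lambda * weights$w2,
    b = sum(dyhat)
  )
}
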