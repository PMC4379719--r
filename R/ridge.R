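# Closed-form ridge regression oracle and the quasi-GBLUP benchmark
# configuration. A one-hidden-neuron network with identity activations fed
# the genomic relationship matrix performs a multiple linear regression on
# relationship covariates; with G proportional to XX' that model corresponds
# to GBLUP, itself equivalent to ridge regression on markers. The
# closed-form solver provides the independent reference the iteratively
# trained benchmark is compared against.

#' Closed-form ridge regression with unpenalized intercept
#'
#' Solves min_b,beta sum_i (y_i - b - x_i beta)^2 + lambda ||beta||^2 via
#' the centered normal equations; the intercept is not shrunk.
#'
#' @param x_train Covariate matrix (n x p).
#' @param y_train Response vector, length n.
#' @param lambda Non-negative penalty on the sum-of-squares scale. `lambda
#'   = 0` requires a full-column-rank problem.
#' @param x_test Optional matrix for predictions.
#' @return Object of class `ridge_solution`: list with `coefficients`,
#'   `intercept`, `lambda`, `fitted` (train predictions) and `predictions`
#'   (for `x_test`, if given).
#' @export
ridge_oracle <- function(x_train, y_train, lambda, x_test = NULL) {
  x_train <- as.matrix(x_train)
  if (nrow(x_train) != length(y_train)) {
    stop_gpnet("x_train and y_train sizes differ.", "gpnet_validation_error")
  }
  assert_scalar_number(lambda, "lambda", 0)
  xm <- colMeans(x_train)
  ym <- mean(y_train)
  xc <- sweep(x_train, 2L, xm)
  a <- crossprod(xc) + diag(lambda, ncol(x_train))
  beta <- tryCatch(
    solve(a, crossprod(xc, y_train - ym)),
    error = function(e) {
      stop_gpnet("singular ridge system; use lambda > 0 for rank-deficient covariates.",
                 "gpnet_validation_error")
    }
  )
  beta <- as.numeric(beta)
  intercept <- ym - sum(xm * beta)
  out <- list(
    coefficients = beta, intercept = intercept, lambda = lambda,
    fitted = as.numeric(x_train %*% beta + intercept)
  )
  if (!is.null(x_test)) {
    out$predictions <- as.numeric(as.matrix(x_test) %*% beta + intercept)
  }
  structure(out, class = "ridge_solution")
}

#' The quasi-GBLUP benchmark configuration
#'
#' One hidden neuron with identity activations in both layers, fed the
#' genomic relationship matrix: the network then performs a multiple linear
#' regression whose hidden-layer weights act as regression coefficients,
#' approximating GBLUP. This configuration is the benchmark arm of every
#' experiment.
#'
#' @param n_inputs Number of covariates (= n individuals when the input is G).
#' @return List with `arch` (the [ann_architecture()]) and `input_kind`
#'   (`"G"`).
#' @export
quasi_gblup_config <- function(n_inputs) {
  list(
    arch = ann_architecture(n_inputs, n_hidden = 1L, hidden_activation = "identity"),
    input_kind = "G"
  )
}

#' Match network weight decay to a ridge penalty
#'
#' The network objective penalizes lambda * ||w||^2 on the averaged (per
#' sample) squared-error scale, while [ridge_oracle()] penalizes on the
#' summed scale; equating the two objectives maps a decay coefficient
#' lambda_ann to lambda_ridge = n_train * lambda_ann.
#'
#' @param weight_decay The network's decay coefficient.
#' @param n_train Training-set size.
#' @return The equivalent ridge lambda.
#' @export
matched_ridge_lambda <- function(weight_decay, n_train) {
  assert_scalar_number(weight_decay, "weight_decay", 0)
  weight_decay * assert_count(n_train, "n_train", 1L)
}

#' Affine coefficients realized by an identity-activation network
#'
#' Any identity-activation network computes an affine map; this constructs
#' its coefficients explicitly: slope = w1' w2, intercept = b + w2'a, so
#' predictions equal `intercept + X %*% slope` exactly.
#'
#' @param weights An `ann_weights` (or the `weights` of a `gpnet_ann`).
#' @return List with `intercept` and `slope` (length n_inputs).
#' @export
linear_coefficients <- function(weights) {
  list(
    intercept = weights$b + sum(weights$w2 * weights$a),
    slope = as.numeric(crossprod(weights$w1, weights$w2))
  )
}
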