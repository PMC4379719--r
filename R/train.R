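# Training loop: full-batch gradient descent with momentum on the
# regularized aMSE objective, stopping at the iteration cap or once the
# training aMSE reaches the tolerance.

#' Train a network by regularized back-propagation
#'
#' Runs full-batch gradient descent with momentum from a fresh random
#' initialization. Training stops when `max_iterations` is reached or when
#' the training aMSE (computed after each update, on the scale of `y` —
#' normally the normalized phenotype scale) drops to `amse_tolerance`,
#' whichever comes first; if both trigger on the same iteration the
#' tolerance is reported as the stop reason.
#'
#' @param x Covariate matrix (individuals x inputs), e.g. the `values` of a
#'   [build_input()] result.
#' @param y Response vector on the normalized scale.
#' @param arch An [ann_architecture()] with `n_inputs = ncol(x)`.
#' @param config A [training_config()].
#' @return Object of class `gpnet_ann`: list with `weights`, `arch`,
#'   `config`, `trace` (tibble: iteration, amse), `stop_reason`
#'   (`"max_iterations"` or `"amse_threshold"`), `n_train`.
#' @export
train_ann <- function(x, y, arch, config = training_config()) {
  stopifnot(inherits(arch, "ann_architecture"), inherits(config, "training_config"))
  x <- check_input_matrix(x, arch)
  if (nrow(x) != length(y) || length(y) < 1) {
    stop_gpnet("x and y must describe the same non-empty training set.",
               "gpnet_validation_error")
  }
  w <- init_weights(arch, config)
  vel <- list(w1 = w$w1 * 0, a = w$a * 0, w2 = w$w2 * 0, b = 0)
  lr <- config$learning_rate
  mom <- config$momentum
  lambda <- config$weight_decay

  trace <- numeric(config$max_iterations)
  stop_reason <- "max_iterations"
  n_iter <- 0L
  while (n_iter < config$max_iterations) {
    n_iter <- n_iter + 1L
    g <- backprop_gradient(w, arch, x, y, lambda)
    for (nm in c("w1", "a", "w2", "b")) {
      vel[[nm]] <- mom * vel[[nm]] - lr * g[[nm]]
      w[[nm]] <- w[[nm]] + vel[[nm]]
    }
    err <- amse(forward_batch(w, arch, x)$yhat, y)
    if (!is.finite(err)) {
      stop_gpnet(sprintf("training diverged at iteration %d (non-finite aMSE); reduce the learning rate.",
                         n_iter), "gpnet_divergence_error")
    }
    trace[n_iter] <- err
    if (err <= config$amse_tolerance) {
      stop_reason <- "amse_threshold"
      break
    }
  }
  structure(
    list(
      weights = w, arch = arch, config = config,
      trace = tibble::tibble(iteration = seq_len(n_iter), amse = trace[seq_len(n_iter)]),
      stop_reason = stop_reason, n_train = nrow(x)
    ),
    class = "gpnet_ann"
  )
}

#' Predict from a trained network
#'
#' Row-wise application of the forward map; no refitting.
#'
#' @param object A `gpnet_ann` from [train_ann()].
#' @param newdata Covariate matrix with `n_inputs` columns.
#' @param ... Unused.
#' @return Numeric vector of predictions on the training (normalized) scale.
#' @export
predict.gpnet_ann <- function(object, newdata, ...) {
  newdata <- check_input_matrix(newdata, object$arch)
  forward_batch(object$weights, object$arch, newdata)$yhat
}

#' @export
print.gpnet_ann <- function(x, ...) {
  final <- if (nrow(x$trace)) x$trace$amse[nrow(x$trace)] else NA_real_
  cat(sprintf(
    "<gpnet_ann> %s net, s = %d, %d inputs; %d iterations (%s), final aMSE = %.4g\n",
    x$arch$hidden_activation, x$arch$n_hidden, x$arch$n_inputs,
    nrow(x$trace), x$stop_reason, final
  ))
  invisible(x)
}

#' Tidy the weights of a trained network
#'
#' One row per parameter, in broom's long format.
#'
#' @param x A `gpnet_ann`.
#' @param ... Unused.
#' @return Tibble with columns `layer` (`input_hidden`, `hidden_bias`,
#'   `hidden_output`, `output_bias`), `neuron`, `input`, `estimate`.
#' @export
tidy.gpnet_ann <- function(x, ...) {
  w <- x$weights
  s <- x$arch$n_hidden
  p <- x$arch$n_inputs
  dplyr::bind_rows(
    tibble::tibble(
      layer = "input_hidden",
      neuron = rep(seq_len(s), times = p),
      input = rep(seq_len(p), each = s),
      estimate = as.numeric(w$w1)
    ),
    tibble::tibble(layer = "hidden_bias", neuron = seq_len(s),
                   input = NA_integer_, estimate = w$a),
    tibble::tibble(layer = "hidden_output", neuron = seq_len(s),
                   input = NA_integer_, estimate = w$w2),
    tibble::tibble(layer = "output_bias", neuron = NA_integer_,
                   input = NA_integer_, estimate = w$b)
  )
}

#' One-row training summary of a fitted network
#'
#' @param x A `gpnet_ann`.
#' @param ... Unused.
#' @return Tibble with `n_train`, `n_hidden`, `hidden_activation`,
#'   `n_iterations`, `final_amse`, `stop_reason`.
#' @export
glance.gpnet_ann <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_hidden = x$arch$n_hidden,
    hidden_activation = x$arch$hidden_activation,
    n_iterations = nrow(x$trace),
    final_amse = if (nrow(x$trace)) x$trace$amse[nrow(x$trace)] else NA_real_,
    stop_reason = x$stop_reason
  )
}

#' Training-curve plot for a fitted network
#'
#' @param object A `gpnet_ann`.
#' @param ... Unused.
#' @return A ggplot of training aMSE against iteration (log10 y scale).
#' @export
autoplot.gpnet_ann <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$iteration, y = .data$amse)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "training aMSE",
                  title = sprintf("%s network, %d hidden neurons (stopped: %s)",
                                  object$arch$hidden_activation,
                                  object$arch$n_hidden, object$stop_reason)) +
    ggplot2::theme_minimal()
}

#' Small grid search for the learning rate
#'
#' Mirrors the pre-processing step in which the optimizer's parameters are
#' adjusted once per data set before all cross-validation runs. With
#' `validation_frac = 0` each candidate learning rate is tried for
#' `probe_iterations` full-batch iterations and the one reaching the lowest
#' finite training aMSE wins. With `validation_frac > 0` a random fraction
#' of the samples is held out of the probe fits and the rate with the best
#' held-out Pearson correlation wins instead — the appropriate criterion
#' when the rate is tuned for predictive quality rather than fit.
#'
#' @param x,y Training data as in [train_ann()] (`y` on the normalized
#'   scale).
#' @param arch An [ann_architecture()].
#' @param config Base [training_config()]; only the learning rate varies.
#'   Its seed fixes the probe initializations and the validation split.
#' @param rates Candidate learning rates.
#' @param probe_iterations Iterations per probe.
#' @param validation_frac Fraction of samples held out for scoring (0 =
#'   score on the training aMSE).
#' @return Tibble (rate, final_amse, validation_r, diverged) sorted best
#'   first, with the winning rate in attribute `"best_rate"`.
#' @export
grid_search_lr <- function(x, y, arch, config = training_config(),
                           rates = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5),
                           probe_iterations = 100L, validation_frac = 0) {
  assert_scalar_number(validation_frac, "validation_frac", 0, 0.9)
  x <- check_input_matrix(x, arch)
  n <- nrow(x)
  val_idx <- integer(0)
  if (validation_frac > 0) {
    val_idx <- withr::with_seed(config$seed,
                                sample.int(n, max(2L, round(validation_frac * n))))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  res <- purrr::map_dfr(rates, function(r) {
    cfg <- config
    cfg$learning_rate <- r
    cfg$max_iterations <- as.integer(probe_iterations)
    fit <- tryCatch(train_ann(x[tr_idx, , drop = FALSE], y[tr_idx], arch, cfg),
                    gpnet_divergence_error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(rate = r, final_amse = Inf,
                            validation_r = -Inf, diverged = TRUE))
    }
    val_r <- NA_real_
    if (length(val_idx) > 0) {
      pred <- predict(fit, x[val_idx, , drop = FALSE])
      val_r <- if (sd(pred) == 0 || sd(y[val_idx]) == 0) -Inf else cor(y[val_idx], pred)
    }
    tibble::tibble(rate = r, final_amse = fit$trace$amse[nrow(fit$trace)],
                   validation_r = val_r, diverged = FALSE)
  })
  res <- if (validation_frac > 0) {
    dplyr::arrange(res, dplyr::desc(.data$validation_r))
  } else {
    dplyr::arrange(res, .data$final_amse)
  }
  attr(res, "best_rate") <- res$rate[1]
  res
}
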