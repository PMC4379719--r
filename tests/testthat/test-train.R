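test_that("zero-iteration training returns the initialization untouched", {
  arch <- ann_architecture(3, 2)
  cfg <- training_config(max_iterations = 0, seed = 4)
  set.seed(1)
  fit <- train_ann(matrix(rnorm(15), 5, 3), rnorm(5), arch, cfg)
  expect_equal(nrow(fit$trace), 0)
  expect_equal(fit$stop_reason, "max_iterations")
  expect_equal(fit$weights, init_weights(arch, cfg))
})

test_that("a linear net reaches the aMSE threshold on a noiseless linear target", {
  set.seed(21)
  x <- matrix(rnorm(200), 50, 4)
  beta <- c(0.5, -0.3, 0.2, 0.1)
  y <- as.numeric(x %*% beta)
  arch <- ann_architecture(4, 1, "identity")
  cfg <- training_config(learning_rate = 0.05, weight_decay = 0, seed = 2)
  fit <- train_ann(x, y, arch, cfg)
  expect_equal(fit$stop_reason, "amse_threshold")
  expect_lt(nrow(fit$trace), 1000)
  expect_lte(fit$trace$amse[nrow(fit$trace)], 1e-3)
})

test_that("gradient descent without momentum is non-increasing on a convex problem", {
  set.seed(22)
  x <- matrix(rnorm(120), 30, 4)
  y <- as.numeric(x %*% c(1, -1, 0.5, 0)) + rnorm(30, sd = 0.2)
  cfg <- training_config(learning_rate = 0.01, momentum = 0, weight_decay = 0.01,
                         max_iterations = 200, amse_tolerance = 1e-12, seed = 3)
  fit <- train_ann(x, y, ann_architecture(4, 1, "identity"), cfg)
  expect_true(all(diff(fit$trace$amse) <= 1e-12))
})

test_that("an excessive learning rate raises a divergence error naming the iteration", {
  set.seed(23)
  x <- matrix(rnorm(500, sd = 10), 50, 10)
  y <- rnorm(50)
  cfg <- training_config(learning_rate = 50, seed = 1)
  expect_error(train_ann(x, y, ann_architecture(10, 3, "tanh"), cfg),
               "iteration", class = "gpnet_divergence_error")
})

test_that("prediction applies the forward map row-wise without refitting", {
  set.seed(24)
  x <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  fit <- train_ann(x, y, ann_architecture(3, 2, "tanh"),
                   training_config(max_iterations = 20, seed = 5))
  # single row equals forward on that row
  expect_equal(predict(fit, x[3, , drop = FALSE]),
               ann_forward(fit$weights, fit$arch, x[3, ]))
  # constant (zero) network predicts its output bias
  w0 <- unflatten_weights(rep(0, 3 * 2 + 2 + 2 + 1), 2, 3)
  w0$b <- 1.7
  fit0 <- fit; fit0$weights <- w0
  expect_equal(predict(fit0, x), rep(1.7, 20))
})

test_that("identity-activation networks are exactly affine maps", {
  set.seed(25)
  arch <- ann_architecture(6, 4, "identity")
  w <- init_weights(arch, training_config(seed = 9, init_range = 2))
  x <- matrix(rnorm(180), 30, 6)
  fit <- list(weights = w, arch = arch)
  class(fit) <- "gpnet_ann"
  lc <- linear_coefficients(w)
  affine <- as.numeric(x %*% lc$slope + lc$intercept)
  expect_equal(predict(fit, x), affine, tolerance = 1e-12)
})

test_that("the full-batch trajectory is invariant to sample order", {
  set.seed(26)
  x <- matrix(rnorm(80), 20, 4)
  y <- rnorm(20)
  cfg <- training_config(max_iterations = 50, seed = 6)
  arch <- ann_architecture(4, 3, "tanh")
  fit1 <- train_ann(x, y, arch, cfg)
  perm <- sample(20)
  fit2 <- train_ann(x[perm, ], y[perm], arch, cfg)
  expect_equal(fit2$weights, fit1$weights, tolerance = 1e-12)
  expect_equal(fit2$trace$amse, fit1$trace$amse, tolerance = 1e-12)
})

test_that("tidy and glance expose the fitted network in broom style", {
  set.seed(27)
  fit <- train_ann(matrix(rnorm(30), 10, 3), rnorm(10),
                   ann_architecture(3, 2, "tanh"),
                   training_config(max_iterations = 15, seed = 7))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2 * 3 + 2 + 2 + 1)
  expect_setequal(unique(td$layer),
                  c("input_hidden", "hidden_bias", "hidden_output", "output_bias"))
  gl <- glance(fit)
  expect_equal(gl$n_iterations, 15)
  expect_equal(gl$stop_reason, "max_iterations")
})

test_that("the learning-rate grid identifies divergent rates and picks a finite one", {
  set.seed(28)
  x <- matrix(rnorm(200, sd = 5), 40, 5)
  y <- as.numeric(x %*% rnorm(5))
  res <- grid_search_lr(x, y / max(abs(y)), ann_architecture(5, 1, "identity"),
                        training_config(seed = 8),
                        rates = c(0.001, 0.01, 10), probe_iterations = 50)
  expect_true(res$diverged[res$rate == 10][1])
  expect_false(attr(res, "best_rate") == 10)
  # validation-based selection returns a rate from the candidate set
  res_v <- grid_search_lr(x, y / max(abs(y)), ann_architecture(5, 2, "tanh"),
                          training_config(seed = 8),
                          rates = c(0.001, 0.01, 0.1), probe_iterations = 50,
                          validation_frac = 0.25)
  expect_true(attr(res_v, "best_rate") %in% c(0.001, 0.01, 0.1))
})
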