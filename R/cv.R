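# Repeated k-fold cross-validation scored by Pearson correlation on the
# held-out fold. Each of the `repeats` randomizations cuts a fresh uniform
# permutation of the samples into k near-equal folds, so k x repeats
# train/test evaluations are performed in total (the canonical 5-fold,
# 20-repeat design yields 100 runs).

#' Build a repeated k-fold cross-validation plan
#'
#' Within each repeat the folds partition all n samples and their sizes
#' differ by at most one (the remainder is spread one-per-fold from the
#' first fold on). The plan is a pure function of the seed.
#'
#' @param n Number of samples.
#' @param k Number of folds (default 5).
#' @param repeats Number of fold randomizations (default 20).
#' @param seed Integer seed.
#' @return Object of class `cv_plan`: tibble with columns `rep`, `sample`,
#'   `fold`, plus attributes `n`, `k`, `repeats`, `seed`.
#' @export
make_folds <- function(n, k = 5L, repeats = 20L, seed = 1L) {
  n <- assert_count(n, "n", 2L)
  k <- assert_count(k, "k", 2L)
  repeats <- assert_count(repeats, "repeats", 1L)
  if (n < k) stop_gpnet("cannot split n samples into more than n folds.",
                        "gpnet_validation_error")
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  labels <- rep(seq_len(k), times = sizes)
  plan <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(repeats), function(r) {
      tibble::tibble(rep = r, sample = sample.int(n), fold = labels)
    })
  })
  plan <- dplyr::arrange(plan, .data$rep, .data$sample)
  structure(plan, class = c("cv_plan", class(plan)),
            n = n, k = k, repeats = repeats, seed = as.integer(seed))
}

#' Pearson product-moment correlation
#'
#' The predictive-ability score: correlation between observed and predicted
#' phenotypes on a held-out fold. Constant inputs make the correlation
#' undefined and raise an error rather than silently returning 0.
#'
#' @param a,b Equal-length numeric vectors (length >= 2, non-constant).
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop_gpnet("pearson_r needs two equal-length vectors of length >= 2.",
               "gpnet_validation_error")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop_gpnet("undefined correlation: at least one vector is constant.",
               "gpnet_undefined_correlation")
  }
  as.numeric(cor(a, b))
}

#' Run repeated k-fold cross-validation of a network
#'
#' For every (repeat, fold) pair the network is trained on the k-1 training
#' folds and scored by [pearson_r()] between its predictions and the
#' observed phenotypes of the held-out fold. Phenotype normalization
#' statistics (mu_y, max_y) are recomputed on the training folds only, so
#' held-out phenotypes never influence training. Genomic inputs (X, G or
#' UD) are taken as given: relationship and score matrices are built once
#' from the genotype panel, which involves no phenotype information. Each
#' run re-initializes the weights with its own seed derived from
#' (seed, repeat, fold), so all k x repeats initializations are distinct.
#'
#' @param x Input matrix (individuals x covariates), e.g.
#'   `build_input(...)$values`.
#' @param y Raw-scale phenotype vector (length nrow(x)), or a data frame
#'   with `sample_id`/`value` columns.
#' @param arch An [ann_architecture()].
#' @param config A [training_config()]; its `seed` is the master seed.
#' @param plan A [make_folds()] plan for `nrow(x)` samples (built from the
#'   master seed if omitted).
#' @param k,repeats Used only when `plan` is omitted.
#' @return Object of class `gpnet_cv`: list with `runs` (tibble: rep, fold,
#'   r, n_test, stop_reason, error), `mean_r`, `var_r` (population variance
#'   over runs, as predictive-ability tables report it), `arch`, `config`,
#'   `plan`.
#' @export
run_cv <- function(x, y, arch, config = training_config(), plan = NULL,
                   k = 5L, repeats = 20L) {
  x <- check_input_matrix(x, arch)
  if (is.data.frame(y)) y <- y$value
  if (length(y) != nrow(x)) {
    stop_gpnet("phenotype length must match the number of input rows.",
               "gpnet_validation_error")
  }
  plan <- plan %||% make_folds(nrow(x), k = k, repeats = repeats, seed = config$seed)
  if (attr(plan, "n") != nrow(x)) {
    stop_gpnet("cross-validation plan was built for a different sample size.",
               "gpnet_validation_error")
  }
  k <- attr(plan, "k")
  repeats <- attr(plan, "repeats")

  grid <- tidyr::expand_grid(rep = seq_len(repeats), fold = seq_len(k))
  runs <- purrr::pmap_dfr(grid, function(rep, fold) {
    test_idx <- plan$sample[plan$rep == rep & plan$fold == fold]
    train_idx <- setdiff(seq_len(nrow(x)), test_idx)
    run_cfg <- config
    run_cfg$seed <- as.integer(derive_seed(config$seed, rep, fold))
    out <- tryCatch({
      norm <- normalize_phenotype(y[train_idx])
      fit <- train_ann(x[train_idx, , drop = FALSE], norm$y_star, arch, run_cfg)
      pred <- denormalize_phenotype(norm, predict(fit, x[test_idx, , drop = FALSE]))
      tibble::tibble(
        rep = rep, fold = fold,
        r = pearson_r(y[test_idx], pred),
        n_test = length(test_idx),
        stop_reason = fit$stop_reason,
        error = NA_character_
      )
    }, gpnet_error = function(e) {
      tibble::tibble(rep = rep, fold = fold, r = NA_real_,
                     n_test = length(test_idx), stop_reason = NA_character_,
                     error = conditionMessage(e))
    })
    out
  })

  n_failed <- sum(!is.na(runs$error))
  if (n_failed > 0.1 * nrow(runs)) {
    stop_gpnet(sprintf(
      "%d of %d cross-validation runs failed (first: %s); aborting.",
      n_failed, nrow(runs), runs$error[!is.na(runs$error)][1]
    ), "gpnet_cv_error")
  }
  ok <- runs$r[is.na(runs$error)]
  structure(
    list(
      runs = runs,
      mean_r = mean(ok),
      var_r = mean((ok - mean(ok))^2),
      n_failed = n_failed,
      arch = arch, config = config, plan = plan
    ),
    class = "gpnet_cv"
  )
}

#' @export
print.gpnet_cv <- function(x, ...) {
  cat(sprintf("<gpnet_cv> %d runs (%dx%d-fold): mean r = %.4f (var %.5f)%s\n",
              nrow(x$runs), attr(x$plan, "repeats"), attr(x$plan, "k"),
              x$mean_r, x$var_r,
              if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}

#' Per-run cross-validation results
#' @param x A `gpnet_cv`.
#' @param ... Unused.
#' @return Tibble with one row per (repeat, fold) run.
#' @export
tidy.gpnet_cv <- function(x, ...) x$runs

#' One-row cross-validation summary
#' @param x A `gpnet_cv`.
#' @param ... Unused.
#' @return Tibble with `n_runs`, `mean_r`, `var_r`, `n_failed`.
#' @export
glance.gpnet_cv <- function(x, ...) {
  tibble::tibble(n_runs = nrow(x$runs), mean_r = x$mean_r,
                 var_r = x$var_r, n_failed = x$n_failed)
}

#' Distribution of per-run predictive ability
#'
#' @param object A `gpnet_cv`.
#' @param ... Unused.
#' @return A ggplot: per-run Pearson r by repeat, with the overall mean.
#' @export
autoplot.gpnet_cv <- function(object, ...) {
  ggplot2::ggplot(object$runs, ggplot2::aes(x = factor(.data$rep), y = .data$r)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_r, linetype = 2) +
    ggplot2::labs(x = "repeat", y = "Pearson r (held-out fold)",
                  title = sprintf("mean r = %.3f over %d runs",
                                  object$mean_r, nrow(object$runs))) +
    ggplot2::theme_minimal()
}
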