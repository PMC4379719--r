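# Phenotype normalization to the network's working scale and its exact
# inverse. The network trains on y* = (y - mean(y)) / max(y), which puts
# typical yield-deviation traits approximately into [-1, 1].

#' Normalize a phenotype to the network scale
#'
#' Computes y*_i = (y_i - mu_y) / max_y with mu_y the sample mean and max_y
#' the sample maximum of the raw values, storing both so the transform is
#' exactly invertible. The literal sample-maximum denominator only
#' guarantees an approximate \[-1, 1\] range; `strict = TRUE` divides by
#' max |y - mu_y| instead, which guarantees it.
#'
#' @param y Numeric phenotype vector, or a data frame with columns
#'   `sample_id` and `value`.
#' @param strict Use max absolute deviation as the denominator.
#' @return Object of class `norm_pheno`: list with `y_star`, `mu_y`, `max_y`,
#'   `sample_ids` (or `NULL`).
#' @export
normalize_phenotype <- function(y, strict = FALSE) {
  ids <- NULL
  if (is.data.frame(y)) {
    if (!all(c("sample_id", "value") %in% names(y))) {
      stop_gpnet("phenotype data frame needs `sample_id` and `value` columns.",
                 "gpnet_validation_error")
    }
    ids <- as.character(y$sample_id)
    y <- y$value
  }
  if (!is.numeric(y) || length(y) < 2 || !all(is.finite(y))) {
    stop_gpnet("phenotype must be a finite numeric vector of length >= 2.",
               "gpnet_validation_error")
  }
  if (diff(range(y)) == 0) {
    stop_gpnet("constant phenotype cannot be normalized (untrainable).",
               "gpnet_validation_error")
  }
  mu <- mean(y)
  mx <- if (strict) max(abs(y - mu)) else max(y)
  if (mx == 0) {
    stop_gpnet("normalization denominator max(y) is zero; use strict = TRUE or shift the trait.",
               "gpnet_validation_error")
  }
  if (!strict && mx < 0) {
    stop_gpnet("phenotype maximum is negative; refusing to sign-flip the scale (use strict = TRUE).",
               "gpnet_validation_error")
  }
  structure(
    list(y_star = (y - mu) / mx, mu_y = mu, max_y = mx, sample_ids = ids),
    class = "norm_pheno"
  )
}

#' Back-transform normalized phenotypes (or predictions) to trait units
#'
#' y_i = y*_i * max_y + mu_y. When `values` is omitted the stored normalized
#' phenotype itself is back-transformed; supplying network predictions on
#' the normalized scale returns predictions in trait units. Pearson
#' correlations are invariant under this affine map, so predictive ability
#' does not depend on the reporting scale.
#'
#' @param norm A `norm_pheno`.
#' @param values Optional numeric vector on the normalized scale.
#' @return Numeric vector in original trait units.
#' @export
denormalize_phenotype <- function(norm, values = NULL) {
  stopifnot(inherits(norm, "norm_pheno"))
  v <- values %||% norm$y_star
  v * norm$max_y + norm$mu_y
}

#' @export
print.norm_pheno <- function(x, ...) {
  cat(sprintf("<norm_pheno> n = %d, mu_y = %.4g, max_y = %.4g, range = [%.3f, %.3f]\n",
              length(x$y_star), x$mu_y, x$max_y, min(x$y_star), max(x$y_star)))
  invisible(x)
}
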