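# Shared fixture builders; everything is generated in code.

# genotype tibble from explicit allele-count columns (markers as list entries)
toy_geno <- function(...) {
  cols <- list(...)
  n <- length(cols[[1]])
  geno_tibble(matrix(unlist(cols), nrow = n),
              marker_ids = names(cols) %||% paste0("mk_", seq_along(cols)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coded_geno built directly, bypassing count coding (for hand-arithmetic cases)
manual_coded <- function(X, q) {
  structure(
    list(
      X = X,
      q = stats::setNames(q, paste0("mk_", seq_len(ncol(X)))),
      sample_ids = paste0("ind_", seq_len(nrow(X))),
      marker_ids = paste0("mk_", seq_len(ncol(X))),
      n_imputed = 0L
    ),
    class = "coded_geno"
  )
}

# small simulated dataset for pipeline tests
small_dataset <- function(n = 60, m = 40, h2 = 0.5, seed = 42, ...) {
  cfg <- sim_config(n, m, h2 = h2, n_qtl = min(10L, m), seed = seed, ...)
  simulate_phenotype(simulate_genotypes(cfg), cfg)
}

# flatten / unflatten network weights, used by finite-difference oracles
flatten_weights <- function(w) c(as.numeric(w$w1), w$a, w$w2, w$b)

unflatten_weights <- function(v, s, p) {
  structure(
    list(
      w1 = matrix(v[seq_len(s * p)], s, p),
      a = v[s * p + seq_len(s)],
      w2 = v[s * p + s + seq_len(s)],
      b = v[s * p + 2 * s + 1]
    ),
    class = "ann_weights"
  )
}

# the regularized objective, written independently of backprop_gradient
objective_value <- function(v, s, p, arch, x, y, lambda) {
  w <- unflatten_weights(v, s, p)
  preds <- vapply(seq_len(nrow(x)), function(i) ann_forward(w, arch, x[i, ]), 0)
  mean((preds - y)^2) + lambda * (sum(w$w1^2) + sum(w$w2^2))
}

# central finite differences of the objective
fd_gradient <- function(v, s, p, arch, x, y, lambda, eps = 1e-6) {
  vapply(seq_along(v), function(j) {
    up <- v; up[j] <- up[j] + eps
    dn <- v; dn[j] <- dn[j] - eps
    (objective_value(up, s, p, arch, x, y, lambda) -
       objective_value(dn, s, p, arch, x, y, lambda)) / (2 * eps)
  }, 0)
}

expect_gradient_matches <- function(s, p, n_batch, activation, lambda, seed = 1,
                                    tol = 1e-6) {
  set.seed(seed)
  arch <- ann_architecture(p, s, activation)
  w <- init_weights(arch, training_config(seed = seed))
  x <- matrix(rnorm(n_batch * p), n_batch, p)
  y <- rnorm(n_batch)
  g <- backprop_gradient(w, arch, x, y, lambda)
  gv <- flatten_weights(structure(g, class = "ann_weights"))
  fd <- fd_gradient(flatten_weights(w), s, p, arch, x, y, lambda)
  rel <- abs(gv - fd) / pmax(abs(fd), 1e-4)
  expect_lt(max(rel), tol)
}
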