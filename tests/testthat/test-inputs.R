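test_that("G matches hand arithmetic on pinned cases", {
  # all heterozygous at q = 0.5: centering by 2q-1 = 0 leaves X = 0 -> G = 0
  coded0 <- manual_coded(matrix(0, 3, 4), rep(0.5, 4))
  expect_equal(compute_G(coded0)$G, matrix(0, 3, 3))

  # one marker, X = [1, -1], q = 0.5: W = X, denominator 0.5
  coded1 <- manual_coded(matrix(c(1, -1), 2, 1), 0.5)
  g <- compute_G(coded1)
  expect_equal(g$denominator, 0.5)
  expect_equal(g$G, matrix(c(2, -2, -2, 2), 2, 2))
})

test_that("G is symmetric PSD and invariant to marker order", {
  ds <- small_dataset(n = 40, m = 60, seed = 11)
  coded <- code_genotypes(qc_filter(ds$genotypes))
  g <- compute_G(coded)$G
  expect_identical(g, t(g))
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))

  # permute markers: same G within floating tolerance
  perm <- sample(length(coded$marker_ids))
  coded_p <- coded
  coded_p$X <- coded$X[, perm]
  coded_p$q <- coded$q[perm]
  coded_p$marker_ids <- coded$marker_ids[perm]
  expect_equal(compute_G(coded_p)$G, g, tolerance = 1e-12)
})

test_that("G denominator of an all-fixed panel errors", {
  coded <- manual_coded(matrix(1, 3, 2), c(1, 1))
  expect_error(compute_G(coded), class = "gpnet_validation_error")
})

test_that("mean diagonal of G approaches 1 under Hardy-Weinberg genotypes", {
  cfg <- sim_config(200, 5000, n_qtl = 10, seed = 12)
  coded <- code_genotypes(simulate_genotypes(cfg))
  g <- compute_G(coded)$G
  expect_lt(abs(mean(diag(g)) - 1), 0.1)
})

test_that("UD preserves the Gram matrix and follows the sign convention", {
  # zero matrix -> zero scores
  coded0 <- manual_coded(matrix(0, 3, 2), c(0.5, 0.5))
  pc0 <- compute_UD(coded0)
  expect_equal(pc0$UD, matrix(0, 3, 3), ignore_attr = TRUE)
  expect_equal(pc0$singular_values, c(0, 0, 0))

  # diagonal matrix: singular values [2, 1], UD = X under the sign rule
  codedD <- manual_coded(matrix(c(2, 0, 0, 1), 2, 2), c(0.5, 0.5))
  pcD <- compute_UD(codedD)
  expect_equal(pcD$singular_values, c(2, 1))
  expect_equal(pcD$UD, matrix(c(2, 0, 0, 1), 2, 2), ignore_attr = TRUE)

  # random matrices, both shapes: (UD)(UD)' = XX' to 1e-8 relative
  for (dims in list(c(15, 40), c(30, 10))) {
    set.seed(dims[1])
    x <- matrix(sample(c(-1, 0, 1), prod(dims), replace = TRUE), dims[1], dims[2])
    coded <- manual_coded(x, rep(0.4, dims[2]))
    ud <- compute_UD(coded)$UD
    expect_equal(dim(ud), c(dims[1], dims[1]))
    gram_err <- max(abs(tcrossprod(ud) - tcrossprod(x)))
    expect_lte(gram_err, 1e-8 * max(abs(tcrossprod(x))))
  }

  # sign convention pins the factorization uniquely (distinct singular values)
  set.seed(3)
  x <- matrix(rnorm(50), 10, 5)
  coded <- manual_coded(x, rep(0.4, 5))
  expect_equal(compute_UD(coded)$UD, compute_UD(coded)$UD)
  sv <- svd(x)
  for (j in 1:5) {
    expect_gt(sv$v[which.max(abs(sv$v[, j])), j] * sign(sv$v[which.max(abs(sv$v[, j])), j]), 0)
  }
})

test_that("min-max scaling maps to [-1, 1] and inverts exactly", {
  sc <- minmax_scale(matrix(c(0, 5, 10), 3, 1))
  expect_equal(as.numeric(sc$values), c(-1, 0, 1))

  # constant column -> 0, and unscale restores the constant
  sc2 <- minmax_scale(matrix(3, 3, 1))
  expect_equal(as.numeric(sc2$values), c(0, 0, 0))
  expect_equal(as.numeric(minmax_unscale(sc2)), rep(3, 3))

  # random round trip, both per-column and whole-matrix
  set.seed(4)
  m <- matrix(rnorm(60, sd = 10), 12, 5)
  for (pc in c(TRUE, FALSE)) {
    sc3 <- minmax_scale(m, per_column = pc)
    expect_true(all(sc3$values >= -1 & sc3$values <= 1))
    expect_equal(minmax_unscale(sc3), m, tolerance = 1e-12)
  }

  expect_error(minmax_scale(matrix(c(1, NA), 1, 2)), class = "gpnet_validation_error")
})

test_that("build_input returns scaled matrices for all three kinds", {
  ds <- small_dataset(n = 30, m = 50, seed = 13)
  coded <- code_genotypes(qc_filter(ds$genotypes))
  xin <- build_input(coded, "X")
  expect_identical(xin$values, coded$X)
  for (k in c("G", "UD")) {
    inp <- build_input(coded, k)
    expect_equal(inp$kind, k)
    expect_true(all(inp$values >= -1 & inp$values <= 1))
    expect_equal(dim(inp$values), c(30, 30))
  }
})
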