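test_that("genotype simulation respects Hardy-Weinberg structure and the seed", {
  # MAF fixed at 0.5: mean allele count must be 1 within 3 standard errors
  cfg <- sim_config(400, 300, maf_range = c(0.5, 0.5), n_qtl = 10, seed = 2)
  g <- geno_matrix(simulate_genotypes(cfg))
  se <- sqrt(0.5 / length(g))   # var of one count is 2q(1-q) = 0.5
  expect_lt(abs(mean(g) - 1), 3 * se)

  # determinism: identical config => bit-identical tables
  expect_identical(simulate_genotypes(cfg), simulate_genotypes(cfg))

  # different seed => different table
  cfg2 <- sim_config(400, 300, maf_range = c(0.5, 0.5), n_qtl = 10, seed = 3)
  expect_false(identical(simulate_genotypes(cfg2), simulate_genotypes(cfg)))
})

test_that("sample allele frequencies track the drawn frequencies (binomial CI oracle)", {
  cfg <- sim_config(500, 200, maf_range = c(0.05, 0.5), n_qtl = 10, seed = 1)
  g <- simulate_genotypes(cfg)
  drawn <- attr(g, "true_maf")
  freq <- allele_frequencies(g)
  # exact binomial 99% CI on 2n allele draws, per marker
  lo <- qbinom(0.005, 2 * cfg$n_individuals, drawn) / (2 * cfg$n_individuals)
  hi <- qbinom(0.995, 2 * cfg$n_individuals, drawn) / (2 * cfg$n_individuals)
  inside <- freq$q >= lo & freq$q <= hi
  expect_gte(mean(inside), 0.95)
})

test_that("missing calls appear at the configured rate", {
  cfg <- sim_config(200, 100, missing_rate = 0.1, n_qtl = 5, seed = 4)
  g <- geno_matrix(simulate_genotypes(cfg))
  expect_gt(mean(is.na(g)), 0.08)
  expect_lt(mean(is.na(g)), 0.12)
})

test_that("maf_range outside (0, 0.5] is rejected", {
  expect_error(sim_config(10, 5, maf_range = c(0, 0.5)), class = "gpnet_validation_error")
  expect_error(sim_config(10, 5, maf_range = c(0.1, 0.6)), class = "gpnet_validation_error")
  expect_error(sim_config(10, 5, maf_range = c(0.4, 0.2)), class = "gpnet_validation_error")
})

test_that("phenotype variance decomposes exactly into genetic and noise parts", {
  for (arch in c("additive", "epistatic_pairs", "mixed")) {
    cfg <- sim_config(300, 50, h2 = 0.4, n_qtl = 10, architecture = arch, seed = 7)
    ds <- simulate_phenotype(simulate_genotypes(cfg), cfg)
    y <- ds$phenotype$value
    expect_equal(y, ds$true_genetic_values + ds$noise)
    vp <- mean((y - mean(y))^2)
    vg <- mean((ds$true_genetic_values - mean(ds$true_genetic_values))^2)
    vn <- mean((ds$noise - mean(ds$noise))^2)
    expect_equal(vp, vg + vn, tolerance = 1e-10)
    expect_equal(ds$realized_h2, 0.4, tolerance = 1e-10)
  }
})

test_that("heritability limits behave correctly", {
  # h2 = 1: phenotype equals the genetic values, noise identically zero
  cfg1 <- sim_config(100, 30, h2 = 1, n_qtl = 10, seed = 5)
  ds1 <- simulate_phenotype(simulate_genotypes(cfg1), cfg1)
  expect_identical(ds1$phenotype$value, ds1$true_genetic_values)
  expect_identical(ds1$noise, numeric(100))

  # h2 = 0: phenotype independent of the genetic architecture; regress the
  # pure-noise trait on the h2 = 1 genetic values from the same seed
  cfg0 <- sim_config(2000, 30, h2 = 0, n_qtl = 10, seed = 6)
  ds0 <- simulate_phenotype(simulate_genotypes(cfg0), cfg0)
  expect_true(all(ds0$true_genetic_values == 0))
  cfg0b <- sim_config(2000, 30, h2 = 1, n_qtl = 10, seed = 6)
  ds0b <- simulate_phenotype(simulate_genotypes(cfg0b), cfg0b)
  fit <- lm(ds0$phenotype$value ~ ds0b$true_genetic_values)
  slope <- summary(fit)$coefficients[2, ]
  expect_lt(abs(slope["Estimate"]), 3 * slope["Std. Error"])

  # intermediate h2 recovered from the returned components
  cfg5 <- sim_config(2000, 100, h2 = 0.5, n_qtl = 20, seed = 8)
  ds5 <- simulate_phenotype(simulate_genotypes(cfg5), cfg5)
  vg <- mean((ds5$true_genetic_values - mean(ds5$true_genetic_values))^2)
  vp <- mean((ds5$phenotype$value - mean(ds5$phenotype$value))^2)
  expect_equal(vg / vp, 0.5, tolerance = 0.05)
})

test_that("h2 > 0 with no QTL is rejected", {
  expect_error(sim_config(50, 10, h2 = 0.5, n_qtl = 0), class = "gpnet_validation_error")
})

test_that("purely epistatic traits carry vanishing marginal additive signal", {
  mean_abs_slope <- function(n, seed) {
    cfg <- sim_config(n, 40, h2 = 1, n_qtl = 8,
                      architecture = "epistatic_pairs", seed = seed)
    ds <- simulate_phenotype(simulate_genotypes(cfg), cfg)
    counts <- geno_matrix(ds$genotypes)
    wc <- sweep(counts, 2, colMeans(counts))
    y <- ds$phenotype$value
    slopes <- apply(wc, 2, function(col) sum(col * (y - mean(y))) / sum(col^2))
    mean(abs(slopes))
  }
  # slopes are ~0 in expectation, so their average magnitude shrinks with n
  small_n <- mean(vapply(1:3, function(s) mean_abs_slope(200, s), 0))
  large_n <- mean(vapply(1:3, function(s) mean_abs_slope(2000, s), 0))
  expect_lt(large_n, small_n)
})
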