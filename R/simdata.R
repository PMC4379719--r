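# Synthetic genotype-phenotype simulator: biallelic SNPs under Hardy-Weinberg
# proportions and quantitative traits with additive, pairwise-epistatic or
# mixed architectures at a controlled heritability.

#' Simulation configuration
#'
#' Bundles all parameters of the synthetic data generator. Loci are simulated
#' independently (no linkage disequilibrium) so that per-marker expectations
#' are exact; an optional block-correlated mode (`ld_blocks > 1`) draws
#' genotypes in blocks sharing a latent gamete to mimic local LD.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param n_markers Number of biallelic markers (>= 1).
#' @param maf_range Length-2 numeric, allele-frequency range in (0, 0.5];
#'   each marker's frequency is drawn uniformly from it.
#' @param n_qtl Number of causal markers (<= `n_markers`).
#' @param h2 Target narrow-sense heritability in \[0, 1\]: the fraction of
#'   phenotypic variance explained by the simulated genetic values.
#' @param architecture `"additive"`, `"epistatic_pairs"` (pairwise products of
#'   centered allele counts) or `"mixed"` (half the QTL additive, half paired).
#' @param missing_rate Fraction of genotype calls set missing, in \[0, 1).
#' @param seed Integer seed; all outputs are pure functions of the config.
#' @param ld_blocks Number of markers per correlated block (1 = independent).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals, n_markers,
                       maf_range = c(0.05, 0.5),
                       n_qtl = min(20L, n_markers),
                       h2 = 0.5,
                       architecture = c("additive", "epistatic_pairs", "mixed"),
                       missing_rate = 0,
                       seed = 1L,
                       ld_blocks = 1L) {
  architecture <- match.arg(architecture)
  n_individuals <- assert_count(n_individuals, "n_individuals", min = 2L)
  n_markers <- assert_count(n_markers, "n_markers", min = 1L)
  if (length(maf_range) != 2L || !is.numeric(maf_range) ||
      maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop_gpnet("`maf_range` must be an increasing pair within (0, 0.5].",
               "gpnet_validation_error")
  }
  n_qtl <- assert_count(n_qtl, "n_qtl", min = 0L)
  if (n_qtl > n_markers) {
    stop_gpnet("`n_qtl` cannot exceed `n_markers`.", "gpnet_validation_error")
  }
  assert_scalar_number(h2, "h2", 0, 1)
  assert_scalar_number(missing_rate, "missing_rate", 0, 1 - 1e-12)
  if (h2 > 0 && n_qtl == 0L) {
    stop_gpnet("`h2` > 0 requires `n_qtl` >= 1.", "gpnet_validation_error")
  }
  structure(
    list(
      n_individuals = n_individuals, n_markers = n_markers,
      maf_range = as.numeric(maf_range), n_qtl = n_qtl, h2 = h2,
      architecture = architecture, missing_rate = missing_rate,
      seed = as.integer(seed), ld_blocks = assert_count(ld_blocks, "ld_blocks", 1L)
    ),
    class = "sim_config"
  )
}

#' Simulate SNP genotypes under Hardy-Weinberg proportions
#'
#' Each marker j gets an allele frequency q_j drawn uniformly from
#' `maf_range`; allele counts are Binomial(2, q_j) per individual. A fraction
#' `missing_rate` of calls is replaced by `NA`. The drawn frequencies are
#' attached as the `"true_maf"` attribute for oracle checks.
#'
#' @param config A [sim_config()].
#' @return Genotype tibble (`sample_id` + marker columns of 0/1/2/`NA`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_markers
  withr::with_seed(config$seed, {
    q <- runif(m, config$maf_range[1], config$maf_range[2])
    if (config$ld_blocks > 1L) {
      counts <- simulate_block_genotypes(n, m, q, config$ld_blocks)
    } else {
      counts <- matrix(rbinom(n * m, size = 2L, prob = rep(q, each = n)),
                       nrow = n, ncol = m)
    }
    if (config$missing_rate > 0) {
      drop <- runif(n * m) < config$missing_rate
      counts[drop] <- NA_integer_
    }
    counts
  }) -> counts
  g <- geno_tibble(counts)
  attr(g, "true_maf") <- stats::setNames(q, marker_ids_of(g))
  g
}

# Block-correlated genotypes: markers within a block reuse the same pair of
# latent uniforms per individual, giving strong positive within-block LD.
simulate_block_genotypes <- function(n, m, q, block_size) {
  counts <- matrix(0L, n, m)
  starts <- seq(1L, m, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, m)
    u1 <- runif(n)
    u2 <- runif(n)
    for (j in idx) {
      counts[, j] <- (u1 < q[j]) + (u2 < q[j])
    }
  }
  counts
}

#' Simulate a quantitative trait on top of a genotype table
#'
#' Genetic values follow the configured architecture on centered allele
#' counts at sampled QTL; `"additive"` sums per-locus effects,
#' `"epistatic_pairs"` sums effects on pairwise products of centered counts
#' (so the trait carries no marginal additive signal in expectation), and
#' `"mixed"` combines both. QTL effects are i.i.d. standard normal. Gaussian
#' noise is calibrated against the realized genetic variance in the sample so
#' the realized heritability matches `h2` tightly even at small n. Missing
#' genotypes are mean-imputed (per marker) before computing genetic values.
#'
#' @param genotypes Genotype tibble as from [simulate_genotypes()].
#' @param config The same [sim_config()] used for the genotypes.
#' @return A list of class `sim_dataset` with elements `genotypes`,
#'   `phenotype` (tibble: sample_id, value), `true_genetic_values`,
#'   `qtl_effects` (tibble: marker, partner, effect), `realized_h2`.
#' @export
simulate_phenotype <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  check_geno_tbl(genotypes)
  if (config$h2 > 0 && config$n_qtl == 0L) {
    stop_gpnet("`h2` > 0 requires at least one QTL.", "gpnet_validation_error")
  }
  counts <- geno_matrix(genotypes)
  n <- nrow(counts)
  # per-marker mean imputation, then centering
  cm <- colMeans(counts, na.rm = TRUE)
  for (j in seq_len(ncol(counts))) {
    miss <- is.na(counts[, j])
    if (any(miss)) counts[miss, j] <- cm[j]
  }
  wc <- sweep(counts, 2L, colMeans(counts))

  withr::with_seed(config$seed + 1L, {
    qtl <- sample.int(ncol(counts), config$n_qtl)
    arch <- config$architecture
    if (arch == "additive") {
      eff <- rnorm(length(qtl))
      gval <- as.numeric(wc[, qtl, drop = FALSE] %*% eff)
      qtl_effects <- tibble::tibble(
        marker = marker_ids_of(genotypes)[qtl], partner = NA_character_, effect = eff
      )
    } else if (arch == "epistatic_pairs") {
      pairs <- qtl_pairs(qtl)
      eff <- rnorm(nrow(pairs))
      gval <- epistatic_values(wc, pairs, eff)
      qtl_effects <- tibble::tibble(
        marker = marker_ids_of(genotypes)[pairs[, 1]],
        partner = marker_ids_of(genotypes)[pairs[, 2]],
        effect = eff
      )
    } else { # mixed: first half additive, second half epistatic pairs
      half <- ceiling(length(qtl) / 2)
      add_q <- qtl[seq_len(half)]
      epi_q <- qtl[setdiff(seq_along(qtl), seq_len(half))]
      eff_a <- rnorm(length(add_q))
      gval <- as.numeric(wc[, add_q, drop = FALSE] %*% eff_a)
      qtl_effects <- tibble::tibble(
        marker = marker_ids_of(genotypes)[add_q], partner = NA_character_, effect = eff_a
      )
      if (length(epi_q) >= 2) {
        pairs <- qtl_pairs(epi_q)
        eff_e <- rnorm(nrow(pairs))
        gval <- gval + epistatic_values(wc, pairs, eff_e)
        qtl_effects <- dplyr::bind_rows(qtl_effects, tibble::tibble(
          marker = marker_ids_of(genotypes)[pairs[, 1]],
          partner = marker_ids_of(genotypes)[pairs[, 2]],
          effect = eff_e
        ))
      }
    }

    vg <- var_pop(gval)
    if (config$h2 >= 1) {
      noise <- numeric(n)
    } else if (config$h2 <= 0 || vg == 0) {
      # pure noise trait; unit variance for definiteness
      gval <- gval * 0
      noise <- rnorm(n)
    } else {
      ve <- vg * (1 - config$h2) / config$h2
      noise <- rnorm(n, sd = sqrt(ve))
      # project out the genetic component and rescale, so the realized
      # variance ratio equals h2 exactly and var(y) = var(g) + var(e)
      gc <- gval - mean(gval)
      noise <- noise - mean(noise)
      noise <- noise - gc * sum(noise * gc) / sum(gc * gc)
      if (var_pop(noise) > 0) {
        noise <- noise * sqrt(ve / var_pop(noise))
      }
    }
    list(gval = gval, noise = noise, qtl_effects = qtl_effects)
  }) -> parts

  y <- parts$gval + parts$noise
  vph <- var_pop(y)
  realized_h2 <- if (vph > 0) var_pop(parts$gval) / vph else 0
  structure(
    list(
      genotypes = genotypes,
      phenotype = tibble::tibble(sample_id = genotypes$sample_id, value = y),
      true_genetic_values = parts$gval,
      noise = parts$noise,
      qtl_effects = parts$qtl_effects,
      realized_h2 = realized_h2,
      config = config
    ),
    class = "sim_dataset"
  )
}

# consecutive disjoint pairs from the sampled QTL indices
qtl_pairs <- function(qtl) {
  if (length(qtl) < 2) {
    stop_gpnet("epistatic architecture needs at least 2 QTL.", "gpnet_validation_error")
  }
  k <- floor(length(qtl) / 2)
  cbind(qtl[seq_len(k) * 2 - 1], qtl[seq_len(k) * 2])
}

epistatic_values <- function(wc, pairs, eff) {
  prod_mat <- wc[, pairs[, 1], drop = FALSE] * wc[, pairs[, 2], drop = FALSE]
  # center the interaction covariates so genetic values are mean-zero
  prod_mat <- sweep(prod_mat, 2L, colMeans(prod_mat))
  as.numeric(prod_mat %*% eff)
}

var_pop <- function(x) mean((x - mean(x))^2)

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d individuals x %d markers, %s architecture, realized h2 = %.3f\n",
    nrow(x$genotypes), length(marker_ids_of(x$genotypes)),
    x$config$architecture, x$realized_h2
  ))
  invisible(x)
}
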