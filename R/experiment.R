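# Full experiment: QC -> coding -> input construction -> phenotype
# normalization (inside CV) -> a grid of hidden-layer sizes, each evaluated
# by repeated k-fold cross-validation, plus the quasi-GBLUP benchmark arm.

#' Experiment configuration
#'
#' Either file paths (`genotype_path`, `phenotype_path`) or in-memory tables
#' (`genotypes`, `phenotypes`) must be supplied. Defaults mirror the
#' canonical protocol: hidden-layer grid 1..20, tanh hidden activation,
#' 5-fold cross-validation repeated 20 times, QC at MAF < 0.05 and missing
#' fraction > 0.95, 1000 training iterations with aMSE threshold 1e-3 and
#' init range \[-0.1, 0.1\].
#'
#' @param genotype_path,phenotype_path Input file paths (native formats).
#' @param genotypes,phenotypes In-memory tibbles (alternative to paths).
#' @param input_kind `"X"`, `"G"` or `"UD"`.
#' @param hidden_grid Hidden-layer sizes to evaluate.
#' @param hidden_activation Activation of the grid arms.
#' @param training A [training_config()].
#' @param k,repeats Cross-validation design.
#' @param seed Master seed for fold assignment and weight initialization.
#' @param maf_min,missing_max QC thresholds.
#' @param dialect Genotype file dialect for `genotype_path`.
#' @param output_dir Optional directory for [write_results()].
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(genotype_path = NULL, phenotype_path = NULL,
                              genotypes = NULL, phenotypes = NULL,
                              input_kind = c("G", "X", "UD"),
                              hidden_grid = 1:20,
                              hidden_activation = "tanh",
                              training = training_config(),
                              k = 5L, repeats = 20L, seed = 1L,
                              maf_min = 0.05, missing_max = 0.95,
                              dialect = "tsv_counts",
                              output_dir = NULL) {
  input_kind <- match.arg(input_kind)
  if (is.null(genotypes) && is.null(genotype_path)) {
    stop_gpnet("provide `genotypes` or `genotype_path`.", "gpnet_validation_error")
  }
  if (is.null(phenotypes) && is.null(phenotype_path)) {
    stop_gpnet("provide `phenotypes` or `phenotype_path`.", "gpnet_validation_error")
  }
  if (any(hidden_grid < 1)) {
    stop_gpnet("`hidden_grid` entries must be >= 1.", "gpnet_validation_error")
  }
  structure(
    list(
      genotype_path = genotype_path, phenotype_path = phenotype_path,
      genotypes = genotypes, phenotypes = phenotypes,
      input_kind = input_kind, hidden_grid = as.integer(hidden_grid),
      hidden_activation = hidden_activation, training = training,
      k = assert_count(k, "k", 2L), repeats = assert_count(repeats, "repeats", 1L),
      seed = as.integer(seed),
      maf_min = maf_min, missing_max = missing_max,
      dialect = dialect, output_dir = output_dir
    ),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' Recognized keys mirror the [experiment_config()] arguments; `training:`
#' holds [training_config()] fields.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) {
    stop_gpnet(sprintf("config file '%s' not found.", path), "gpnet_io_error")
  }
  raw <- yaml::read_yaml(path)
  tr <- do.call(training_config, raw$training %||% list())
  args <- raw[setdiff(names(raw), "training")]
  if (!is.null(args$hidden_grid)) args$hidden_grid <- as.integer(unlist(args$hidden_grid))
  do.call(experiment_config, c(args, list(training = tr)))
}

#' Run a full prediction experiment
#'
#' Executes quality control, -1/0/1 coding, construction of the configured
#' input structure, then repeated k-fold cross-validation for every
#' hidden-layer size in the grid, and always adds the quasi-GBLUP benchmark
#' arm (one identity neuron on min-max-scaled G). Deterministic for a fixed
#' master seed.
#'
#' @param config An [experiment_config()].
#' @return Object of class `gpnet_experiment`: list with `results` (long
#'   tibble: input_kind, hidden_activation, n_hidden, arm, rep, fold, r),
#'   `summary` (per-arm mean_r and var_r), `qc_log`, `n`, `m`, `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  geno <- config$genotypes %||% load_genotypes(config$genotype_path, config$dialect)
  pheno <- config$phenotypes %||% load_phenotypes(config$phenotype_path, geno)
  if (is.data.frame(pheno) && !is.null(config$genotypes)) {
    # align in-memory phenotypes to the genotype sample order as well
    pheno <- dplyr::semi_join(pheno, geno, by = "sample_id")
    geno <- dplyr::semi_join(geno, pheno, by = "sample_id")
    pheno <- pheno[match(geno$sample_id, pheno$sample_id), ]
  }

  filtered <- qc_filter(geno, maf_min = config$maf_min, missing_max = config$missing_max)
  coded <- code_genotypes(filtered)
  input <- build_input(coded, config$input_kind)
  y <- pheno$value
  n <- nrow(input$values)
  plan <- make_folds(n, k = config$k, repeats = config$repeats, seed = config$seed)

  arms <- tibble::tibble(
    arm = c(sprintf("%s_s%02d", config$input_kind, config$hidden_grid), "benchmark_gblup"),
    n_hidden = c(config$hidden_grid, 1L),
    hidden_activation = c(rep(config$hidden_activation, length(config$hidden_grid)), "identity"),
    input_kind = c(rep(config$input_kind, length(config$hidden_grid)), "G")
  )
  bench_input <- if (config$input_kind == "G") input else build_input(coded, "G")

  cv_of_arm <- function(arm, n_hidden, hidden_activation, input_kind) {
    xmat <- if (input_kind == "G") bench_input$values else input$values
    arch <- ann_architecture(ncol(xmat), n_hidden, hidden_activation)
    cfg <- config$training
    cfg$seed <- config$seed
    cv <- run_cv(xmat, y, arch, cfg, plan = plan)
    dplyr::mutate(cv$runs, arm = arm, n_hidden = n_hidden,
                  hidden_activation = hidden_activation, input_kind = input_kind,
                  .before = 1)
  }
  results <- purrr::pmap_dfr(arms, cv_of_arm)

  summary <- results |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$arm, .data$input_kind, .data$hidden_activation, .data$n_hidden) |>
    dplyr::summarise(
      mean_r = mean(.data$r),
      var_r = mean((.data$r - mean(.data$r))^2),
      n_runs = dplyr::n(),
      .groups = "drop"
    )

  out <- structure(
    list(results = results, summary = summary, qc_log = qc_log(filtered),
         n = n, m = length(coded$marker_ids), config = config),
    class = "gpnet_experiment"
  )
  if (!is.null(config$output_dir)) write_results(out, config$output_dir)
  out
}

#' @export
print.gpnet_experiment <- function(x, ...) {
  cat(sprintf("<gpnet_experiment> n = %d, m = %d, input = %s; %d arms, %d CV runs each\n",
              x$n, x$m, x$config$input_kind, nrow(x$summary),
              attr(x$plan, "repeats") %||% (x$config$repeats * x$config$k)))
  print(x$summary)
  invisible(x)
}

#' Per-run experiment results
#' @param x A `gpnet_experiment`.
#' @param ... Unused.
#' @return The long results tibble (one row per arm x repeat x fold).
#' @export
tidy.gpnet_experiment <- function(x, ...) x$results

#' Per-arm experiment summary
#' @param x A `gpnet_experiment`.
#' @param ... Unused.
#' @return Tibble with one row per arm: mean_r with var_r over CV runs.
#' @export
glance.gpnet_experiment <- function(x, ...) x$summary

#' Predictive ability against network size
#'
#' One line per input kind showing mean cross-validated Pearson r as a
#' function of the number of hidden neurons, with the benchmark arm as a
#' horizontal reference.
#'
#' @param object A `gpnet_experiment` (or a row-bound combination of their
#'   `summary` tables via `plot_cv_curve()`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gpnet_experiment <- function(object, ...) {
  plot_cv_curve(object$summary)
}

#' @rdname autoplot.gpnet_experiment
#' @param summary A summary tibble with columns `arm`, `input_kind`,
#'   `n_hidden`, `mean_r`.
#' @export
plot_cv_curve <- function(summary) {
  grid <- dplyr::filter(summary, .data$arm != "benchmark_gblup")
  bench <- dplyr::filter(summary, .data$arm == "benchmark_gblup")
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$n_hidden, y = .data$mean_r,
                                          colour = .data$input_kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "hidden neurons", y = "mean Pearson r",
                  colour = "input") +
    ggplot2::theme_minimal()
  if (nrow(bench)) {
    p <- p + ggplot2::geom_hline(yintercept = bench$mean_r, linetype = 2, colour = "grey40")
  }
  p
}

#' Write experiment results to disk
#'
#' Writes `results_long.tsv` (per-run records), `results_summary.tsv`
#' (per-arm mean and variance of r) and `manifest.yaml` (config echo, seed,
#' package and R versions, QC removals).
#'
#' @param experiment A `gpnet_experiment`.
#' @param output_dir Directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_results <- function(experiment, output_dir) {
  stopifnot(inherits(experiment, "gpnet_experiment"))
  if (nrow(experiment$results) == 0) {
    stop_gpnet("empty results table: nothing to write.", "gpnet_validation_error")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) {
    stop_gpnet(sprintf("cannot create output directory '%s'.", output_dir), "gpnet_io_error")
  }
  long_path <- file.path(output_dir, "results_long.tsv")
  summary_path <- file.path(output_dir, "results_summary.tsv")
  manifest_path <- file.path(output_dir, "manifest.yaml")
  readr::write_tsv(experiment$results, long_path, progress = FALSE)
  readr::write_tsv(experiment$summary, summary_path, progress = FALSE)
  cfg <- experiment$config
  manifest <- list(
    master_seed = cfg$seed,
    input_kind = cfg$input_kind,
    hidden_grid = cfg$hidden_grid,
    cv = list(k = cfg$k, repeats = cfg$repeats),
    qc = list(maf_min = cfg$maf_min, missing_max = cfg$missing_max,
              markers_removed = nrow(experiment$qc_log)),
    training = cfg$training[c("learning_rate", "momentum", "weight_decay",
                              "max_iterations", "amse_tolerance", "init_range")],
    n = experiment$n, m = experiment$m,
    versions = list(gpnet = as.character(packageVersion("gpnet")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  )
  yaml::write_yaml(manifest, manifest_path)
  invisible(c(long_path, summary_path, manifest_path))
}
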