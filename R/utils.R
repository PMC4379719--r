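# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gpnet <- function(msg, class) {
  rlang::abort(msg, class = c(class, "gpnet_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_gpnet(
      sprintf("`%s` must be a single finite number in [%s, %s].", name, lower, upper),
      "gpnet_validation_error"
    )
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_gpnet(
      sprintf("`%s` must be a single integer >= %d.", name, min),
      "gpnet_validation_error"
    )
  }
  invisible(as.integer(x))
}

#' Convert a genotype tibble to an integer matrix
#'
#' Genotype tables travel through the package as tibbles with a `sample_id`
#' column followed by one column per marker holding allele counts 0/1/2
#' (`NA` = missing). This peels off the id column and returns the numeric
#' matrix with sample ids as row names.
#'
#' @param geno A genotype tibble (`sample_id` + marker columns).
#' @return Numeric matrix, samples in rows, markers in columns.
#' @export
geno_matrix <- function(geno) {
  check_geno_tbl(geno)
  m <- as.matrix(geno[, setdiff(names(geno), "sample_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- geno$sample_id
  m
}

#' Convert a genotype matrix to the package's genotype tibble
#'
#' @param m Numeric matrix of allele counts (samples x markers).
#' @param sample_ids,marker_ids Optional ids; defaults to dimnames or
#'   generated `ind_i` / `mk_j` labels.
#' @return A tibble with `sample_id` plus one column per marker.
#' @export
geno_tibble <- function(m, sample_ids = NULL, marker_ids = NULL) {
  sample_ids <- sample_ids %||% rownames(m) %||% paste0("ind_", seq_len(nrow(m)))
  marker_ids <- marker_ids %||% colnames(m) %||% paste0("mk_", seq_len(ncol(m)))
  colnames(m) <- marker_ids
  out <- tibble::as_tibble(m)
  dplyr::bind_cols(tibble::tibble(sample_id = as.character(sample_ids)), out)
}

check_geno_tbl <- function(geno) {
  if (!is.data.frame(geno) || !"sample_id" %in% names(geno)) {
    stop_gpnet("genotype table must be a data frame with a `sample_id` column.",
               "gpnet_validation_error")
  }
  if (anyDuplicated(geno$sample_id)) {
    stop_gpnet("duplicate sample ids in genotype table.", "gpnet_validation_error")
  }
  vals <- unlist(geno[, setdiff(names(geno), "sample_id"), drop = FALSE], use.names = FALSE)
  bad <- !is.na(vals) & !vals %in% c(0, 1, 2)
  if (any(bad)) {
    stop_gpnet("genotype entries must be 0, 1, 2 or NA.", "gpnet_validation_error")
  }
  invisible(geno)
}

marker_ids_of <- function(geno) setdiff(names(geno), "sample_id")

# Deterministic per-run seed from (master seed, repeat, fold); kept < 2^31.
derive_seed <- function(master_seed, rep_i, fold_i) {
  (as.double(master_seed) * 2654435 + rep_i * 97003 + fold_i * 613) %% 2147483647
}
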