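# Marker quality control, allele frequencies and -1/0/1 coding.

#' Per-marker allele frequencies
#'
#' Frequency of the counted allele at each marker:
#' q_j = sum(counts) / (2 * number of non-missing calls).
#'
#' @param geno Genotype tibble (`sample_id` + 0/1/2/`NA` marker columns).
#' @return A tibble with columns `marker`, `q` (counted-allele frequency),
#'   `maf`, `n_called`, `missing_frac`.
#' @export
allele_frequencies <- function(geno) {
  counts <- geno_matrix(geno)
  n_called <- colSums(!is.na(counts))
  if (any(n_called == 0)) {
    bad <- colnames(counts)[n_called == 0][1]
    stop_gpnet(sprintf("marker '%s' has no non-missing calls.", bad),
               "gpnet_validation_error")
  }
  q <- colSums(counts, na.rm = TRUE) / (2 * n_called)
  tibble::tibble(
    marker = colnames(counts),
    q = unname(q),
    maf = pmin(unname(q), 1 - unname(q)),
    n_called = unname(n_called),
    missing_frac = 1 - unname(n_called) / nrow(counts)
  )
}

#' Marker quality control
#'
#' Removes markers with sample minor allele frequency below `maf_min` or
#' missing-call fraction above `missing_max`; survivor order is preserved.
#' Defaults follow common SNP-panel practice: MAF < 0.05 excluded, missing
#' genotype frequency > 0.95 excluded (the latter threshold is unusually
#' permissive but configurable).
#'
#' @param geno Genotype tibble.
#' @param maf_min Minimum minor allele frequency retained.
#' @param missing_max Maximum tolerated missing fraction.
#' @return The filtered genotype tibble; the removal log (tibble with
#'   `marker`, `reason`, `maf`, `missing_frac`) is attached as attribute
#'   `"qc_log"` and retrievable with [qc_log()].
#' @export
qc_filter <- function(geno, maf_min = 0.05, missing_max = 0.95) {
  check_geno_tbl(geno)
  assert_scalar_number(maf_min, "maf_min", 0, 0.5)
  assert_scalar_number(missing_max, "missing_max", 0, 1)
  freq <- allele_frequencies(geno)
  drop_maf <- freq$maf < maf_min
  drop_miss <- freq$missing_frac > missing_max
  log <- dplyr::filter(
    dplyr::mutate(freq,
      reason = dplyr::case_when(
        drop_maf & drop_miss ~ "maf+missing",
        drop_maf ~ "maf",
        drop_miss ~ "missing",
        TRUE ~ NA_character_
      )
    ),
    !is.na(.data$reason)
  )
  keep <- freq$marker[!(drop_maf | drop_miss)]
  if (length(keep) == 0) {
    stop_gpnet("empty marker panel: QC removed every marker.", "gpnet_qc_error")
  }
  out <- geno[, c("sample_id", keep)]
  attr(out, "qc_log") <- log[, c("marker", "reason", "maf", "missing_frac")]
  out
}

#' Retrieve the QC removal log attached by [qc_filter()]
#' @param geno A genotype tibble returned by [qc_filter()].
#' @return Tibble of removed markers (empty if none recorded).
#' @export
qc_log <- function(geno) {
  attr(geno, "qc_log") %||%
    tibble::tibble(marker = character(), reason = character(),
                   maf = double(), missing_frac = double())
}

#' Code genotypes as -1/0/1 with mean imputation
#'
#' Allele counts 0/1/2 map to -1/0/1 with -1 the homozygote for the minor
#' allele and +1 the homozygote for the major allele; columns where the
#' counted allele is the minor one (q <= 0.5) are flipped so the orientation
#' rule holds. Missing entries are replaced by the per-marker mean of the
#' coded non-missing values, so coded columns are real-valued. The stored
#' `q` is the frequency of the allele coded +1 (always >= 0.5 after
#' orientation).
#'
#' @param geno Genotype tibble, normally after [qc_filter()].
#' @return An object of class `coded_geno`: list with `X` (n x m numeric
#'   matrix in \[-1, 1\]), `q` (named +1-allele frequencies), `sample_ids`,
#'   `marker_ids`, `n_imputed`.
#' @export
code_genotypes <- function(geno) {
  counts <- geno_matrix(geno)
  freq <- allele_frequencies(geno)
  x <- counts - 1
  flip <- freq$q < 0.5   # q = 0.5 has no minor allele; keep counted orientation
  x[, flip] <- -x[, flip, drop = FALSE]
  q <- ifelse(flip, 1 - freq$q, freq$q)
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0) {
    cm <- colMeans(x, na.rm = TRUE)
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (any(miss)) x[miss, j] <- cm[j]
    }
  }
  structure(
    list(
      X = x,
      q = stats::setNames(q, colnames(counts)),
      sample_ids = rownames(counts),
      marker_ids = colnames(counts),
      n_imputed = n_imputed
    ),
    class = "coded_geno"
  )
}

#' @export
print.coded_geno <- function(x, ...) {
  cat(sprintf("<coded_geno> %d individuals x %d markers (-1/0/1 coding, %d imputed calls)\n",
              nrow(x$X), ncol(x$X), x$n_imputed))
  invisible(x)
}
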