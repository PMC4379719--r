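# Delimited file formats. Native genotype format (`tsv_counts`): a TSV with
# a `sample_id` column followed by one column per marker holding allele
# counts 0/1/2 (`NA` = missing). A PLINK-.raw-style dialect (`plink_raw`) is
# also read: whitespace-delimited with FID IID PAT MAT SEX PHENOTYPE header
# columns, sample ids taken from IID. Phenotypes are two-column delimited
# files (sample_id, value), header optional.

#' Read a genotype file
#'
#' @param path File path.
#' @param dialect `"tsv_counts"` (native) or `"plink_raw"`.
#' @return Genotype tibble (`sample_id` + marker columns).
#' @export
load_genotypes <- function(path, dialect = c("tsv_counts", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_gpnet(sprintf("genotype file '%s' not found.", path), "gpnet_io_error")
  }
  if (dialect == "tsv_counts") {
    raw <- readr::read_tsv(path, col_types = readr::cols(
      sample_id = readr::col_character(), .default = readr::col_character()
    ), na = character(), progress = FALSE)
    if (!"sample_id" %in% names(raw)) {
      stop_gpnet("tsv_counts genotype file must have a `sample_id` header column.",
                 "gpnet_parse_error")
    }
    id_col <- "sample_id"
  } else {
    raw <- readr::read_table(path, col_types = readr::cols(.default = readr::col_character()),
                             na = character(), progress = FALSE)
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(need %in% names(raw))) {
      stop_gpnet("plink_raw genotype file must carry FID IID PAT MAT SEX PHENOTYPE columns.",
                 "gpnet_parse_error")
    }
    raw <- raw[, c("IID", setdiff(names(raw), need))]
    names(raw)[1] <- "sample_id"
    id_col <- "sample_id"
  }
  marker_cols <- setdiff(names(raw), id_col)
  parsed <- raw
  for (mc in marker_cols) {
    v <- raw[[mc]]
    bad <- !(v %in% c("0", "1", "2", "NA", ""))
    if (any(bad)) {
      stop_gpnet(sprintf("invalid genotype token '%s' at line %d (marker %s).",
                         v[bad][1], which(bad)[1] + 1L, mc), "gpnet_parse_error")
    }
    parsed[[mc]] <- suppressWarnings(as.integer(v))
  }
  if (anyDuplicated(parsed$sample_id)) {
    dup <- parsed$sample_id[duplicated(parsed$sample_id)][1]
    stop_gpnet(sprintf("duplicate sample id '%s' in genotype file.", dup), "gpnet_parse_error")
  }
  check_geno_tbl(parsed)
  parsed
}

#' Write a genotype table in the native TSV format
#'
#' @param geno Genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  check_geno_tbl(geno)
  readr::write_tsv(geno, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a phenotype file and align it to a genotype table
#'
#' Two delimited columns: sample id and numeric value (header optional,
#' tab/comma/space separated). When `geno` is supplied the phenotypes are
#' inner-joined to its sample order; ids present on only one side are
#' dropped with a warning.
#'
#' @param path File path.
#' @param geno Optional genotype tibble to align against.
#' @return Tibble with `sample_id`, `value` (in genotype order if aligned).
#' @export
load_phenotypes <- function(path, geno = NULL) {
  if (!file.exists(path)) {
    stop_gpnet(sprintf("phenotype file '%s' not found.", path), "gpnet_io_error")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[\t, ]+")
  n_tok <- lengths(parts)
  if (any(n_tok != 2)) {
    stop_gpnet(sprintf("expected 2 columns but found %d at line %d.",
                       n_tok[n_tok != 2][1], which(n_tok != 2)[1]), "gpnet_parse_error")
  }
  ids <- vapply(parts, `[[`, "", 1L)
  vals_chr <- vapply(parts, `[[`, "", 2L)
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(vals_chr[1])))) start <- 2L  # header row
  ids <- ids[seq(start, length(ids))]
  vals_chr <- vals_chr[seq(start, length(vals_chr))]
  vals <- suppressWarnings(as.numeric(vals_chr))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop_gpnet(sprintf("non-numeric phenotype value '%s' at line %d.",
                       vals_chr[bad], bad + start - 1L), "gpnet_parse_error")
  }
  ph <- tibble::tibble(sample_id = ids, value = vals)
  if (is.null(geno)) return(ph)
  check_geno_tbl(geno)
  keep <- intersect(geno$sample_id, ph$sample_id)
  if (length(keep) == 0) {
    stop_gpnet("no overlapping sample ids between phenotype and genotype files.",
               "gpnet_io_error")
  }
  dropped <- setdiff(union(geno$sample_id, ph$sample_id), keep)
  if (length(dropped) > 0) {
    warn(sprintf("dropping %d sample id(s) without both genotype and phenotype: %s",
                 length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  dplyr::left_join(tibble::tibble(sample_id = geno$sample_id[geno$sample_id %in% keep]),
                   ph, by = "sample_id")
}

#' Write a phenotype table
#'
#' @param pheno Tibble with `sample_id`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno[, c("sample_id", "value")], path, progress = FALSE)
  invisible(path)
}
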