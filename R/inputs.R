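# The three genomic covariate structures fed to the network: raw coded
# markers X, the standardized genomic relationship matrix G, and principal
# component scores UD from the SVD of X, plus min-max feature scaling.

#' Standardized genomic relationship matrix
#'
#' VanRaden-type construction on the -1/0/1 coding: each column of X is
#' centered by its expectation 2*q_j - 1 (q_j the frequency of the allele
#' coded +1), and
#' \deqn{G = W W^T / (2 \sum_j q_j (1 - q_j))}
#' with W the centered matrix. G is symmetric positive semidefinite up to
#' floating error and has average diagonal near 1 when the genotypes follow
#' Hardy-Weinberg proportions at the same frequencies.
#'
#' @param coded A `coded_geno` from [code_genotypes()].
#' @return Object of class `genomic_rel`: list with `G` (n x n), `denominator`.
#' @export
compute_G <- function(coded) {
  stopifnot(inherits(coded, "coded_geno"))
  q <- coded$q
  denom <- 2 * sum(q * (1 - q))
  if (denom <= 0) {
    stop_gpnet("G denominator 2*sum(q(1-q)) is zero: all markers are monomorphic.",
               "gpnet_validation_error")
  }
  w <- sweep(coded$X, 2L, 2 * q - 1)
  g <- tcrossprod(w) / denom
  g <- (g + t(g)) / 2  # enforce exact symmetry against floating noise
  structure(list(G = g, denominator = denom), class = "genomic_rel")
}

#' Principal-component scores of the coded marker matrix
#'
#' Factorizes X = U D V' and returns the n-column score matrix UD (equal to
#' X V), which preserves the Gram matrix: (UD)(UD)' = XX'. Columns are
#' ordered by descending singular value. Signs are pinned by requiring the
#' largest-magnitude element of each right-singular vector to be positive;
#' trailing zero singular values are kept so UD is always n x n.
#'
#' @param coded A `coded_geno` from [code_genotypes()].
#' @return Object of class `pc_scores`: list with `UD` (n x n) and
#'   `singular_values` (length n, descending).
#' @export
compute_UD <- function(coded) {
  stopifnot(inherits(coded, "coded_geno"))
  x <- coded$X
  n <- nrow(x)
  if (n < 2) stop_gpnet("need at least 2 individuals for the SVD.", "gpnet_validation_error")
  k <- min(dim(x))
  if (all(x == 0)) {
    ud <- matrix(0, n, n)
    d <- numeric(n)
  } else {
    sv <- svd(x, nu = k, nv = k)
    # sign convention: largest-magnitude entry of each right-singular vector > 0
    for (j in seq_len(k)) {
      v <- sv$v[, j]
      pivot <- which.max(abs(v))
      if (v[pivot] < 0) {
        sv$v[, j] <- -v
        sv$u[, j] <- -sv$u[, j]
      }
    }
    d <- c(sv$d, numeric(max(0L, n - k)))
    ud <- cbind(sv$u %*% diag(sv$d, nrow = k), matrix(0, n, max(0L, n - k)))
  }
  rownames(ud) <- rownames(x)
  colnames(ud) <- paste0("PC", seq_len(n))
  structure(list(UD = ud, singular_values = d), class = "pc_scores")
}

#' Min-max scaling to \[-1, 1\]
#'
#' Maps x to 2 (x - min) / (max - min) - 1, by default per column. Constant
#' columns map to 0. The (min, max) pairs are retained so [minmax_unscale()]
#' inverts the transform exactly.
#'
#' @param m Numeric matrix (or data frame of numerics).
#' @param per_column Scale each column with its own range (default) or use
#'   the global matrix range for every entry.
#' @param kind Optional label (`"X"`, `"G"`, `"UD"`) carried in the result.
#' @return Object of class `scaled_input`: list with `values` (entries in
#'   \[-1, 1\]), `scaling` (tibble: column, min, max), `per_column`, `kind`.
#' @export
minmax_scale <- function(m, per_column = TRUE, kind = NULL) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) {
    stop_gpnet("matrix to scale must be finite.", "gpnet_validation_error")
  }
  if (per_column) {
    lo <- apply(m, 2L, min)
    hi <- apply(m, 2L, max)
  } else {
    lo <- rep(min(m), ncol(m))
    hi <- rep(max(m), ncol(m))
  }
  rng <- hi - lo
  vals <- m
  for (j in seq_len(ncol(m))) {
    vals[, j] <- if (rng[j] == 0) 0 else 2 * (m[, j] - lo[j]) / rng[j] - 1
  }
  structure(
    list(
      values = vals,
      scaling = tibble::tibble(
        column = colnames(m) %||% paste0("col_", seq_len(ncol(m))),
        min = unname(lo), max = unname(hi)
      ),
      per_column = per_column,
      kind = kind
    ),
    class = "scaled_input"
  )
}

#' Invert [minmax_scale()]
#' @param scaled A `scaled_input`.
#' @return The source matrix, recovered within floating tolerance.
#' @export
minmax_unscale <- function(scaled) {
  stopifnot(inherits(scaled, "scaled_input"))
  vals <- scaled$values
  lo <- scaled$scaling$min
  hi <- scaled$scaling$max
  out <- vals
  for (j in seq_len(ncol(vals))) {
    out[, j] <- if (hi[j] == lo[j]) lo[j] else (vals[, j] + 1) / 2 * (hi[j] - lo[j]) + lo[j]
  }
  out
}

#' Build one of the three network input structures
#'
#' `"X"` returns the -1/0/1 coded markers as-is (the coding is itself the
#' feature scaling); `"G"` and `"UD"` are min-max scaled to \[-1, 1\] using
#' the global matrix minimum and maximum (one affine map for the whole
#' matrix, as the brnn-style normalization does). Whole-matrix scaling
#' matters for UD: it preserves the singular-value weighting of the
#' columns, whereas per-column scaling (`per_column = TRUE`) inflates
#' trailing noise components to full range.
#'
#' @param coded A `coded_geno`.
#' @param kind `"X"`, `"G"` or `"UD"`.
#' @param per_column Passed to [minmax_scale()] for G and UD.
#' @return A `scaled_input` whose `values` matrix is ready for training.
#' @export
build_input <- function(coded, kind = c("X", "G", "UD"), per_column = FALSE) {
  kind <- match.arg(kind)
  if (kind == "X") {
    structure(
      list(
        values = coded$X,
        scaling = tibble::tibble(column = coded$marker_ids,
                                 min = rep(-1, ncol(coded$X)),
                                 max = rep(1, ncol(coded$X))),
        per_column = TRUE,
        kind = "X"
      ),
      class = "scaled_input"
    )
  } else if (kind == "G") {
    minmax_scale(compute_G(coded)$G, per_column = per_column, kind = "G")
  } else {
    minmax_scale(compute_UD(coded)$UD, per_column = per_column, kind = "UD")
  }
}
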