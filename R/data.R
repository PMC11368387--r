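#' Assemble an exposure/omics/outcome dataset
#'
#' Bundles the three observed data components of the LUCID model: an
#' exposure matrix `G` (complete), an omics matrix `Z` that may contain
#' missing cells, and a continuous outcome vector `Y` (complete).
#' Missingness in `Z` is carried as an explicit logical mask (`TRUE` =
#' missing) alongside the numeric matrix, so that imputed values remain
#' distinguishable from observed ones throughout a fit. `NA` cells in the
#' supplied `Z` define the mask.
#'
#' @param G numeric matrix (n x p) of exposures; no missing values allowed.
#' @param Z numeric matrix (n x m) of omics measurements; `NA` marks a
#'   missing cell.
#' @param Y numeric vector of length n, the continuous outcome; complete.
#' @param row_ids optional character vector of row labels; defaults to the
#'   rownames of `G` or `"row1"..."rown"`.
#' @return An object of class `lucid_data` with elements `G`, `Z`, `mask`,
#'   `Y`, `row_ids`, and dimensions `n`, `p`, `m`.
#' @export
lucid_data <- function(G, Z, Y, row_ids = NULL) {
  G <- as.matrix(G)
  Z <- as.matrix(Z)
  Y <- as.numeric(Y)
  if (!is.numeric(G)) stop("G must be numeric")
  if (!is.numeric(Z)) stop("Z must be numeric")
  n <- nrow(G)
  if (n < 2L) stop("need at least 2 observations")
  if (nrow(Z) != n || length(Y) != n)
    stop("G, Z and Y must share the same number of rows")
  if (ncol(G) < 1L || ncol(Z) < 1L) stop("G and Z need at least one column")
  if (anyNA(G) || any(!is.finite(G)))
    stop("exposures G must be complete and finite")
  if (anyNA(Y) || any(!is.finite(Y)))
    stop("outcome must be complete: Y contains missing or non-finite values")
  mask <- is.na(Z)
  if (any(!is.finite(Z[!mask])))
    stop("observed cells of Z must be finite")
  if (is.null(row_ids)) {
    row_ids <- rownames(G)
    if (is.null(row_ids)) row_ids <- paste0("row", seq_len(n))
  }
  if (length(row_ids) != n) stop("row_ids must have length n")
  dimnames(mask) <- dimnames(Z)
  structure(
    list(G = G, Z = Z, mask = mask, Y = Y, row_ids = as.character(row_ids),
         n = n, p = ncol(G), m = ncol(Z)),
    class = "lucid_data")
}

#' @export
print.lucid_data <- function(x, ...) {
  part <- classify_missing_pattern(x$mask, check_columns = FALSE)
  cat(sprintf("lucid_data: n = %d, p = %d exposures, m = %d omics features\n",
              x$n, x$p, x$m))
  cat(sprintf("  Z rows: %d complete, %d partially missing, %d fully missing\n",
              part$n_a, part$n_b, part$n_c))
  invisible(x)
}

#' Partition observations by their omics missingness pattern
#'
#' Splits row indices into three disjoint sets by the missingness mask of
#' the omics matrix: `ia` (no missing cells), `ib` (some but not all cells
#' missing -- the sporadic pattern), and `ic` (the whole row missing -- the
#' list-wise pattern). The partitioned likelihood treats each set
#' differently: `ia` and `ib` (after imputation) contribute full density
#' terms, `ic` rows contribute exposure and outcome terms only.
#'
#' @param mask logical matrix (n x m); `TRUE` marks a missing cell.
#' @param check_columns if `TRUE` (default), error when some omics feature
#'   has no observed value on `ia` and `ib` rows, since its Gaussian
#'   parameters would be unidentifiable.
#' @return A `missing_partition` object with integer index vectors `ia`,
#'   `ib`, `ic` and counts `n_a`, `n_b`, `n_c`.
#' @export
classify_missing_pattern <- function(mask, check_columns = TRUE) {
  mask <- as.matrix(mask)
  if (nrow(mask) == 0L || ncol(mask) == 0L) stop("empty missingness mask")
  if (!is.logical(mask)) stop("mask must be logical")
  n_miss <- rowSums(mask)
  m <- ncol(mask)
  ia <- which(n_miss == 0L)
  ic <- which(n_miss == m)
  ib <- which(n_miss > 0L & n_miss < m)
  if (check_columns) {
    iab <- c(ia, ib)
    obs_per_col <- if (length(iab)) colSums(!mask[iab, , drop = FALSE]) else
      rep(0L, m)
    bad <- which(obs_per_col == 0L)
    if (length(bad))
      stop("omics column(s) with no observed values outside fully-missing rows: ",
           paste(bad, collapse = ", "))
  }
  structure(
    list(ia = ia, ib = ib, ic = ic,
         n_a = length(ia), n_b = length(ib), n_c = length(ic)),
    class = "missing_partition")
}

#' @export
print.missing_partition <- function(x, ...) {
  cat(sprintf("missing_partition: %d complete (ia), %d sporadic (ib), %d list-wise (ic)\n",
              x$n_a, x$n_b, x$n_c))
  invisible(x)
}

#' Validate a LUCID dataset and summarise its missingness
#'
#' Re-checks the container invariants and reports per-column missingness
#' fractions of the omics matrix together with any constant columns in `G`
#' or `Z` (constant columns carry no clustering information and make the
#' multinomial-logit or Gaussian fits ill-conditioned).
#'
#' @param data a [lucid_data] object.
#' @return Invisibly, a list with `missing_fraction` (per omics column),
#'   `constant_G`, `constant_Z` (column indices) and the `missing_partition`.
#' @export
validate_lucid_data <- function(data) {
  stopifnot(inherits(data, "lucid_data"))
  if (anyNA(data$G)) stop("exposures G must be complete")
  if (anyNA(data$Y)) stop("outcome must be complete")
  part <- classify_missing_pattern(data$mask)
  frac <- colMeans(data$mask)
  const_g <- which(apply(data$G, 2, function(v) length(unique(v)) == 1L))
  const_z <- which(apply(data$Z, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0L && length(unique(v)) == 1L
  }))
  rep <- list(missing_fraction = frac, constant_G = const_g,
              constant_Z = const_z, partition = part)
  invisible(rep)
}
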