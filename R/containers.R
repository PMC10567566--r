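#' Annotated count matrix
#'
#' Bundles a sparse gene x nucleus raw UMI count matrix with per-nucleus
#' metadata. This is the central container consumed by every downstream
#' stage; columns of `counts` and rows of `meta` are matched by barcode.
#'
#' @param counts A genes x nuclei matrix of non-negative integer UMI counts
#'   (dense or any `Matrix` sparse class; stored as `dgCMatrix`). Row names
#'   are gene identifiers, column names nucleus barcodes.
#' @param meta A `data.frame` with one row per nucleus. Must contain a
#'   `barcode` column matching `colnames(counts)`; typical further columns
#'   are `lane`, `animal`, `cell_type` and `perturbation`.
#' @return An object of class `annotated_counts` with elements `counts`
#'   (dgCMatrix) and `meta` (data.frame, ordered as the columns).
#' @export
annotated_counts <- function(counts, meta) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene row names and barcode column names")
  if (anyDuplicated(rownames(counts)))
    stop("gene identifiers must be unique")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be non-negative integers")
  if (!is.data.frame(meta) || is.null(meta$barcode))
    stop("meta must be a data.frame with a 'barcode' column")
  missing <- setdiff(colnames(counts), meta$barcode)
  if (length(missing))
    stop("metadata row missing for ", length(missing), " barcode(s), e.g. ",
         missing[1])
  meta <- meta[match(colnames(counts), meta$barcode), , drop = FALSE]
  rownames(meta) <- meta$barcode
  structure(list(counts = counts, meta = meta), class = "annotated_counts")
}

#' @export
print.annotated_counts <- function(x, ...) {
  cat(sprintf("annotated_counts: %d genes x %d nuclei\n",
              nrow(x$counts), ncol(x$counts)))
  cat("metadata columns:", paste(colnames(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.annotated_counts <- function(x) dim(x$counts)

#' Subset an annotated count matrix by nuclei
#'
#' @param x An `annotated_counts` object.
#' @param barcodes Character vector of barcodes (or logical/integer index
#'   over columns) to keep.
#' @return An `annotated_counts` restricted to the selected nuclei.
#' @export
subset_nuclei <- function(x, barcodes) {
  stopifnot(inherits(x, "annotated_counts"))
  annotated_counts(x$counts[, barcodes, drop = FALSE],
                   x$meta[x$meta$barcode %in% colnames(x$counts[, barcodes, drop = FALSE]), ,
                          drop = FALSE])
}

#' Library-size normalization with log transform (log CP10K)
#'
#' Scales each nucleus to 10,000 total UMIs and applies `log(1 + x)`:
#' entry `x` in a column with total `T` becomes `log(1 + 1e4 * x / T)`.
#' Columns with zero total carry no information and are dropped with a
#' warning.
#'
#' @param counts A genes x nuclei count matrix (sparse or dense), or an
#'   `annotated_counts` object.
#' @param scale_factor Target per-nucleus total after scaling (default 1e4).
#' @return A sparse `dgCMatrix` of normalized expression, same shape as the
#'   input minus any zero-total columns.
#' @export
normalize_log1p <- function(counts, scale_factor = 1e4) {
  if (inherits(counts, "annotated_counts")) counts <- counts$counts
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (!length(counts)) stop("empty count matrix")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " nucleus column(s) with zero total dropped")
    counts <- counts[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  # scale the sparse slot column-wise, then log1p (zeros map to zero)
  fac <- scale_factor / tot
  counts@x <- counts@x * rep.int(fac, diff(counts@p))
  counts@x <- log1p(counts@x)
  counts
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes relative scaling factors for pseudobulk libraries by the
#' classical trimmed-mean-of-M-values scheme: per-gene log ratios (M) to a
#' reference library are trimmed (30 percent each tail) jointly with
#' absolute log expression (A, 5 percent each tail) and averaged with
#' inverse-variance weights. The reference library is the column whose
#' upper quartile of scaled counts is closest to the mean upper quartile.
#' Factors are normalized to have geometric mean one.
#'
#' @param counts A genes x samples matrix of non-negative counts.
#' @param trim_m,trim_a Tail trim fractions for M and A values.
#' @return Numeric vector of normalization factors, one per column.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero-total library")
  uq <- apply(counts, 2, function(v) stats::quantile(v[v > 0], 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f / exp(mean(log(f)))
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  p_o <- obs / n_obs; p_r <- ref / n_ref
  m <- log2(p_o / p_r)
  a <- 0.5 * log2(p_o * p_r)
  # asymptotic (delta-method) binomial variance of M
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & is.finite(w)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (!length(m)) return(1)
  if (max(abs(m)) < 1e-6) return(1)
  lo_m <- stats::quantile(m, trim_m); hi_m <- stats::quantile(m, 1 - trim_m)
  lo_a <- stats::quantile(a, trim_a); hi_a <- stats::quantile(a, 1 - trim_a)
  keep <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}
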