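#' Genes passing the control-expression filter
#'
#' Keeps genes whose mean raw UMI count across control nuclei is strictly
#' greater than `min_mean` (default 0.25 UMI per nucleus). All fold-change
#' based analyses are restricted to this list.
#'
#' @param x An [annotated_counts] object.
#' @param control_label Value of `group_col` identifying control nuclei.
#' @param min_mean Strict lower bound on the control mean (default 0.25).
#' @param group_col Metadata column holding the group label
#'   (default "perturbation").
#' @return Character vector of gene identifiers.
#' @export
filter_expressed_genes <- function(x, control_label, min_mean = 0.25,
                                   group_col = "perturbation") {
  stopifnot(inherits(x, "annotated_counts"))
  ctrl <- x$meta[[group_col]] == control_label
  if (!any(ctrl)) stop("zero control nuclei with label '", control_label, "'")
  m <- Matrix::rowSums(x$counts[, ctrl, drop = FALSE]) / sum(ctrl)
  rownames(x$counts)[m > min_mean]
}

#' Aggregate nuclei into pseudobulk replicates
#'
#' Sums raw UMI counts over all nuclei sharing a (group, replicate-unit)
#' combination within one cell type, producing bulk-like libraries whose
#' columns are exact integer sums of their member nuclei. In the pooled
#' screen the replicate unit is the library lane; in an animal cohort it
#' is the animal.
#'
#' @param x An [annotated_counts] object.
#' @param replicate_key Metadata column naming the replicate unit
#'   (`"lane"` or `"animal"`).
#' @param group_key Metadata column naming the comparison group
#'   (default "perturbation").
#' @param cell_type If non-`NULL`, restrict to nuclei of this cell type.
#' @param min_nuclei Minimum nuclei per pseudobulk column; smaller columns
#'   are dropped with a warning (default 3).
#' @param groups Optional subset of group labels to aggregate.
#' @return A list of class `pseudobulk`: `counts` (dense genes x samples
#'   integer matrix), `samples` (`sample`, `group`, `replicate`,
#'   `cell_type`, `n_nuclei`), `lib_sizes`.
#' @export
make_pseudobulk <- function(x, replicate_key = c("lane", "animal"),
                            group_key = "perturbation", cell_type = NULL,
                            min_nuclei = 3, groups = NULL) {
  stopifnot(inherits(x, "annotated_counts"))
  replicate_key <- match.arg(replicate_key)
  meta <- x$meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(cell_type)) keep <- keep & meta$cell_type == cell_type
  if (!is.null(groups)) keep <- keep & meta[[group_key]] %in% groups
  if (!any(keep)) stop("no nuclei in the requested stratum")
  meta <- meta[keep, , drop = FALSE]
  counts <- x$counts[, keep, drop = FALSE]
  f <- interaction(meta[[group_key]], meta[[replicate_key]], drop = TRUE,
                   sep = "\r")
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), nlevels(f)))
  pb <- as.matrix(counts %*% ind)
  n_nuc <- as.integer(table(f))
  parts <- do.call(rbind, strsplit(levels(f), "\r", fixed = TRUE))
  samples <- data.frame(sample = paste(parts[, 1], parts[, 2], sep = "."),
                        group = parts[, 1], replicate = parts[, 2],
                        cell_type = if (is.null(cell_type)) NA_character_ else cell_type,
                        n_nuclei = n_nuc, stringsAsFactors = FALSE)
  small <- samples$n_nuclei < min_nuclei
  if (any(small)) {
    warning(sum(small), " pseudobulk column(s) below min_nuclei = ",
            min_nuclei, " dropped")
    pb <- pb[, !small, drop = FALSE]
    samples <- samples[!small, , drop = FALSE]
  }
  lost <- setdiff(unique(meta[[group_key]]), samples$group)
  if (length(lost))
    stop("group(s) with zero surviving pseudobulk columns: ",
         paste(lost, collapse = ", "))
  colnames(pb) <- samples$sample
  rownames(samples) <- samples$sample
  structure(list(counts = pb, samples = samples,
                 lib_sizes = colSums(pb)), class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk: %d genes x %d samples (%d groups)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$group))))
  invisible(x)
}
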