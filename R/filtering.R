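#' Classify perturbation strength by DEG count
#'
#' A (perturbation, cell type) contrast is called relevant when its
#' differential-expression table contains at least `min_degs` genes at
#' `fdr < fdr_thresh`; otherwise the perturbation is considered to have no
#' strong transcriptional phenotype in that cell type.
#'
#' @param de A `de_table` from [nb_glm_lrt()].
#' @param min_degs Minimum number of DEGs (default 5).
#' @param fdr_thresh FDR cutoff defining a DEG (default 0.05).
#' @return A list of class `strength_call`: `relevant` (logical),
#'   `n_degs`, `deg_genes`, thresholds.
#' @export
classify_perturbation_strength <- function(de, min_degs = 5, fdr_thresh = 0.05) {
  ok <- !is.na(de$fdr) & de$fdr < fdr_thresh
  structure(list(relevant = sum(ok) >= min_degs, n_degs = sum(ok),
                 deg_genes = de$gene[ok], min_degs = min_degs,
                 fdr_thresh = fdr_thresh), class = "strength_call")
}

# Two-class linear discriminant with diagonally loaded pooled covariance.
# Returns the predicted class (0 = control, 1 = perturbation) per column.
.lda2_predict <- function(M0, M1, lambda, prior = NULL) {
  n0 <- ncol(M0); n1 <- ncol(M1)
  mu0 <- rowMeans(M0); mu1 <- rowMeans(M1)
  C0 <- M0 - mu0; C1 <- M1 - mu1
  S <- (tcrossprod(C0) + tcrossprod(C1)) / (n0 + n1 - 2)
  load <- mean(diag(S))
  if (load <= 0) stop("all features constant: cannot fit LDA")
  Sreg <- (1 - lambda) * S + lambda * load * diag(nrow(S))
  w <- solve(Sreg, mu1 - mu0)
  if (is.null(prior)) prior <- c(n0, n1) / (n0 + n1)
  thr <- as.numeric(crossprod(w, (mu0 + mu1) / 2)) + log(prior[1] / prior[2])
  list(pred0 = as.numeric(crossprod(w, M0)) > thr,
       pred1 = as.numeric(crossprod(w, M1)) > thr, w = w)
}

#' LDA filter for non-perturbed (mosaic) nuclei
#'
#' Trains a two-class linear discriminant on the log-normalized expression
#' of the perturbation-specific DEGs, with control and perturbation nuclei
#' as observations, and predicts the label of every training nucleus
#' (resubstitution, as in the screening procedure). Perturbation nuclei
#' whose predicted label disagrees with their experimental label are
#' removed; control nuclei are always retained. The pooled within-class
#' covariance is regularized by diagonal loading because the DEG count can
#' approach the nucleus count.
#'
#' @param norm_expr Normalized expression (genes x nuclei).
#' @param control_barcodes,perturbation_barcodes Column names of the two
#'   classes.
#' @param deg_genes Perturbation-specific DEG feature list (deduplicated
#'   internally).
#' @param lambda Diagonal-loading shrinkage intensity in `[0, 1]`
#'   (default 0.1).
#' @param prior Class priors, `"empirical"` (default) or `"uniform"`.
#' @return A list of class `lda_filter`: `retained` (barcodes kept:
#'   all controls plus concordant perturbation nuclei),
#'   `retained_perturbation`, `perturbed_fraction`, `predicted`
#'   (per-nucleus predicted label), `deg_genes`.
#' @export
lda_filter_nuclei <- function(norm_expr, control_barcodes,
                              perturbation_barcodes, deg_genes,
                              lambda = 0.1, prior = c("empirical", "uniform")) {
  prior <- match.arg(prior)
  deg_genes <- unique(deg_genes)
  deg_genes <- intersect(deg_genes, rownames(norm_expr))
  if (length(deg_genes) < 1) stop("no DEG features present in the matrix")
  if (length(control_barcodes) < 2 || length(perturbation_barcodes) < 2)
    stop("each class needs at least 2 nuclei")
  M0 <- as.matrix(norm_expr[deg_genes, control_barcodes, drop = FALSE])
  M1 <- as.matrix(norm_expr[deg_genes, perturbation_barcodes, drop = FALSE])
  cons <- apply(cbind(M0, M1), 1, stats::var) == 0
  if (all(cons)) stop("all-constant features: ",
                      paste(utils::head(deg_genes[cons], 5), collapse = ", "))
  if (any(cons)) {
    M0 <- M0[!cons, , drop = FALSE]; M1 <- M1[!cons, , drop = FALSE]
    deg_genes <- deg_genes[!cons]
  }
  p <- .lda2_predict(M0, M1, lambda,
                     prior = if (prior == "uniform") c(0.5, 0.5) else NULL)
  keep_pert <- perturbation_barcodes[p$pred1]
  predicted <- c(stats::setNames(ifelse(p$pred0, "perturbation", "control"),
                                 control_barcodes),
                 stats::setNames(ifelse(p$pred1, "perturbation", "control"),
                                 perturbation_barcodes))
  structure(list(retained = c(control_barcodes, keep_pert),
                 retained_perturbation = keep_pert,
                 perturbed_fraction = length(keep_pert) /
                   length(perturbation_barcodes),
                 predicted = predicted, deg_genes = deg_genes),
            class = "lda_filter")
}

#' Recompute pseudobulk DE on LDA-retained nuclei
#'
#' Repeats the pseudobulk differential-expression analysis using only the
#' nuclei retained by [lda_filter_nuclei()] and reports how the result
#' changed: the difference in DEG counts and the correlation of fold
#' changes before and after filtering. Removing diluting non-perturbed
#' nuclei should increase sensitivity without redirecting the phenotype.
#'
#' @param x An [annotated_counts] object (unfiltered).
#' @param filter An `lda_filter` result.
#' @param contrast `c(perturbation, control)` labels in the metadata.
#' @param pre_de The pre-filter `de_table` for the same contrast.
#' @param cell_type,replicate_key,group_key,min_nuclei Passed to
#'   [make_pseudobulk()].
#' @param genes Gene subset (expression filter), as used pre-filter.
#' @param fdr_thresh DEG threshold for the comparison record.
#' @param ... Passed to [estimate_dispersions()].
#' @return List: `de` (post-filter `de_table`), `comparison`
#'   (`delta_degs`, `lfc_correlation`, `n_removed`).
#' @export
refit_de_after_filter <- function(x, filter, contrast, pre_de,
                                  cell_type = NULL,
                                  replicate_key = "lane",
                                  group_key = "perturbation",
                                  min_nuclei = 3, genes = NULL,
                                  fdr_thresh = 0.05, ...) {
  stopifnot(inherits(filter, "lda_filter"))
  keep <- x$meta$barcode %in% filter$retained |
    !(x$meta[[group_key]] %in% contrast[1])
  sub <- subset_nuclei(x, x$meta$barcode[keep])
  pb <- make_pseudobulk(sub, replicate_key = replicate_key,
                        group_key = group_key, cell_type = cell_type,
                        min_nuclei = min_nuclei, groups = contrast)
  disp <- estimate_dispersions(pb, ...)
  de <- nb_glm_lrt(pb, disp, contrast, genes = genes)
  shared <- intersect(de$gene, pre_de$gene)
  n_pre <- sum(pre_de$fdr < fdr_thresh, na.rm = TRUE)
  n_post <- sum(de$fdr < fdr_thresh, na.rm = TRUE)
  list(de = de,
       comparison = list(
         delta_degs = n_post - n_pre,
         lfc_correlation = stats::cor(
           de$lfc_log2[match(shared, de$gene)],
           pre_de$lfc_log2[match(shared, pre_de$gene)]),
         n_removed = sum(!x$meta$barcode %in% filter$retained &
                           x$meta[[group_key]] == contrast[1])))
}

#' Hotelling's T-squared perturbation score
#'
#' Scores the multivariate separation between a perturbation and the
#' control in a shared principal-component space: the expressed-gene
#' matrix of one cell type is z-scored per gene, projected onto its first
#' `n_pcs` principal components (one basis for all perturbations of the
#' cell type), and each perturbation is compared with the control by the
#' two-sample Hotelling T-squared statistic with pooled covariance, with
#' the classical F transform for the p-value.
#'
#' @param norm_expr Normalized expression (genes x nuclei) of one cell
#'   type (all its nuclei).
#' @param groups Group label per nucleus.
#' @param contrast `c(perturbation, control)`.
#' @param n_pcs Number of principal components (default 20; reduced with
#'   a warning when the pooled covariance is singular).
#' @param genes Optional expressed-gene subset.
#' @param scores Optional precomputed PC score matrix (nuclei x PCs) to
#'   reuse one basis across perturbations; see [pca_scores()].
#' @return A list of class `hotelling_result`: `t2`, `f_stat`, `pvalue`,
#'   `n_pcs`, `n1`, `n2`.
#' @export
hotelling_t2 <- function(norm_expr, groups, contrast, n_pcs = 20,
                         genes = NULL, scores = NULL) {
  stopifnot(length(contrast) == 2)
  if (is.null(scores)) scores <- pca_scores(norm_expr, n_pcs = n_pcs, genes = genes)
  n_both <- sum(groups %in% contrast)
  if (n_both <= n_pcs + 2)
    stop("combined group size must exceed n_pcs + 2")
  n_pcs <- min(n_pcs, ncol(scores))
  S1 <- scores[groups == contrast[1], seq_len(n_pcs), drop = FALSE]
  S2 <- scores[groups == contrast[2], seq_len(n_pcs), drop = FALSE]
  n1 <- nrow(S1); n2 <- nrow(S2)
  repeat {
    p <- n_pcs
    d <- colMeans(S1[, seq_len(p), drop = FALSE]) -
      colMeans(S2[, seq_len(p), drop = FALSE])
    Sp <- ((n1 - 1) * stats::cov(S1[, seq_len(p), drop = FALSE]) +
             (n2 - 1) * stats::cov(S2[, seq_len(p), drop = FALSE])) / (n1 + n2 - 2)
    ch <- tryCatch(chol(Sp), error = function(e) NULL)
    if (!is.null(ch)) break
    warning("singular pooled covariance: reducing n_pcs to ", n_pcs - 1)
    n_pcs <- n_pcs - 1
    if (n_pcs < 1) stop("pooled covariance singular at every dimension")
  }
  t2 <- (n1 * n2 / (n1 + n2)) * sum(backsolve(ch, d, transpose = TRUE)^2)
  f_stat <- (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * t2
  pv <- stats::pf(f_stat, p, n1 + n2 - p - 1, lower.tail = FALSE)
  structure(list(t2 = t2, f_stat = f_stat, pvalue = pv, n_pcs = p,
                 n1 = n1, n2 = n2), class = "hotelling_result")
}

#' Principal-component scores of a z-scored expression matrix
#'
#' Z-scores each gene across nuclei (constant genes dropped) and returns
#' the first `n_pcs` principal-component scores. Used as the shared basis
#' for Hotelling comparisons within a cell type.
#'
#' @param norm_expr Normalized expression (genes x nuclei).
#' @param n_pcs Number of components.
#' @param genes Optional gene subset.
#' @return Numeric matrix nuclei x `n_pcs` with barcode row names.
#' @export
pca_scores <- function(norm_expr, n_pcs = 20, genes = NULL) {
  if (!is.null(genes)) norm_expr <- norm_expr[intersect(genes, rownames(norm_expr)), ,
                                              drop = FALSE]
  M <- as.matrix(norm_expr)
  sdv <- apply(M, 1, stats::sd)
  M <- (M[sdv > 0, , drop = FALSE] - rowMeans(M[sdv > 0, , drop = FALSE])) /
    sdv[sdv > 0]
  n_pcs <- min(n_pcs, nrow(M) - 1L, ncol(M) - 1L)
  sv <- svd(t(M), nu = n_pcs, nv = 0)
  sc <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  rownames(sc) <- colnames(norm_expr)
  colnames(sc) <- paste0("PC", seq_len(n_pcs))
  sc
}
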