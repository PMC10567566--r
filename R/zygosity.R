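#' Diffusion-map embedding of control and perturbed nuclei
#'
#' Embeds nuclei on a low-dimensional expression continuum: a Gaussian
#' kernel on Euclidean distances (bandwidth = median pairwise distance by
#' default), anisotropic normalization with `alpha = 1` (dividing the
#' kernel by the outer product of its degrees, which removes the
#' sampling-density effect), then the row-normalized transition operator
#' whose eigenvectors (constant first eigenvector dropped) are the
#' diffusion components. Components are ordered by descending eigenvalue.
#'
#' Sign convention: when `control` labels are supplied, each component is
#' oriented so the control-nuclei mean is less than or equal to the
#' overall mean; otherwise the entry of largest magnitude is made
#' positive. This pins an otherwise arbitrary eigenvector sign so output
#' is reproducible.
#'
#' @param norm_expr Normalized expression (genes x nuclei) of control
#'   plus one perturbation, optionally restricted to DEG features.
#' @param n_components Number of diffusion components (default 2).
#' @param control Optional logical/character vector marking control
#'   nuclei (barcodes or a logical over columns).
#' @param bandwidth Kernel bandwidth; default the median nonzero
#'   pairwise distance.
#' @return A list of class `diffusion_embedding`: `components` (nuclei x
#'   `n_components`, named DC1, DC2, ...), `eigenvalues`, `bandwidth`,
#'   `control` (logical per nucleus or `NULL`).
#' @export
diffusion_map <- function(norm_expr, n_components = 2, control = NULL,
                          bandwidth = NULL) {
  M <- as.matrix(norm_expr)
  if (!all(is.finite(M))) stop("non-finite values in the expression input")
  n <- ncol(M)
  if (n < 10) stop("need at least 10 nuclei")
  D <- as.matrix(stats::dist(t(M)))
  if (is.null(bandwidth)) bandwidth <- stats::median(D[D > 0])
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    warning("degenerate kernel (duplicate identical nuclei); using unit bandwidth")
    bandwidth <- 1
  }
  K <- exp(-D^2 / (2 * bandwidth^2))
  q <- rowSums(K)
  K1 <- K / outer(q, q)                   # alpha = 1 density normalization
  d <- rowSums(K1)
  # symmetric conjugate of the row-stochastic operator: same spectrum
  S <- K1 / outer(sqrt(d), sqrt(d))
  eig <- eigen(S, symmetric = TRUE)
  psi <- eig$vectors / sqrt(d)            # right eigenvectors of D^-1 K1
  keep <- 2:(n_components + 1)            # drop trivial constant eigenvector
  comp <- psi[, keep, drop = FALSE]
  ev <- eig$values[keep]
  if (!is.null(control) && !is.logical(control))
    control <- colnames(M) %in% control
  for (j in seq_len(ncol(comp))) {
    flip <- if (!is.null(control) && any(control))
      mean(comp[control, j]) > mean(comp[, j])
    else comp[which.max(abs(comp[, j])), j] < 0
    if (isTRUE(flip)) comp[, j] <- -comp[, j]
  }
  # unit-normalize for scale stability across eigen-solvers
  comp <- sweep(comp, 2, sqrt(colSums(comp^2)), "/")
  dimnames(comp) <- list(colnames(M), paste0("DC", seq_len(ncol(comp))))
  structure(list(components = comp, eigenvalues = ev, bandwidth = bandwidth,
                 control = control), class = "diffusion_embedding")
}

#' Cluster nuclei on the first diffusion component
#'
#' One-dimensional k-means (k-means++ style via many random restarts) on
#' DC1 with `k = 3` by default, interpreting the clusters as zygosity
#' states. Cluster labels are ordered by the distance of the cluster mean
#' from the control-nuclei mean on DC1: `control-like` (closest),
#' `intermediate`, `strong` for `k = 3`, or `state_1..k` otherwise.
#'
#' @param embedding A [diffusion_map()] result.
#' @param k Number of clusters (default 3).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Number of restarts (default 50).
#' @return A list of class `zygosity_labels`: `labels` (named character
#'   per nucleus), `cluster_means` (on DC1, in label order), `k`.
#' @export
cluster_dc1 <- function(embedding, k = 3, seed = 7L, nstart = 50L) {
  dc1 <- embedding$components[, "DC1"]
  if (!all(is.finite(dc1))) stop("non-finite DC1")
  if (length(unique(dc1)) < k)
    stop("k exceeds the number of distinct DC1 values")
  set.seed(seed)
  km <- stats::kmeans(dc1, centers = k, nstart = nstart, iter.max = 100)
  ctrl_mean <- if (!is.null(embedding$control) && any(embedding$control))
    mean(dc1[embedding$control]) else min(km$centers)
  ord <- order(abs(km$centers - ctrl_mean))
  lab_names <- if (k == 3) c("control-like", "intermediate", "strong")
               else paste0("state_", seq_len(k))
  map <- character(k)
  map[ord] <- lab_names
  labels <- map[km$cluster]
  names(labels) <- names(dc1)
  means <- as.numeric(km$centers)[ord]
  names(means) <- lab_names
  structure(list(labels = labels, cluster_means = means, k = k),
            class = "zygosity_labels")
}

#' Contrast expression between zygosity clusters
#'
#' Runs pseudobulk differential expression of each non-control-like
#' cluster against the control nuclei and reports whether the clusters
#' share dysregulated gene identities but differ in magnitude: the
#' Jaccard overlap of their DEG sets and the ratio of median absolute
#' log2 fold change (strong over intermediate) on the union of DEGs.
#'
#' @param x An [annotated_counts] object covering the embedded nuclei
#'   and the control group.
#' @param labels A [cluster_dc1()] result.
#' @param control_label Control value of `group_col`.
#' @param group_col Metadata column holding group labels.
#' @param genes Expressed-gene subset for the DE.
#' @param fdr_thresh DEG threshold (default 0.05).
#' @param min_cluster Minimum nuclei for a cluster to be tested
#'   (default 20; smaller clusters are skipped with a flag).
#' @param replicate_key,min_nuclei Passed to [make_pseudobulk()].
#' @return A list of class `zygosity_contrast`: per-cluster `de` tables,
#'   `jaccard`, `lfc_ratio` (strong / intermediate), `skipped`.
#' @export
zygosity_expression_contrast <- function(x, labels, control_label = "SH",
                                         group_col = "perturbation",
                                         genes = NULL, fdr_thresh = 0.05,
                                         min_cluster = 20,
                                         replicate_key = "lane",
                                         min_nuclei = 3) {
  stopifnot(inherits(labels, "zygosity_labels"))
  meta <- x$meta
  grp <- rep(NA_character_, nrow(meta))
  grp[meta[[group_col]] == control_label] <- "control"
  idx <- match(meta$barcode, names(labels$labels))
  take <- !is.na(idx) & is.na(grp)
  grp[take] <- labels$labels[idx[take]]
  keep <- !is.na(grp)
  sub <- subset_nuclei(x, meta$barcode[keep])
  sub$meta$zyg_group <- grp[keep][match(sub$meta$barcode, meta$barcode[keep])]
  clusters <- setdiff(unique(sub$meta$zyg_group), "control")
  de_list <- list(); skipped <- character(0)
  for (cl in clusters) {
    n_cl <- sum(sub$meta$zyg_group == cl)
    if (n_cl < min_cluster) { skipped <- c(skipped, cl); next }
    pb <- make_pseudobulk(sub, replicate_key = replicate_key,
                          group_key = "zyg_group", min_nuclei = min_nuclei,
                          groups = c(cl, "control"))
    disp <- estimate_dispersions(pb)
    de_list[[cl]] <- nb_glm_lrt(pb, disp, c(cl, "control"), genes = genes)
  }
  jaccard <- NA_real_; lfc_ratio <- NA_real_
  if (all(c("intermediate", "strong") %in% names(de_list))) {
    d_i <- de_list[["intermediate"]]; d_s <- de_list[["strong"]]
    deg_i <- d_i$gene[!is.na(d_i$fdr) & d_i$fdr < fdr_thresh]
    deg_s <- d_s$gene[!is.na(d_s$fdr) & d_s$fdr < fdr_thresh]
    uni <- union(deg_i, deg_s)
    if (length(uni)) {
      jaccard <- length(intersect(deg_i, deg_s)) / length(uni)
      shared <- intersect(uni, intersect(d_i$gene, d_s$gene))
      lfc_ratio <- stats::median(abs(d_s$lfc_log2[match(shared, d_s$gene)])) /
        stats::median(abs(d_i$lfc_log2[match(shared, d_i$gene)]))
    }
  }
  structure(list(de = de_list, jaccard = jaccard, lfc_ratio = lfc_ratio,
                 skipped = skipped), class = "zygosity_contrast")
}
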