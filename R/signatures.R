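#' Define up/down gene programs from a DE table
#'
#' Splits significant genes into two perturbation-specific programs:
#' upregulated (`lfc > lfc_thresh`) and downregulated
#' (`lfc < -lfc_thresh`), both at `fdr < fdr_thresh` (strict). Empty
#' programs are allowed and flagged.
#'
#' @param de A `de_table`.
#' @param lfc_thresh Absolute log2 fold-change threshold (default 0.5).
#' @param fdr_thresh FDR threshold (default 0.01).
#' @param perturbation Optional label stored with the programs.
#' @return A list of class `gene_programs`: `up`, `down` (character
#'   vectors), `thresholds`, `perturbation`, `empty` (logical flags).
#' @export
define_gene_programs <- function(de, lfc_thresh = 0.5, fdr_thresh = 0.01,
                                 perturbation = NULL) {
  sig <- !is.na(de$fdr) & de$fdr < fdr_thresh
  up <- de$gene[sig & de$lfc_log2 > lfc_thresh]
  down <- de$gene[sig & de$lfc_log2 < -lfc_thresh]
  structure(list(up = up, down = down,
                 thresholds = c(lfc = lfc_thresh, fdr = fdr_thresh),
                 perturbation = perturbation,
                 empty = c(up = length(up) == 0, down = length(down) == 0)),
            class = "gene_programs")
}

#' Rank the top upregulated genes of a DE table
#'
#' Returns the `n` strongest upregulated genes at the program thresholds,
#' ranked by descending log2 fold change; ties break by smaller FDR, then
#' lexicographic gene id.
#'
#' @param de A `de_table`.
#' @param n Number of genes (default 20).
#' @param lfc_thresh,fdr_thresh Program thresholds.
#' @return Character vector of at most `n` gene ids.
#' @export
top_upregulated <- function(de, n = 20, lfc_thresh = 0.5, fdr_thresh = 0.01) {
  sig <- !is.na(de$fdr) & de$fdr < fdr_thresh & de$lfc_log2 > lfc_thresh
  d <- de[sig, , drop = FALSE]
  d <- d[order(-d$lfc_log2, d$fdr, d$gene), , drop = FALSE]
  utils::head(d$gene, n)
}

#' Per-nucleus gene program score
#'
#' Normalizes raw counts (log CP10K), z-scores every gene across all
#' nuclei of the dataset, and averages the z-scores of the program genes
#' per nucleus. Program genes absent from the matrix are dropped with a
#' warning; duplicated entries are collapsed.
#'
#' @param counts An [annotated_counts] object or raw count matrix.
#' @param program_genes Character vector of program genes (one direction).
#' @param norm_expr Optional precomputed [normalize_log1p()] matrix.
#' @return Named numeric vector of scores, one per nucleus.
#' @export
gene_program_score <- function(counts, program_genes, norm_expr = NULL) {
  if (is.null(norm_expr)) norm_expr <- normalize_log1p(counts)
  genes <- unique(program_genes)
  missing <- setdiff(genes, rownames(norm_expr))
  if (length(missing) == length(genes)) stop("no program gene present in the matrix")
  if (length(missing))
    warning(length(missing), " program gene(s) absent from the matrix dropped")
  genes <- setdiff(genes, missing)
  M <- as.matrix(norm_expr[genes, , drop = FALSE])
  mu <- rowMeans(M)
  sdv <- apply(M, 1, stats::sd)
  sdv[sdv == 0] <- 1                      # constant gene contributes 0
  colMeans((M - mu) / sdv)
}

#' Similarity of LFC signatures across conditions
#'
#' Computes pairwise Pearson correlation or cosine similarity between the
#' log2 fold-change vectors of several DE tables, restricted either to
#' the union of their DEGs (genes passing `lfc`/`fdr` thresholds in at
#' least one condition) or to a fixed gene list, and attaches an
#' average-linkage hierarchical clustering order on `1 - similarity`.
#'
#' @param de_tables Named list of `de_table` objects.
#' @param gene_rule `"union"` (default) or a character vector of genes.
#' @param metric `"pearson"` or `"cosine"`.
#' @param lfc_thresh,fdr_thresh DEG thresholds for the union rule.
#' @return A list of class `similarity_matrix`: `similarity` (square
#'   matrix), `genes`, `order` (dendrogram leaf order), `hclust`.
#' @export
lfc_similarity <- function(de_tables, gene_rule = "union",
                           metric = c("pearson", "cosine"),
                           lfc_thresh = 0.5, fdr_thresh = 0.01) {
  metric <- match.arg(metric)
  stopifnot(length(de_tables) >= 2)
  if (is.null(names(de_tables)))
    names(de_tables) <- paste0("cond", seq_along(de_tables))
  shared <- Reduce(intersect, lapply(de_tables, `[[`, "gene"))
  if (identical(gene_rule, "union")) {
    genes <- unique(unlist(lapply(de_tables, function(d) {
      d$gene[!is.na(d$fdr) & d$fdr < fdr_thresh & abs(d$lfc_log2) > lfc_thresh]
    })))
    genes <- intersect(genes, shared)
  } else genes <- intersect(gene_rule, shared)
  if (!length(genes)) stop("empty gene selection for similarity")
  L <- vapply(de_tables, function(d) d$lfc_log2[match(genes, d$gene)],
              numeric(length(genes)))
  if (metric == "pearson") {
    sim <- stats::cor(L)
    diag(sim) <- 1
  } else {
    nrm <- sqrt(colSums(L^2))
    sim <- crossprod(L) / outer(nrm, nrm)
  }
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  structure(list(similarity = sim, genes = genes, order = hc$order,
                 hclust = hc, metric = metric),
            class = "similarity_matrix")
}

#' Cosine similarity of two LFC vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

#' Hypergeometric overlap test
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between two gene sets drawn from a common universe, with
#' optional BH adjustment across a family of tests.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector (or its size) defining the sampling
#'   frame.
#' @param n_lists_for_bh Number of tests in the family for the BH
#'   adjustment (default 1: the raw p is returned as adjusted).
#' @return A list of class `overlap_test`: `overlap`, `size_a`, `size_b`,
#'   `universe_size`, `pvalue`, `p_adjusted`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe, n_lists_for_bh = 1) {
  if (is.numeric(universe) && length(universe) == 1) {
    N <- as.integer(universe)
    a <- length(unique(set_a)); b <- length(unique(set_b))
    k <- length(intersect(set_a, set_b))
  } else {
    if (!length(universe)) stop("empty universe")
    set_a <- intersect(unique(set_a), universe)
    set_b <- intersect(unique(set_b), universe)
    N <- length(unique(universe))
    a <- length(set_a); b <- length(set_b)
    k <- length(intersect(set_a, set_b))
  }
  if (N == 0) stop("empty universe")
  p <- stats::phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  # for a single test the BH-adjusted value of the worst-ranked member is
  # min(1, p * m); families should be adjusted with adjust_overlap_family()
  structure(list(overlap = k, size_a = a, size_b = b, universe_size = N,
                 pvalue = p, p_adjusted = min(1, p * n_lists_for_bh)),
            class = "overlap_test")
}

#' BH adjustment across a family of overlap tests
#'
#' @param tests List of `overlap_test` results.
#' @return The list with `p_adjusted` replaced by BH-adjusted values
#'   across the family.
#' @export
adjust_overlap_family <- function(tests) {
  p <- vapply(tests, `[[`, numeric(1), "pvalue")
  adj <- stats::p.adjust(p, "BH")
  for (i in seq_along(tests)) tests[[i]]$p_adjusted <- adj[i]
  tests
}
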