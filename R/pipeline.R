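#' Run the screen analysis pipeline end to end
#'
#' Executes, per cell type: guide assignment, the expression filter,
#' pseudobulk NB-GLM differential expression of every perturbation
#' against the control, the >= `min_degs` relevance rule, the LDA mosaic
#' filter, the post-filter DE refit, gene programs and similarity, and
#' optional Hotelling scoring. Artifacts are written as plain-text tables
#' under `out_dir` together with a structured run log; reruns with the
#' same seed are deterministic.
#'
#' @param x An [annotated_counts] object (nucleus metadata must carry
#'   `lane`/`animal` and `cell_type`).
#' @param guide_table Guide records `data.frame`.
#' @param guide_library Guide library `data.frame`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param cell_types Cell types to analyze (default: all in metadata).
#' @param hotelling Compute Hotelling scores (default `TRUE`).
#' @return A list of class `pipeline_result`: per-cell-type lists with
#'   `de_pre`, `strength`, `lda`, `de_post`, `programs`, `hotelling`;
#'   plus `assignments` and `log`.
#' @export
run_pipeline <- function(x, guide_table, guide_library,
                         config = pipeline_config(), out_dir = NULL,
                         cell_types = NULL, hotelling = TRUE) {
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- list(stage = stage, time = format(Sys.time()),
                                     info = paste0(...))
  }
  note("assign_guides", "begin")
  filtered <- filter_guide_records(guide_table,
                                   min_coverage = config$min_coverage,
                                   min_umi = config$min_umi,
                                   min_fraction = config$min_fraction)
  assign <- assign_guides(filtered, guide_library,
                          all_barcodes = colnames(x$counts),
                          control_label = config$control_label)
  note("assign_guides", "unique=", sum(assign$status == "unique"),
       " multiplet=", sum(assign$status == "multiplet"),
       " unassigned=", sum(assign$status == "unassigned"))
  uniq <- assign[assign$status == "unique", ]
  x <- subset_nuclei(x, x$meta$barcode[x$meta$barcode %in% uniq$barcode])
  x$meta$perturbation <- uniq$target[match(x$meta$barcode, uniq$barcode)]

  if (is.null(cell_types)) cell_types <- unique(x$meta$cell_type)
  results <- list()
  for (ct in cell_types) {
    note("cell_type", ct, " begin")
    ct_bc <- x$meta$barcode[x$meta$cell_type == ct]
    xs <- subset_nuclei(x, ct_bc)
    genes <- tryCatch(filter_expressed_genes(xs, config$control_label,
                                             min_mean = config$min_mean),
                      error = function(e) { note("expression_filter", ct, ": ",
                                                 conditionMessage(e)); NULL })
    if (is.null(genes)) next
    norm <- normalize_log1p(xs)
    perts <- setdiff(unique(xs$meta$perturbation), config$control_label)
    scores <- if (hotelling)
      tryCatch(pca_scores(norm, n_pcs = config$n_pcs, genes = genes),
               error = function(e) NULL) else NULL
    ct_res <- list()
    for (p in perts) {
      res <- tryCatch({
        pb <- make_pseudobulk(xs, replicate_key = config$replicate_key,
                              groups = c(p, config$control_label))
        disp <- estimate_dispersions(pb)
        de_pre <- nb_glm_lrt(pb, disp, c(p, config$control_label),
                             genes = genes)
        strength <- classify_perturbation_strength(de_pre,
                                                   min_degs = config$min_degs,
                                                   fdr_thresh = config$strength_fdr)
        out <- list(de_pre = de_pre, strength = strength)
        if (strength$relevant) {
          ctrl_bc <- xs$meta$barcode[xs$meta$perturbation == config$control_label]
          pert_bc <- xs$meta$barcode[xs$meta$perturbation == p]
          lda <- lda_filter_nuclei(norm, ctrl_bc, pert_bc,
                                   strength$deg_genes,
                                   lambda = config$lda_lambda)
          refit <- refit_de_after_filter(xs, lda, c(p, config$control_label),
                                         de_pre,
                                         replicate_key = config$replicate_key,
                                         genes = genes,
                                         fdr_thresh = config$strength_fdr)
          out$lda <- lda
          out$de_post <- refit$de
          out$refit_comparison <- refit$comparison
          out$programs <- define_gene_programs(refit$de,
                                               lfc_thresh = config$deg_lfc,
                                               fdr_thresh = config$deg_fdr,
                                               perturbation = p)
        }
        if (hotelling && !is.null(scores))
          out$hotelling <- tryCatch(
            hotelling_t2(norm, xs$meta$perturbation,
                         c(p, config$control_label), n_pcs = config$n_pcs,
                         scores = scores),
            error = function(e) NULL)
        out
      }, error = function(e) {
        note("perturbation", ct, "/", p, " failed: ", conditionMessage(e))
        NULL
      })
      if (!is.null(res)) ct_res[[p]] <- res
    }
    results[[ct]] <- ct_res
    note("cell_type", ct, " end (", length(ct_res), " perturbations)")
  }

  out <- structure(list(results = results, assignments = assign, log = log,
                        config = config), class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

.write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.table(res$assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ct in names(res$results)) {
    for (p in names(res$results[[ct]])) {
      r <- res$results[[ct]][[p]]
      stem <- file.path(out_dir, paste0(ct, ".", p))
      write_de_table(r$de_pre, paste0(stem, ".de_pre.csv"),
                     seed = res$config$seed)
      if (!is.null(r$de_post))
        write_de_table(r$de_post, paste0(stem, ".de_post.csv"),
                       seed = res$config$seed)
      if (!is.null(r$programs)) {
        lines <- c(paste(c(paste0(p, "_up"), "na", r$programs$up),
                         collapse = "\t"),
                   paste(c(paste0(p, "_down"), "na", r$programs$down),
                         collapse = "\t"))
        writeLines(lines, paste0(stem, ".programs.gmt"))
      }
    }
  }
  summ <- pipeline_summary(res)
  utils::write.table(summ, file.path(out_dir, "summary.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Per-perturbation pipeline summary table
#'
#' @param res A `pipeline_result`.
#' @return `data.frame` with one row per (cell type, perturbation):
#'   `n_degs`, `relevant`, `perturbed_fraction`, `t2`, `t2_pvalue`.
#' @export
pipeline_summary <- function(res) {
  rows <- list()
  for (ct in names(res$results)) for (p in names(res$results[[ct]])) {
    r <- res$results[[ct]][[p]]
    rows[[length(rows) + 1L]] <- data.frame(
      cell_type = ct, perturbation = p,
      n_degs = r$strength$n_degs, relevant = r$strength$relevant,
      perturbed_fraction = if (is.null(r$lda)) NA_real_
                           else r$lda$perturbed_fraction,
      t2 = if (is.null(r$hotelling)) NA_real_ else r$hotelling$t2,
      t2_pvalue = if (is.null(r$hotelling)) NA_real_ else r$hotelling$pvalue,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
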