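#' Write an annotated count matrix to disk (10x-style layout)
#'
#' Writes `matrix.mtx` (Matrix Market coordinate format),
#' `features.tsv`, `barcodes.tsv` and `metadata.tsv` into a directory.
#'
#' @param x An [annotated_counts] object.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  stopifnot(inherits(x, "annotated_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(x$meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load an annotated count matrix from a 10x-style directory
#'
#' Reads `matrix.mtx` with its `features.tsv` / `barcodes.tsv` sidecars
#' and joins `metadata.tsv`. Dimension mismatches between the matrix
#' header and the sidecars are errors; barcodes missing from the metadata
#' are excluded with a reported count.
#'
#' @param dir Directory containing the four files.
#' @return An [annotated_counts] object.
#' @export
load_count_matrix <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                            "metadata.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing file(s): ", paste(missing, collapse = ", "))
  m <- tryCatch(Matrix::readMM(paths[1]),
                error = function(e) stop("malformed Matrix Market file '",
                                         paths[1], "': ", conditionMessage(e)))
  feats <- readLines(paths[2])
  # tolerate 10x multi-column features files
  feats <- vapply(strsplit(feats, "\t", fixed = TRUE), `[[`, character(1), 1)
  bcs <- readLines(paths[3])
  if (nrow(m) != length(feats))
    stop("matrix header declares ", nrow(m), " rows but features.tsv has ",
         length(feats))
  if (ncol(m) != length(bcs))
    stop("matrix header declares ", ncol(m), " columns but barcodes.tsv has ",
         length(bcs))
  dimnames(m) <- list(feats, bcs)
  meta <- utils::read.table(paths[4], sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
  lost <- setdiff(bcs, meta$barcode)
  if (length(lost)) {
    message(length(lost), " barcode(s) without metadata excluded")
    m <- m[, setdiff(bcs, lost), drop = FALSE]
  }
  annotated_counts(m, meta)
}

#' Read / write guide record tables
#'
#' Guide tables are TSV with fixed header
#' `barcode guide_id umi_count read_count`.
#'
#' @param path File path.
#' @return `read_guide_table`: a validated guide-record `data.frame`.
#' @export
read_guide_table <- function(path) {
  rec <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  .check_guide_records(rec)
  rec
}

#' @param records Guide records to write.
#' @rdname read_guide_table
#' @export
write_guide_table <- function(records, path) {
  .check_guide_records(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a DE table as CSV with fixed column order
#'
#' Columns: `gene, baseMean_control, lfc_log2, lr_stat, pvalue, fdr`. A
#' header comment line records the package version and, when given, the
#' seed.
#'
#' @param de A `de_table`.
#' @param path Output path.
#' @param seed Optional seed recorded in the header comment.
#' @export
write_de_table <- function(de, path, seed = NULL) {
  cols <- c("gene", "baseMean_control", "lfc_log2", "lr_stat", "pvalue", "fdr")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# perturbscope %s%s",
                     as.character(utils::packageVersion("perturbscope")),
                     if (is.null(seed)) "" else paste0(" seed=", seed)), con)
  utils::write.table(de[, cols], con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a DE table written by [write_de_table()]
#' @param path CSV path.
#' @return A `de_table` data.frame.
#' @export
read_de_table <- function(path) {
  de <- utils::read.table(path, sep = ",", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  class(de) <- c("de_table", "data.frame")
  de
}

#' Pipeline configuration
#'
#' Bundles paths and every analysis threshold with validated defaults.
#' Serializable to/from YAML.
#'
#' @param counts_dir Directory for [load_count_matrix()].
#' @param guide_table Path to the guide-record TSV.
#' @param control_label Control perturbation label (default "SH").
#' @param min_coverage,min_umi,min_fraction Guide filters.
#' @param min_mean Expression filter (UMI per control nucleus).
#' @param deg_lfc,deg_fdr Gene-program thresholds.
#' @param strength_fdr,min_degs Perturbation-relevance rule.
#' @param lda_lambda LDA diagonal loading.
#' @param n_pcs Hotelling PCA dimension.
#' @param k_zygosity k for DC1 clustering.
#' @param replicate_key `"lane"` or `"animal"`.
#' @param seed Pipeline seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_dir = NULL, guide_table = NULL,
                            control_label = "SH",
                            min_coverage = 60, min_umi = 2, min_fraction = 0.10,
                            min_mean = 0.25, deg_lfc = 0.5, deg_fdr = 0.01,
                            strength_fdr = 0.05, min_degs = 5,
                            lda_lambda = 0.1, n_pcs = 20, k_zygosity = 3,
                            replicate_key = "lane", seed = 1L) {
  cfg <- as.list(environment())
  num <- c("min_coverage", "min_umi", "min_fraction", "min_mean", "deg_lfc",
           "deg_fdr", "strength_fdr", "min_degs", "lda_lambda", "n_pcs",
           "k_zygosity")
  if (any(unlist(cfg[num]) <= 0)) stop("thresholds must be positive")
  if (!replicate_key %in% c("lane", "animal"))
    stop("replicate_key must be 'lane' or 'animal'")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @return `read_pipeline_config`: a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

#' @param config A `pipeline_config` to write.
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
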