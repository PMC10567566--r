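#' Filter raw guide capture records
#'
#' Applies the three guide-calling filters to per-nucleus guide records.
#' A record is kept iff, simultaneously:
#' \itemize{
#'   \item coverage `read_count / umi_count >= min_coverage` (records with
#'     coverage below 60 are ambient-like; the boundary is inclusive),
#'   \item `umi_count >= min_umi` (single captured molecules are removed),
#'   \item its UMI count is at least `min_fraction` of all guide UMIs seen
#'     for that barcode.
#' }
#' The fraction denominator is by default the pre-filter total of the
#' barcode, i.e. the three criteria are applied simultaneously rather than
#' sequentially; set `recompute_fraction = TRUE` to recompute the
#' denominator after the coverage and UMI filters.
#'
#' @param records `data.frame` with columns `barcode`, `guide_id`,
#'   `umi_count`, `read_count`.
#' @param min_coverage Minimum reads per UMI (default 60).
#' @param min_umi Minimum UMI count (default 2).
#' @param min_fraction Minimum within-barcode UMI fraction (default 0.10).
#' @param recompute_fraction Recompute the fraction denominator on the
#'   coverage/UMI-surviving records (default `FALSE`).
#' @return The surviving records, same columns.
#' @export
filter_guide_records <- function(records, min_coverage = 60, min_umi = 2,
                                 min_fraction = 0.10,
                                 recompute_fraction = FALSE) {
  if (min_coverage <= 0 || min_umi <= 0 || min_fraction <= 0)
    stop("thresholds must be positive")
  .check_guide_records(records)
  if (!nrow(records)) return(records)
  pass_cov <- records$read_count / records$umi_count >= min_coverage
  pass_umi <- records$umi_count >= min_umi
  denom_set <- if (recompute_fraction) pass_cov & pass_umi else rep(TRUE, nrow(records))
  tot <- rowsum(records$umi_count * denom_set, records$barcode)
  frac <- records$umi_count / tot[records$barcode, 1]
  keep <- pass_cov & pass_umi & !is.na(frac) & frac >= min_fraction
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.check_guide_records <- function(records) {
  need <- c("barcode", "guide_id", "umi_count", "read_count")
  if (!all(need %in% colnames(records)))
    stop("guide records need columns: ", paste(need, collapse = ", "))
  if (nrow(records)) {
    if (any(records$umi_count < 1) || any(records$read_count < records$umi_count))
      stop("guide records must satisfy read_count >= umi_count >= 1")
    if (anyDuplicated(paste(records$barcode, records$guide_id)))
      stop("(barcode, guide_id) pairs must be unique")
  }
  invisible(records)
}

#' Assign a unique guide to each nucleus
#'
#' Classifies every barcode by the number of guide records surviving
#' [filter_guide_records()]: exactly one record is a `unique` assignment,
#' more than one a `multiplet`, and barcodes present in the expression
#' data but absent from the surviving records are `unassigned`. Targets
#' are resolved through the guide library; safe-harbour control guides
#' collapse to the control label, and a gene's multiple guides collapse to
#' one perturbation label.
#'
#' @param filtered Filtered guide records.
#' @param library Guide library `data.frame` (`guide_id`, `target`,
#'   `is_control`) as from [default_guide_library()].
#' @param all_barcodes Optional character vector of all barcodes in the
#'   expression matrix; barcodes without surviving records are reported as
#'   `unassigned`.
#' @param control_label Label used for control-guide targets (default "SH").
#' @return A `data.frame` (`barcode`, `status`, `guide_id`, `target`,
#'   `umi_count`) with attribute `unknown_guides`: guide ids seen in the
#'   data but absent from the library (reported, never silently dropped).
#' @export
assign_guides <- function(filtered, library, all_barcodes = NULL,
                          control_label = "SH") {
  .check_guide_records(filtered)
  unknown <- setdiff(unique(filtered$guide_id), library$guide_id)
  n_per_bc <- table(filtered$barcode)
  uniq_bc <- names(n_per_bc)[n_per_bc == 1L]
  multi_bc <- names(n_per_bc)[n_per_bc > 1L]
  one <- filtered[filtered$barcode %in% uniq_bc, , drop = FALSE]
  idx <- match(one$guide_id, library$guide_id)
  target <- ifelse(is.na(idx), NA_character_,
                   ifelse(library$is_control[idx], control_label,
                          library$target[idx]))
  out <- data.frame(barcode = one$barcode,
                    status = rep("unique", nrow(one)),
                    guide_id = one$guide_id, target = target,
                    umi_count = one$umi_count, stringsAsFactors = FALSE)
  if (length(multi_bc))
    out <- rbind(out, data.frame(barcode = multi_bc, status = "multiplet",
                                 guide_id = NA_character_, target = NA_character_,
                                 umi_count = NA_integer_, stringsAsFactors = FALSE))
  if (!is.null(all_barcodes)) {
    rest <- setdiff(all_barcodes, out$barcode)
    if (length(rest))
      out <- rbind(out, data.frame(barcode = rest, status = "unassigned",
                                   guide_id = NA_character_, target = NA_character_,
                                   umi_count = NA_integer_, stringsAsFactors = FALSE))
  }
  out <- out[order(out$barcode), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unknown_guides") <- unknown
  out
}

#' Summarize guide assignments
#'
#' Tabulates nucleus counts per stratum (guide, target, or cell type) and
#' the overall fraction of unique / multiplet / unassigned barcodes.
#'
#' @param assignments Output of [assign_guides()].
#' @param by One of `"guide"`, `"target"`, `"cell_type"`.
#' @param meta Optional nucleus metadata (needed for `by = "cell_type"`).
#' @return A list: `counts` (nuclei per stratum, unique assignments only)
#'   and `status_fractions`.
#' @export
assignment_summary <- function(assignments, by = c("guide", "target", "cell_type"),
                               meta = NULL) {
  by <- match.arg(by)
  uniq <- assignments[assignments$status == "unique", , drop = FALSE]
  key <- switch(by,
    guide = uniq$guide_id,
    target = uniq$target,
    cell_type = {
      if (is.null(meta)) stop("cell-type summary needs nucleus metadata")
      meta$cell_type[match(uniq$barcode, meta$barcode)]
    })
  counts <- as.data.frame(table(stratum = key), stringsAsFactors = FALSE)
  colnames(counts) <- c(by, "n_nuclei")
  st <- table(factor(assignments$status,
                     c("unique", "multiplet", "unassigned")))
  frac <- as.numeric(st) / max(1L, nrow(assignments))
  names(frac) <- names(st)
  list(counts = counts, status_fractions = frac)
}
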