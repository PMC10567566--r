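#' Default guide library
#'
#' Builds a guide library table in the screen's design: `n_targets` genes
#' with `guides_per_target` independent gRNAs each, plus `n_controls`
#' safe-harbour (SH) control guides.
#'
#' @param n_targets Number of perturbed genes (default 29).
#' @param guides_per_target Guides per gene (default 2).
#' @param n_controls Number of safe-harbour control guides (default 5).
#' @param target_names Optional character vector of target gene names.
#' @return A `data.frame` with columns `guide_id`, `target`, `is_control`.
#' @export
default_guide_library <- function(n_targets = 29, guides_per_target = 2,
                                  n_controls = 5, target_names = NULL) {
  if (is.null(target_names)) target_names <- sprintf("target%02d", seq_len(n_targets))
  stopifnot(length(target_names) == n_targets, n_controls >= 1)
  tg <- data.frame(
    guide_id = paste0(rep(target_names, each = guides_per_target), "_g",
                      rep(seq_len(guides_per_target), n_targets)),
    target = rep(target_names, each = guides_per_target),
    is_control = FALSE, stringsAsFactors = FALSE)
  ctrl <- data.frame(
    guide_id = sprintf("SH_g%d", seq_len(n_controls)),
    target = "SH", is_control = TRUE, stringsAsFactors = FALSE)
  rbind(tg, ctrl)
}

#' Simulation configuration
#'
#' Collects every generative parameter of the synthetic screen / cohort in
#' one validated object. Defaults describe the emulated experiment: six
#' brain cell types, a 29-gene x 2-gRNA library with five safe-harbour
#' controls, nine library lanes, 50 percent editing mosaicism with an even
#' heterozygous/homozygous split (heterozygous effects at half strength),
#' guide capture at ~25 UMIs per gRNA with 65 percent detection, and
#' negative-binomial counts.
#'
#' @param n_genes Number of genes.
#' @param cell_types Named numeric vector of cell-type relative frequencies.
#' @param n_nuclei Total nuclei to simulate (ignored when
#'   `nuclei_per_guide` is given).
#' @param nuclei_per_guide If non-`NULL`, each guide receives exactly this
#'   many nuclei and `n_nuclei` is derived.
#' @param n_lanes Number of single-nucleus library lanes (default 9).
#' @param guide_library Guide table as from [default_guide_library()].
#' @param mosaic_fraction Probability that a guide-carrying nucleus carries
#'   a loss-of-function edit (default 0.5).
#' @param zygosity_split Probability that a perturbed nucleus is homozygous
#'   (vs heterozygous; default 0.5).
#' @param het_effect_scale Multiplier on program log2 fold changes for
#'   heterozygous nuclei (default 0.5).
#' @param program_size Genes per program direction (up and down each get
#'   this many; default 50).
#' @param effect_lfc Absolute log2 fold change of program genes in
#'   homozygous nuclei (default 1).
#' @param nb_dispersion Negative-binomial dispersion, scalar or per-gene
#'   vector (default 0.05).
#' @param library_size_lognormal `c(meanlog, sdlog)` of the per-nucleus
#'   total-UMI distribution (default `c(log(5000), 0.35)`).
#' @param ambient_rate Expected number of spurious (ambient) guide records
#'   per nucleus (default 0.2).
#' @param guide_dropout Fraction of nuclei whose true guide goes uncaptured
#'   (default 0.35, i.e. 65 percent detection).
#' @param guide_umi_mean Mean UMI count of a truly captured guide
#'   (Poisson, truncated at 1; default 25).
#' @param coverage_factor Reads per UMI for true guide records (default 100).
#' @param baseline_sdlog Log-normal spread of baseline gene rates
#'   (default 1.5).
#' @param celltype_sdlog Log-normal cell-type jitter on gene rates
#'   (default 0.2).
#' @param seed Integer seed for the single RNG stream.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 6000,
                              cell_types = c(excit_L23 = 0.25, excit_L5 = 0.20,
                                             excit_L6 = 0.15, interneuron = 0.20,
                                             astrocyte = 0.12, oligodendrocyte = 0.08),
                              n_nuclei = 10000,
                              nuclei_per_guide = NULL,
                              n_lanes = 9,
                              guide_library = default_guide_library(),
                              mosaic_fraction = 0.5,
                              zygosity_split = 0.5,
                              het_effect_scale = 0.5,
                              program_size = 50,
                              effect_lfc = 1,
                              nb_dispersion = 0.05,
                              library_size_lognormal = c(log(5000), 0.35),
                              ambient_rate = 0.2,
                              guide_dropout = 0.35,
                              guide_umi_mean = 25,
                              coverage_factor = 100,
                              baseline_sdlog = 1.5,
                              celltype_sdlog = 0.2,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), cell_types = cell_types,
              n_nuclei = as.integer(n_nuclei), nuclei_per_guide = nuclei_per_guide,
              n_lanes = as.integer(n_lanes), guide_library = guide_library,
              mosaic_fraction = mosaic_fraction, zygosity_split = zygosity_split,
              het_effect_scale = het_effect_scale, program_size = as.integer(program_size),
              effect_lfc = effect_lfc, nb_dispersion = nb_dispersion,
              library_size_lognormal = library_size_lognormal,
              ambient_rate = ambient_rate, guide_dropout = guide_dropout,
              guide_umi_mean = guide_umi_mean, coverage_factor = coverage_factor,
              baseline_sdlog = baseline_sdlog, celltype_sdlog = celltype_sdlog,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$mosaic_fraction, cfg$zygosity_split, cfg$guide_dropout)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_genes <= 0 || cfg$n_lanes <= 0) stop("counts must be positive")
  if (cfg$effect_lfc < 0) stop("effect_lfc must be >= 0")
  if (any(cfg$nb_dispersion < 0)) stop("nb_dispersion must be >= 0")
  if (cfg$ambient_rate < 0) stop("ambient_rate must be >= 0")
  if (any(cfg$cell_types <= 0) || is.null(names(cfg$cell_types)))
    stop("cell_types must be a named vector of positive frequencies")
  lib <- cfg$guide_library
  if (!all(c("guide_id", "target", "is_control") %in% colnames(lib)))
    stop("guide_library needs columns guide_id, target, is_control")
  if (!any(lib$is_control))
    stop("guide_library must contain at least one safe-harbour control guide")
  if (anyDuplicated(lib$guide_id)) stop("duplicate guide ids in library")
  invisible(cfg)
}

# Baseline relative expression rates: shared log-normal gene rates with a
# mild per-cell-type log-normal jitter. Column sums are left unnormalized;
# count means divide by the baseline sum so perturbation fold changes act
# on single genes without a compositional rescaling.
.sim_baseline <- function(cfg) {
  base <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = cfg$baseline_sdlog)
  ct <- vapply(names(cfg$cell_types),
               function(x) base * stats::rlnorm(cfg$n_genes, 0, cfg$celltype_sdlog),
               numeric(cfg$n_genes))
  rownames(ct) <- sprintf("gene%05d", seq_len(cfg$n_genes))
  ct
}

# Disjoint up/down programs per perturbation with exact |log2FC| = effect_lfc.
.sim_programs <- function(cfg, perturbations) {
  need <- 2L * cfg$program_size * length(perturbations)
  if (need > cfg$n_genes)
    stop("program_size x number of perturbations exceeds n_genes (",
         need, " > ", cfg$n_genes, ")")
  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  picked <- sample(genes, need)
  out <- list()
  for (i in seq_along(perturbations)) {
    idx <- (i - 1L) * 2L * cfg$program_size
    up <- picked[idx + seq_len(cfg$program_size)]
    down <- picked[idx + cfg$program_size + seq_len(cfg$program_size)]
    out[[perturbations[i]]] <- data.frame(
      gene = c(up, down),
      direction = rep(c("up", "down"), each = cfg$program_size),
      true_lfc = rep(c(cfg$effect_lfc, -cfg$effect_lfc), each = cfg$program_size),
      stringsAsFactors = FALSE)
  }
  out
}

# NB counts for one homogeneous block of nuclei: shared cell type and
# shared log2 fold-change vector. Chunked to bound dense memory.
.sim_count_block <- function(rates_ct, fc_log2, lib_sizes, dispersion,
                             chunk = 500L) {
  n_genes <- length(rates_ct)
  rate_eff <- rates_ct * 2^fc_log2
  denom <- sum(rates_ct)              # fixed baseline denominator
  n <- length(lib_sizes)
  size <- 1 / pmax(dispersion, 1e-12)
  if (length(size) == 1L) size <- rep(size, n_genes)
  pieces <- list()
  for (s in seq(1L, n, by = chunk)) {
    j <- s:min(s + chunk - 1L, n)
    mu <- outer(rate_eff / denom, lib_sizes[j])
    x <- stats::rnbinom(length(mu), mu = mu, size = size)
    dim(x) <- dim(mu)
    pieces[[length(pieces) + 1L]] <- methods::as(Matrix::Matrix(x, sparse = TRUE),
                                                 "CsparseMatrix")
  }
  do.call(cbind, pieces)
}

#' Simulate a pooled in vivo perturbation screen
#'
#' Generates a full synthetic screen with known ground truth: per nucleus a
#' cell type, lane and guide are drawn; a nucleus carrying a targeting
#' guide is loss-of-function with probability `mosaic_fraction` and then
#' homozygous with probability `zygosity_split` (heterozygous effects are
#' scaled by `het_effect_scale`); program genes change their expected
#' expression rate by the zygosity-scaled log2 fold change; counts are
#' negative binomial with per-nucleus log-normal library sizes; guide
#' capture (true, ambient and dropped records) is simulated on top.
#'
#' The single RNG stream is seeded once from `config$seed` and consumed in
#' a fixed documented order: (1) baseline rates, (2) programs, (3) nucleus
#' annotations, (4) library sizes, (5) counts block-by-block in
#' (cell type, perturbation, zygosity) order, (6) guide capture.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_screen` with elements `counts`
#'   ([annotated_counts]), `guide_table` (per-nucleus guide records) and
#'   `truth` (list: `nuclei` per-nucleus truth table, `programs`
#'   per-perturbation program tables).
#' @export
simulate_screen <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  lib <- config$guide_library
  perturbations <- unique(lib$target[!lib$is_control])

  rates <- .sim_baseline(config)                       # substream 1
  programs <- .sim_programs(config, perturbations)     # substream 2

  # substream 3: nucleus annotations
  if (!is.null(config$nuclei_per_guide)) {
    guide_id <- rep(lib$guide_id, each = config$nuclei_per_guide)
    n <- length(guide_id)
    guide_id <- sample(guide_id)                      # shuffle lane/type draws
  } else {
    n <- config$n_nuclei
    guide_id <- sample(lib$guide_id, n, replace = TRUE)
  }
  target <- lib$target[match(guide_id, lib$guide_id)]
  is_ctrl <- lib$is_control[match(guide_id, lib$guide_id)]
  cell_type <- sample(names(config$cell_types), n, replace = TRUE,
                      prob = config$cell_types)
  if (any(tabulate(factor(cell_type, names(config$cell_types)),
                   length(config$cell_types)) == 0))
    warning("a requested cell type received zero nuclei (empty stratum)")
  lane <- sample(sprintf("lane%d", seq_len(config$n_lanes)), n, replace = TRUE)
  perturbed <- !is_ctrl & stats::runif(n) < config$mosaic_fraction
  zygosity <- ifelse(!perturbed, "control",
                     ifelse(stats::runif(n) < config$zygosity_split, "hom", "het"))
  barcode <- sprintf("BC%06d", seq_len(n))

  lib_sizes <- stats::rlnorm(n, config$library_size_lognormal[1],  # substream 4
                             config$library_size_lognormal[2])

  # substream 5: counts, block by (cell type, target, zygosity)
  block <- interaction(cell_type, target, zygosity, drop = TRUE)
  cols <- vector("list", nlevels(block))
  ord <- integer(0)
  for (b in seq_len(nlevels(block))) {
    idx <- which(block == levels(block)[b])
    ct <- cell_type[idx[1]]
    fc <- numeric(config$n_genes)
    names(fc) <- rownames(rates)
    if (zygosity[idx[1]] != "control") {
      pr <- programs[[target[idx[1]]]]
      scale <- if (zygosity[idx[1]] == "het") config$het_effect_scale else 1
      fc[pr$gene] <- pr$true_lfc * scale
    }
    cols[[b]] <- .sim_count_block(rates[, ct], fc, lib_sizes[idx],
                                  config$nb_dispersion)
    ord <- c(ord, idx)
  }
  counts <- do.call(cbind, cols)[, order(ord), drop = FALSE]
  dimnames(counts) <- list(rownames(rates), barcode)

  truth_nuclei <- data.frame(barcode = barcode, guide_id = guide_id,
                             target = target, perturbed = perturbed,
                             zygosity = zygosity, lane = lane,
                             animal = "pooled", cell_type = cell_type,
                             stringsAsFactors = FALSE)
  meta <- data.frame(barcode = barcode, lane = lane, animal = "pooled",
                     cell_type = cell_type,
                     perturbation = ifelse(is_ctrl, "SH", target),
                     stringsAsFactors = FALSE)

  guide_table <- simulate_guide_capture(truth_nuclei, config, .in_stream = TRUE)

  structure(list(counts = annotated_counts(counts, meta),
                 guide_table = guide_table,
                 truth = list(nuclei = truth_nuclei, programs = programs)),
            class = "synthetic_screen")
}

#' Simulate guide capture records
#'
#' Emulates the capture statistics of the gRNA enrichment library: each
#' nucleus's true guide is observed with probability `1 - guide_dropout`
#' at a UMI count drawn from a Poisson (mean `guide_umi_mean`, truncated at
#' one) with reads per UMI near `coverage_factor`; ambient (spurious)
#' records arrive per nucleus at rate `ambient_rate` with 1-2 UMIs and low
#' coverage (reads/UMI uniform on 5..40), the signature that the
#' coverage/UMI/fraction filters remove.
#'
#' @param truth Per-nucleus truth table (needs `barcode`, `guide_id`).
#' @param config A [simulation_config()].
#' @param .in_stream Internal: `TRUE` when called inside
#'   [simulate_screen()]'s RNG stream (no reseeding).
#' @return A `data.frame` of guide records: `barcode`, `guide_id`,
#'   `umi_count`, `read_count`.
#' @export
simulate_guide_capture <- function(truth, config, .in_stream = FALSE) {
  if (!.in_stream) set.seed(config$seed + 1L)
  n <- nrow(truth)
  keep <- stats::runif(n) >= config$guide_dropout
  umi <- stats::qpois(stats::runif(sum(keep),
                                   stats::dpois(0, config$guide_umi_mean), 1),
                      config$guide_umi_mean)   # zero-truncated Poisson
  cover <- config$coverage_factor * stats::rlnorm(sum(keep), 0, 0.1)
  true_rec <- data.frame(barcode = truth$barcode[keep],
                         guide_id = truth$guide_id[keep],
                         umi_count = umi,
                         read_count = pmax(round(umi * cover), umi),
                         stringsAsFactors = FALSE)
  n_amb <- stats::rpois(n, config$ambient_rate)
  amb <- NULL
  if (sum(n_amb) > 0) {
    bc <- rep(truth$barcode, n_amb)
    gid <- sample(config$guide_library$guide_id, sum(n_amb), replace = TRUE)
    aumi <- sample(1:2, sum(n_amb), replace = TRUE, prob = c(0.8, 0.2))
    acov <- sample(5:40, sum(n_amb), replace = TRUE)
    amb <- data.frame(barcode = bc, guide_id = gid, umi_count = aumi,
                      read_count = aumi * acov, stringsAsFactors = FALSE)
    # ambient copy of the already-captured true guide would violate the
    # (barcode, guide) uniqueness contract; merge by summing counts
  }
  rec <- rbind(true_rec, amb)
  if (is.null(rec) || !nrow(rec))
    return(data.frame(barcode = character(), guide_id = character(),
                      umi_count = integer(), read_count = integer()))
  key <- paste(rec$barcode, rec$guide_id, sep = "\r")
  if (anyDuplicated(key)) {
    rec <- data.frame(barcode = rec$barcode[!duplicated(key)],
                      guide_id = rec$guide_id[!duplicated(key)],
                      umi_count = as.integer(rowsum(rec$umi_count, key)[unique(key), ]),
                      read_count = as.integer(rowsum(rec$read_count, key)[unique(key), ]),
                      stringsAsFactors = FALSE)
  }
  rec <- rec[order(rec$barcode, rec$guide_id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Simulate a deletion-model cohort
#'
#' Generates a wild-type vs heterozygous-deletion cohort of
#' `n_animals_per_arm` animals each. In deletion animals, genes in
#' `deleted_genes` are generated at `deletion_multiplier` times the
#' wild-type rate (half dosage by default); every other gene carries a true
#' log2 fold change equal to the weighted sum of the per-perturbation
#' program fold changes (`weights`) plus gene-level Gaussian noise
#' (`noise_sd`), emulating an aggregate phenotype that is a linear
#' combination of single-perturbation signatures.
#'
#' @param config A [simulation_config()]; its gene world (baseline rates,
#'   programs) is re-derived from `config$seed` so that screen and cohort
#'   share program definitions.
#' @param weights Named numeric vector of combination weights, one per
#'   perturbation program (names become perturbation labels).
#' @param deleted_genes Character vector of gene ids, or a single integer
#'   (that many genes are sampled from outside the programs).
#' @param n_animals_per_arm Animals per arm (>= 2; default 3).
#' @param nuclei_per_animal Nuclei per animal (default 2000).
#' @param noise_sd Gene-level Gaussian noise sd on the combined log2 fold
#'   change (default 0.3).
#' @param deletion_multiplier Rate multiplier for deleted genes in deletion
#'   animals (default 0.5).
#' @return A list of class `synthetic_cohort`: `counts`
#'   ([annotated_counts] with `condition` metadata), `truth` (per-gene true
#'   LFC vector, deleted genes, programs, weights).
#' @export
simulate_deletion_cohort <- function(config, weights, deleted_genes,
                                     n_animals_per_arm = 3,
                                     nuclei_per_animal = 2000,
                                     noise_sd = 0.3,
                                     deletion_multiplier = 0.5) {
  validate_sim_config(config)
  if (n_animals_per_arm < 2)
    stop("n_animals_per_arm must be >= 2: differential expression needs replicates")
  if (is.null(names(weights)))
    names(weights) <- sprintf("P%d", seq_along(weights))
  set.seed(config$seed)
  rates <- .sim_baseline(config)                        # substream 1
  programs <- .sim_programs(config, names(weights))     # substream 2
  genes <- rownames(rates)

  if (is.numeric(deleted_genes) && length(deleted_genes) == 1L) {
    pool <- setdiff(genes, unlist(lapply(programs, `[[`, "gene")))
    deleted_genes <- sample(pool, deleted_genes)        # substream 3
  }
  stopifnot(all(deleted_genes %in% genes))

  true_lfc <- numeric(length(genes)); names(true_lfc) <- genes
  for (p in names(weights)) {
    pr <- programs[[p]]
    true_lfc[pr$gene] <- true_lfc[pr$gene] + weights[p] * pr$true_lfc
  }
  if (noise_sd > 0)
    true_lfc <- true_lfc + stats::rnorm(length(genes), 0, noise_sd)  # substream 4
  true_lfc[deleted_genes] <- log2(deletion_multiplier)

  animals <- c(sprintf("WT%d", seq_len(n_animals_per_arm)),
               sprintf("DEL%d", seq_len(n_animals_per_arm)))
  condition <- rep(c("WT", "DEL"), each = n_animals_per_arm)
  n <- length(animals) * nuclei_per_animal
  animal <- rep(animals, each = nuclei_per_animal)
  cond <- rep(condition, each = nuclei_per_animal)
  cell_type <- sample(names(config$cell_types), n, replace = TRUE,   # substream 5
                      prob = config$cell_types)
  lib_sizes <- stats::rlnorm(n, config$library_size_lognormal[1],
                             config$library_size_lognormal[2])
  barcode <- sprintf("CB%06d", seq_len(n))

  block <- interaction(cell_type, cond, drop = TRUE)                 # substream 6
  cols <- vector("list", nlevels(block)); ord <- integer(0)
  zero <- numeric(length(genes))
  for (b in seq_len(nlevels(block))) {
    idx <- which(block == levels(block)[b])
    fc <- if (cond[idx[1]] == "DEL") true_lfc else zero
    cols[[b]] <- .sim_count_block(rates[, cell_type[idx[1]]], fc,
                                  lib_sizes[idx], config$nb_dispersion)
    ord <- c(ord, idx)
  }
  counts <- do.call(cbind, cols)[, order(ord), drop = FALSE]
  dimnames(counts) <- list(genes, barcode)

  meta <- data.frame(barcode = barcode, lane = animal, animal = animal,
                     cell_type = cell_type, perturbation = cond,
                     condition = cond, stringsAsFactors = FALSE)
  structure(list(counts = annotated_counts(counts, meta),
                 truth = list(true_lfc = true_lfc, deleted_genes = deleted_genes,
                              programs = programs, weights = weights,
                              deletion_multiplier = deletion_multiplier)),
            class = "synthetic_cohort")
}
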