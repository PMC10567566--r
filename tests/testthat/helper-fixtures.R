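# Shared fixtures, built in code at test time.

# A small single-cell-type screen with clean guide capture, for DE and
# filtering tests.
small_screen <- function(seed = 5, n_targets = 2, nuclei_per_guide = 400,
                         n_genes = 1200, effect_lfc = 1, ambient_rate = 0,
                         guide_dropout = 0, ...) {
  cfg <- simulation_config(
    n_genes = n_genes, nuclei_per_guide = nuclei_per_guide,
    cell_types = c(neuron = 1),
    guide_library = default_guide_library(n_targets = n_targets,
                                          guides_per_target = 1,
                                          n_controls = 1),
    program_size = 50, effect_lfc = effect_lfc,
    ambient_rate = ambient_rate, guide_dropout = guide_dropout,
    seed = seed, ...)
  list(cfg = cfg, sim = simulate_screen(cfg))
}

# Hand-written toy guide record table exercising every filter boundary.
toy_guide_records <- function() {
  data.frame(
    barcode    = c("bc1", "bc2", "bc3", "bc3", "bc4", "bc4"),
    guide_id   = c("gA",  "gA",  "gA",  "gB",  "gA",  "gB"),
    umi_count  = c(2L,    1L,    18L,   2L,    18L,   1L),
    read_count = c(120L,  600L,  1800L, 200L,  1800L, 100L),
    stringsAsFactors = FALSE)
}

# Minimal pseudobulk object from a plain matrix.
as_pseudobulk <- function(Y, group, n_nuclei = 10L) {
  structure(list(
    counts = Y,
    samples = data.frame(sample = colnames(Y), group = group,
                         replicate = seq_len(ncol(Y)),
                         cell_type = NA_character_,
                         n_nuclei = rep(n_nuclei, ncol(Y)),
                         stringsAsFactors = FALSE, row.names = colnames(Y)),
    lib_sizes = colSums(Y)), class = "pseudobulk")
}

# Direct-maximization Poisson LRT (closed-form MLE), the dispersion-0
# oracle for the NB GLM test.
poisson_lrt_oracle <- function(Y, group, offsets) {
  vapply(seq_len(nrow(Y)), function(i) {
    y <- Y[i, ]
    ll <- function(idx) {
      lam <- sum(y[idx]) / sum(offsets[idx])
      sum(stats::dpois(y[idx], lam * offsets[idx], log = TRUE))
    }
    g <- unique(group)
    2 * ((ll(group == g[1]) + ll(group == g[2])) - ll(rep(TRUE, length(y))))
  }, numeric(1))
}

# Naive O(n^2) double-loop distance correlation (biased estimator).
dcor_naive <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-")); b <- abs(outer(y, y, "-"))
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  am <- mean(a); bm <- mean(b)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + am
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + bm
  }
  dcov2 <- mean(A * B)
  sqrt(dcov2) / (mean(A * A) * mean(B * B))^(1 / 4)
}
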