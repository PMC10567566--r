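test_that("strength call applies the >= 5 DEG rule at its boundary", {
  mk <- function(n_sig) {
    data.frame(gene = paste0("g", 1:20), baseMean_control = 1,
               lfc_log2 = 1, lr_stat = 1,
               pvalue = 0.001,
               fdr = c(rep(0.01, n_sig), rep(0.5, 20 - n_sig)))
  }
  expect_false(classify_perturbation_strength(mk(4))$relevant)
  expect_true(classify_perturbation_strength(mk(5))$relevant)
  expect_identical(classify_perturbation_strength(mk(7))$n_degs, 7L)
})

test_that("LDA filter: controls kept, separation, dedup/order invariance", {
  set.seed(6)
  n <- 80; p <- 10
  ctrl <- matrix(rnorm(p * n), p, n, dimnames = list(paste0("g", 1:p),
                                                     paste0("ctl", 1:n)))
  pert <- matrix(rnorm(p * n, 4), p, n, dimnames = list(paste0("g", 1:p),
                                                        paste0("prt", 1:n)))
  M <- cbind(ctrl, pert)
  r <- lda_filter_nuclei(M, colnames(ctrl), colnames(pert), paste0("g", 1:p))
  # disjoint supports -> everything retained; controls always kept
  expect_equal(r$perturbed_fraction, 1)
  expect_true(all(colnames(ctrl) %in% r$retained))
  # invariance to feature order and duplication
  feats <- c(rev(paste0("g", 1:p)), "g1", "g1")
  r2 <- lda_filter_nuclei(M, colnames(ctrl), colnames(pert), feats)
  expect_identical(r2$retained, r$retained)
  # no effect: fraction near chance for balanced classes, never drops controls
  set.seed(8)
  M0 <- matrix(rnorm(p * 2 * n), p, 2 * n,
               dimnames = list(paste0("g", 1:p), c(colnames(ctrl), colnames(pert))))
  r0 <- lda_filter_nuclei(M0, colnames(ctrl), colnames(pert), paste0("g", 1:p))
  expect_gt(r0$perturbed_fraction, 0.3)
  expect_lt(r0$perturbed_fraction, 0.7)
  expect_error(lda_filter_nuclei(M, colnames(ctrl)[1], colnames(pert),
                                 paste0("g", 1:p)), "at least 2")
  Mc <- M * 0
  expect_error(lda_filter_nuclei(Mc, colnames(ctrl), colnames(pert),
                                 paste0("g", 1:p)), "constant")
})

test_that("LDA mosaic filter tracks the true loss-of-function fraction", {
  s <- small_screen(seed = 19, n_targets = 1, nuclei_per_guide = 400,
                    n_genes = 1000)
  x <- s$sim$counts
  genes <- filter_expressed_genes(x, "SH")
  pb <- make_pseudobulk(x, "lane")
  de <- nb_glm_lrt(pb, estimate_dispersions(pb), c("target01", "SH"),
                   genes = genes)
  st <- classify_perturbation_strength(de)
  expect_true(st$relevant)
  norm <- normalize_log1p(x)
  ctrl <- x$meta$barcode[x$meta$perturbation == "SH"]
  pert <- x$meta$barcode[x$meta$perturbation == "target01"]
  r <- lda_filter_nuclei(norm, ctrl, pert, st$deg_genes)
  tr <- s$sim$truth$nuclei
  truly <- tr$perturbed[match(pert, tr$barcode)]
  # essentially all truly perturbed nuclei survive; retained fraction sits
  # between the true fraction and 1 (resubstitution keeps extras, never
  # drops below truth by much)
  keep <- pert %in% r$retained_perturbation
  expect_gt(mean(keep[truly]), 0.9)
  expect_gt(r$perturbed_fraction, mean(truly) - 0.05)
})

test_that("refit after filter is idempotent when nothing is removed and gains DEGs otherwise", {
  s <- small_screen(seed = 25, n_targets = 1, nuclei_per_guide = 300,
                    n_genes = 800)
  x <- s$sim$counts
  genes <- filter_expressed_genes(x, "SH")
  pb <- make_pseudobulk(x, "lane")
  de_pre <- nb_glm_lrt(pb, estimate_dispersions(pb), c("target01", "SH"),
                       genes = genes)
  ctrl <- x$meta$barcode[x$meta$perturbation == "SH"]
  pert <- x$meta$barcode[x$meta$perturbation == "target01"]
  # a pass-through filter: identical DE table
  noop <- structure(list(retained = c(ctrl, pert),
                         retained_perturbation = pert,
                         perturbed_fraction = 1,
                         predicted = NULL, deg_genes = character(0)),
                    class = "lda_filter")
  out <- refit_de_after_filter(x, noop, c("target01", "SH"), de_pre,
                               genes = genes)
  expect_equal(out$de$lfc_log2, de_pre$lfc_log2, tolerance = 1e-10)
  expect_identical(out$comparison$delta_degs, 0L)
  expect_equal(out$comparison$lfc_correlation, 1, tolerance = 1e-9)
  # the real filter: DEG count does not drop, and program-gene LFC moves
  # toward the homozygous truth
  st <- classify_perturbation_strength(de_pre)
  norm <- normalize_log1p(x)
  lda <- lda_filter_nuclei(norm, ctrl, pert, st$deg_genes)
  out2 <- refit_de_after_filter(x, lda, c("target01", "SH"), de_pre,
                                genes = genes)
  expect_gte(out2$comparison$delta_degs, 0L)
  pr <- s$sim$truth$programs$target01
  up <- intersect(pr$gene[pr$direction == "up"], out2$de$gene)
  bias_pre <- mean(de_pre$lfc_log2[match(up, de_pre$gene)]) - 1
  bias_post <- mean(out2$de$lfc_log2[match(up, out2$de$gene)]) - 1
  expect_lt(abs(bias_post), abs(bias_pre))
})

test_that("Hotelling T2: null at zero, 1-PC equals squared two-sample t", {
  set.seed(10)
  n <- 30; p <- 40
  M <- matrix(rnorm(p * 2 * n), p, 2 * n,
              dimnames = list(paste0("g", 1:p), paste0("c", 1:(2 * n))))
  grp <- rep(c("P", "SH"), each = n)
  # identical groups (same nuclei duplicated): T2 = 0
  Mdup <- cbind(M[, 1:n], M[, 1:n])
  colnames(Mdup) <- paste0("d", 1:(2 * n))
  r0 <- hotelling_t2(Mdup, grp, c("P", "SH"), n_pcs = 5)
  expect_lt(r0$t2, 1e-16)
  # 1-PC case: equals the squared pooled-variance two-sample t statistic
  sc <- pca_scores(M, n_pcs = 1)
  r1 <- hotelling_t2(M, grp, c("P", "SH"), n_pcs = 1, scores = sc)
  x1 <- sc[grp == "P", 1]; x2 <- sc[grp == "SH", 1]
  sp2 <- ((n - 1) * var(x1) + (n - 1) * var(x2)) / (2 * n - 2)
  t_stat <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n + 1 / n))
  expect_equal(r1$t2, t_stat^2, tolerance = 1e-10)
  expect_error(hotelling_t2(M, grp, c("P", "SH"), n_pcs = 2 * n),
               "exceed")
})

test_that("Hotelling separates a true shift and PCA scores are well-formed", {
  set.seed(15)
  p <- 60; n <- 50
  ctrl <- matrix(rnorm(p * n), p, n)
  pert <- matrix(rnorm(p * n, mean = 0.6), p, n)
  M <- cbind(ctrl, pert)
  dimnames(M) <- list(paste0("g", 1:p), paste0("c", 1:(2 * n)))
  grp <- rep(c("SH", "P"), each = n)
  r <- hotelling_t2(M, grp, c("P", "SH"), n_pcs = 10)
  expect_lt(r$pvalue, 1e-6)
  sc <- pca_scores(M, n_pcs = 10)
  expect_identical(dim(sc), c(as.integer(2 * n), 10L))
  # component variance non-increasing
  v <- apply(sc, 2, var)
  expect_true(all(diff(v) <= 1e-8))
})
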