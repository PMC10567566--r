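test_that("Huber regression: exact recovery, OLS limit, scale equivariance", {
  set.seed(1)
  X <- matrix(rnorm(500 * 3), 500, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(a = 0.21, b = 0.18, c = -0.11)
  y <- as.numeric(X %*% beta)
  # exact linear data: coefficients recovered to 1e-8
  fit <- huber_rlm(y + rnorm(500, 0, 1e-12), X)
  expect_equal(fit$coefficients, beta, tolerance = 1e-8)
  # tuning constant -> infinity reduces to OLS (normal-equations oracle)
  yn <- y + rnorm(500, 0, 0.3)
  fit_inf <- huber_rlm(yn, X, k = 1e6)
  Xd <- cbind(1, X)
  ols <- solve(crossprod(Xd), crossprod(Xd, yn))
  expect_equal(unname(fit_inf$coefficients), unname(ols[-1]), tolerance = 1e-8)
  expect_equal(fit_inf$intercept, ols[1], tolerance = 1e-8)
  # scale equivariance: scaling a column by s divides its coefficient by s
  X2 <- X; X2[, 2] <- X2[, 2] * 10
  fit2 <- huber_rlm(yn, X2)
  fit1 <- huber_rlm(yn, X)
  expect_equal(fit2$coefficients["b"] * 10, fit1$coefficients["b"],
               tolerance = 1e-8)
  # rank deficiency named
  X3 <- cbind(X, dup = X[, 1])
  expect_error(huber_rlm(yn, X3), "collinear")
  expect_error(huber_rlm(yn[-1], X), "rows")
})

test_that("Huber beats OLS under gross outliers", {
  set.seed(9)
  errs <- replicate(20, {
    X <- matrix(rnorm(1000 * 3, 0, 0.4), 1000, 3)
    beta <- c(0.21, 0.18, -0.11)
    y <- as.numeric(X %*% beta) + rnorm(1000, 0, 0.2)
    out <- sample(1000, 50)                       # 5% gross outliers
    y[out] <- y[out] + sample(c(-5, 5), 50, replace = TRUE)
    h <- huber_rlm(y, X)$coefficients
    Xd <- cbind(1, X)
    o <- solve(crossprod(Xd), crossprod(Xd, y))[-1]
    c(huber = sum((h - beta)^2), ols = sum((o - beta)^2))
  })
  expect_lt(mean(errs["huber", ]), mean(errs["ols", ]))
})

test_that("distance correlation matches the O(n^2) double-loop oracle", {
  set.seed(3)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200)
  expect_equal(distance_correlation(x, y), dcor_naive(x, y),
               tolerance = 1e-10)
  z <- runif(200)
  expect_equal(distance_correlation(x, z), dcor_naive(x, z),
               tolerance = 1e-10)
  # basic invariances
  expect_equal(distance_correlation(x, x), 1, tolerance = 1e-12)
  expect_equal(distance_correlation(x, -x), 1, tolerance = 1e-12)
  expect_equal(distance_correlation(x, 3 * y + 2),
               distance_correlation(x, y), tolerance = 1e-12)
  cst <- distance_correlation(x, rep(1, 200))
  expect_identical(as.numeric(cst), 0)
  expect_true(isTRUE(attr(cst, "constant_input")))
  expect_error(distance_correlation(x, y[-1]), "equal length")
  expect_error(distance_correlation(1:3, 1:3), "n >= 4")
})

test_that("dcor increases to 1 as noise vanishes (median-monotone sweep)", {
  set.seed(11)
  x <- rnorm(300)
  med <- vapply(c(2, 1, 0.5, 0.1, 0), function(s) {
    stats::median(replicate(5, distance_correlation(x, x + rnorm(300, 0, s))))
  }, numeric(1))
  expect_true(all(diff(med) >= -1e-10))
  expect_equal(med[5], 1, tolerance = 1e-12)
})

test_that("decomposition recovers pure, combined and permuted profiles", {
  mk_de <- function(lfc) {
    data.frame(gene = paste0("g", seq_along(lfc)), baseMean_control = 1,
               lfc_log2 = lfc, lr_stat = 1, pvalue = 1e-4, fdr = 1e-3)
  }
  set.seed(21)
  n <- 5000
  profs <- list(Dgcr8 = rnorm(n, 0, 0.4), Gnb1l = rnorm(n, 0, 0.4),
                Dgcr14 = rnorm(n, 0, 0.4))
  # deletion profile equals one perturbation exactly
  d1 <- decompose_deletion(mk_de(profs$Dgcr8), lapply(profs, mk_de))
  expect_equal(unname(d1$coefficients), c(1, 0, 0), tolerance = 1e-6)
  expect_equal(d1$dcor, 1, tolerance = 1e-6)
  # predicted vector identity holds exactly
  Xm <- vapply(profs, identity, numeric(n))
  expect_equal(unname(d1$predicted),
               unname(d1$intercept + Xm %*% d1$coefficients)[, 1],
               tolerance = 1e-12)
  # stated combination + noise: weights recovered
  w <- c(Dgcr8 = 0.21, Gnb1l = 0.18, Dgcr14 = -0.11)
  y <- as.numeric(Xm %*% w) + rnorm(n, 0, 0.3)
  d2 <- decompose_deletion(mk_de(y), lapply(profs, mk_de))
  expect_equal(d2$coefficients, w, tolerance = 0.05)
  expect_identical(nrow(d2$top_table), 100L)
  expect_true(all(abs(d2$top_table$predicted_lfc) >=
                    max(abs(d2$predicted[!names(d2$predicted) %in%
                                           d2$top_table$gene]))))
  # gene-shuffled combination: dcor collapses
  d3 <- decompose_deletion(mk_de(sample(y)), lapply(profs, mk_de))
  expect_lt(d3$dcor, 0.1)
})

test_that("end-to-end cohort decomposition recovers generating weights", {
  # the per-seed coefficient sd is ~0.03 (gene noise 0.3 over 100 program
  # genes), so bias is assessed on the mean over seeds
  w <- c(Dgcr8 = 0.21, Gnb1l = 0.18, Dgcr14 = -0.11)
  one_run <- function(seed) {
    cfg <- simulation_config(n_genes = 1500, cell_types = c(neuron = 1),
                             program_size = 50, effect_lfc = 1, seed = seed)
    coh <- simulate_deletion_cohort(cfg, w, deleted_genes = 10,
                                    nuclei_per_animal = 400, noise_sd = 0.3)
    pb <- make_pseudobulk(coh$counts, "animal", group_key = "condition")
    genes <- filter_expressed_genes(coh$counts, "WT", group_col = "condition")
    de <- nb_glm_lrt(pb, estimate_dispersions(pb), c("DEL", "WT"),
                     genes = genes)
    # perturbation profiles: the true program LFC vectors (a perfectly
    # estimated single-perturbation experiment)
    perf <- lapply(coh$truth$programs, function(pr) {
      lfc <- numeric(length(genes)); names(lfc) <- genes
      common <- intersect(pr$gene, genes)
      lfc[common] <- pr$true_lfc[match(common, pr$gene)]
      data.frame(gene = genes, baseMean_control = 1, lfc_log2 = unname(lfc),
                 lr_stat = 1, pvalue = 1e-4, fdr = 1e-3)
    })
    dec <- decompose_deletion(de, perf,
                              genes = setdiff(genes, coh$truth$deleted_genes))
    c(dec$coefficients, dcor = dec$dcor)
  }
  runs <- vapply(41:46, one_run, numeric(4))
  bias <- rowMeans(runs[names(w), ]) - w
  expect_lt(max(abs(bias)), 0.05)
  expect_gt(median(runs["dcor", ]), 0.2)
})
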