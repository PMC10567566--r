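# Negative-binomial GLM machinery, vectorized across genes.
#
# All models here are one-way layouts (group means with log-library-size
# offsets), for which the likelihood separates by group: each group's
# coefficient is a 1-parameter NB GLM fitted by damped IRLS, run
# simultaneously for all genes via matrix arithmetic. This keeps the
# per-gene fits exact while avoiding a per-gene loop.

# log-likelihood of NB(mu, dispersion d) row-wise; d may be per-gene.
.nb_loglik <- function(Y, MU, disp) {
  if (length(disp) == 1L) disp <- rep(disp, nrow(Y))
  pois <- disp < 1e-10
  ll <- numeric(nrow(Y))
  if (any(pois))
    ll[pois] <- rowSums(stats::dpois(Y[pois, , drop = FALSE],
                                     MU[pois, , drop = FALSE], log = TRUE))
  if (any(!pois)) {
    sz <- 1 / disp[!pois]
    ll[!pois] <- rowSums(stats::dnbinom(Y[!pois, , drop = FALSE],
                                        size = sz,
                                        mu = MU[!pois, , drop = FALSE],
                                        log = TRUE))
  }
  ll
}

# One-parameter NB GLM per gene: y_gj ~ NB(exp(beta_g + o_j), d_g).
# Returns beta (G), loglik (G), cr_info (G, = log sum of IRLS weights,
# the Cox-Reid information term for this block), converged (G).
.nb_fit1 <- function(Y, offset, disp, tol = 1e-8, maxit = 50L) {
  G <- nrow(Y); n <- ncol(Y)
  if (length(disp) == 1L) disp <- rep(disp, G)
  eo <- exp(offset)
  beta <- log((rowSums(Y) + 0.5) / sum(eo))
  O <- matrix(offset, G, n, byrow = TRUE)
  D <- matrix(disp, G, n)
  MU <- exp(beta + O)
  ll <- .nb_loglik(Y, MU, disp)
  moved <- rep(Inf, G)
  for (it in seq_len(maxit)) {
    W <- MU / (1 + D * MU)
    score <- rowSums((Y - MU) / (1 + D * MU))
    info <- rowSums(W)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    repeat {
      beta_new <- pmin(pmax(beta + step, -30), 30)
      MU_new <- exp(beta_new + O)
      ll_new <- .nb_loglik(Y, MU_new, disp)
      bad <- ll_new < ll - 1e-12 & abs(step) > 1e-12
      if (!any(bad)) break
      step[bad] <- step[bad] / 2           # damped step on likelihood decrease
    }
    moved <- abs(beta_new - beta)
    beta <- beta_new; MU <- MU_new; ll <- ll_new
    if (all(moved < tol)) break
  }
  W <- MU / (1 + D * MU)
  list(beta = beta, loglik = ll, cr_info = log(pmax(rowSums(W), 1e-300)),
       converged = moved < tol * 10 | abs(beta) >= 30, mu = MU)
}

# One-way NB fit: independent group-mean fits; returns per-gene total
# log-likelihood, Cox-Reid adjustment (sum of log information over
# groups), and the per-group coefficients.
.nb_fit_oneway <- function(Y, group, offset, disp) {
  group <- as.factor(group)
  ll <- numeric(nrow(Y)); cr <- numeric(nrow(Y))
  beta <- matrix(NA_real_, nrow(Y), nlevels(group),
                 dimnames = list(rownames(Y), levels(group)))
  conv <- rep(TRUE, nrow(Y))
  for (g in levels(group)) {
    j <- group == g
    f <- .nb_fit1(Y[, j, drop = FALSE], offset[j], disp)
    ll <- ll + f$loglik
    cr <- cr + f$cr_info
    beta[, g] <- f$beta
    conv <- conv & f$converged
  }
  list(loglik = ll, cr = cr, beta = beta, converged = conv)
}

#' Estimate negative-binomial dispersions
#'
#' Estimates per-gene dispersions by maximum Cox-Reid adjusted profile
#' likelihood (APL) on a log-spaced grid with quadratic interpolation, a
#' common dispersion by maximizing the gene-summed APL, and shrunken
#' (tagwise) dispersions by maximizing a weighted APL in which each gene's
#' own likelihood is augmented by `prior_df / residual_df` times the
#' average APL of all genes. Shrunken values are clamped to lie between
#' the raw and common estimates.
#'
#' @param pb A [make_pseudobulk()] object (or a plain count matrix).
#' @param group Factor of group memberships, one per column (defaults to
#'   `pb$samples$group`).
#' @param prior_df Prior degrees of freedom of the empirical-Bayes
#'   shrinkage (default 10).
#' @param use_tmm Apply TMM normalization factors to the library-size
#'   offsets (default `TRUE`); otherwise plain library sizes.
#' @param grid Dispersion grid (default 15 log-spaced points in
#'   `[1e-4, 4]`).
#' @return A list of class `dispersion_model`: `raw`, `common`, `tagwise`
#'   (per-gene), `prior_df`, `offset` (the log effective library sizes
#'   used).
#' @export
estimate_dispersions <- function(pb, group = NULL, prior_df = 10,
                                 use_tmm = TRUE,
                                 grid = exp(seq(log(1e-4), log(4),
                                                length.out = 15))) {
  if (inherits(pb, "pseudobulk")) {
    Y <- pb$counts
    if (is.null(group)) group <- pb$samples$group
  } else Y <- as.matrix(pb)
  group <- as.factor(group)
  if (min(table(group)) < 2)
    stop("single-replicate design: use a common dispersion supplied externally")
  lib <- colSums(Y)
  fac <- if (use_tmm) tmm_factors(Y) else rep(1, ncol(Y))
  offset <- log(lib * fac)
  apl <- vapply(grid, function(d) {
    f <- .nb_fit_oneway(Y, group, offset, d)
    f$loglik - 0.5 * f$cr
  }, numeric(nrow(Y)))                         # genes x grid
  ldisp <- log(grid)
  pick <- function(vals) {                     # quadratic interpolation at max
    i <- which.max(vals)
    if (i == 1L) return(0)                     # edge: effectively Poisson
    if (i == length(grid)) return(grid[i])
    x <- ldisp[(i - 1):(i + 1)]; y <- vals[(i - 1):(i + 1)]
    den <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / den
    b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / den
    if (a >= 0) return(exp(x[2]))
    exp(min(max(-b / (2 * a), x[1]), x[3]))
  }
  raw <- apply(apl, 1, pick)
  common <- pick(colSums(apl))
  resid_df <- ncol(Y) - nlevels(group)
  w <- prior_df / max(resid_df, 1)
  mean_apl <- colMeans(apl)
  tagwise <- apply(apl + rep(w * mean_apl, each = nrow(apl)), 1, pick)
  lo <- pmin(raw, common); hi <- pmax(raw, common)
  tagwise <- pmin(pmax(tagwise, lo), hi)
  structure(list(raw = raw, common = common, tagwise = tagwise,
                 prior_df = prior_df, offset = offset),
            class = "dispersion_model")
}

#' Negative-binomial GLM likelihood-ratio test
#'
#' Tests one group against the control for every gene with a NB GLM
#' (group-means parameterization with log effective-library-size offsets).
#' The likelihood-ratio statistic `2 (loglik_full - loglik_null)` is
#' referred to a chi-square with one degree of freedom; the reported fold
#' change is the group-vs-control coefficient in log2; p-values are
#' Benjamini-Hochberg adjusted across tested genes. Genes with zero
#' counts in both groups are excluded (their fold change is undefined).
#'
#' @param pb A [make_pseudobulk()] object.
#' @param disp A [estimate_dispersions()] model (its `tagwise` values and
#'   offsets are used), or a numeric dispersion (scalar or per-gene).
#' @param contrast Character pair `c(group, control)`.
#' @param genes Optional gene subset (e.g. from
#'   [filter_expressed_genes()]).
#' @return A `data.frame` of class `de_table`: `gene`, `baseMean_control`
#'   (raw UMI per control nucleus where nucleus counts are available,
#'   otherwise per-library mean), `lfc_log2`, `lr_stat`, `pvalue`, `fdr`,
#'   plus contrast metadata in attributes.
#' @export
nb_glm_lrt <- function(pb, disp, contrast, genes = NULL) {
  stopifnot(inherits(pb, "pseudobulk"), length(contrast) == 2)
  sel <- pb$samples$group %in% contrast
  if (sum(pb$samples$group == contrast[1]) < 2 ||
      sum(pb$samples$group == contrast[2]) < 2)
    stop("both contrast groups need >= 2 pseudobulk columns")
  Y <- pb$counts[, sel, drop = FALSE]
  grp <- factor(pb$samples$group[sel], levels = rev(contrast)) # control first
  if (!is.null(genes)) Y <- Y[intersect(genes, rownames(Y)), , drop = FALSE]
  nz <- rowSums(Y) > 0
  if (!all(nz)) Y <- Y[nz, , drop = FALSE]
  if (inherits(disp, "dispersion_model")) {
    offset <- disp$offset[sel]
    d <- disp$tagwise[match(rownames(Y), names(disp$tagwise))]
    if (anyNA(d)) d[is.na(d)] <- disp$common
  } else {
    offset <- log(colSums(pb$counts)[sel])
    d <- rep(disp, length.out = nrow(pb$counts))[match(rownames(Y), rownames(pb$counts))]
  }
  full <- .nb_fit_oneway(Y, grp, offset, d)
  null <- .nb_fit1(Y, offset, d)
  lr <- pmax(2 * (full$loglik - null$loglik), 0)
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  p[!full$converged] <- NA
  lfc <- (full$beta[, contrast[1]] - full$beta[, contrast[2]]) / log(2)
  ctrl_cols <- pb$samples$group == contrast[2]
  n_ctrl_nuc <- sum(pb$samples$n_nuclei[ctrl_cols])
  base <- rowSums(pb$counts[rownames(Y), ctrl_cols, drop = FALSE]) /
    if (is.na(n_ctrl_nuc) || n_ctrl_nuc == 0) sum(ctrl_cols) else n_ctrl_nuc
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], "BH")
  out <- data.frame(gene = rownames(Y), baseMean_control = base,
                    lfc_log2 = lfc, lr_stat = lr, pvalue = p, fdr = fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- contrast
  attr(out, "cell_type") <- pb$samples$cell_type[1]
  class(out) <- c("de_table", "data.frame")
  out
}

#' Single-cell logistic-regression differential expression
#'
#' Per gene, regresses the group label (group vs control) on normalized
#' expression by logistic regression and tests the expression coefficient
#' with a likelihood-ratio test against the intercept-only model
#' (chi-square, 1 df); BH adjustment across genes. This is the
#' single-cell-level comparator to the pseudobulk test.
#'
#' @param norm_expr Normalized expression (genes x nuclei), e.g. from
#'   [normalize_log1p()].
#' @param labels Group label per nucleus.
#' @param contrast Character pair `c(group, control)`.
#' @param genes Optional gene subset.
#' @return A `de_table` data.frame (`lfc_log2` here is the difference of
#'   group means of normalized expression divided by `log(2)`, reported
#'   for orientation only; `flag` marks non-converged / separated fits).
#' @export
single_cell_logreg_de <- function(norm_expr, labels, contrast, genes = NULL) {
  stopifnot(length(contrast) == 2)
  sel <- labels %in% contrast
  X <- norm_expr[, sel, drop = FALSE]
  if (!is.null(genes)) X <- X[intersect(genes, rownames(X)), , drop = FALSE]
  y <- as.integer(labels[sel] == contrast[1])
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2 || n0 < 2) stop("both groups need >= 2 nuclei")
  dev_null <- -2 * (n1 * log(n1 / (n1 + n0)) + n0 * log(n0 / (n1 + n0)))
  res <- t(vapply(seq_len(nrow(X)), function(i) {
    x <- as.numeric(X[i, ])
    if (stats::var(x) == 0) return(c(0, 1, 0))
    fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y,
                                           family = stats::binomial()))
    lr <- max(dev_null - fit$deviance, 0)
    flag <- as.numeric(!fit$converged || any(abs(fit$coefficients) > 15))
    c(lr, stats::pchisq(lr, 1, lower.tail = FALSE), flag)
  }, numeric(3)))
  m1 <- rowMeans(X[, y == 1, drop = FALSE]); m0 <- rowMeans(X[, y == 0, drop = FALSE])
  out <- data.frame(gene = rownames(X), baseMean_control = as.numeric(m0),
                    lfc_log2 = as.numeric(m1 - m0) / log(2),
                    lr_stat = res[, 1], pvalue = res[, 2],
                    fdr = stats::p.adjust(res[, 2], "BH"),
                    flag = res[, 3] > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- contrast
  class(out) <- c("de_table", "data.frame")
  out
}
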