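#' Huber robust linear regression (M-estimation by IRLS)
#'
#' Fits `y ~ X` by iteratively reweighted least squares with the Huber psi
#' function (tuning constant `k = 1.345` gives ~95 percent Gaussian
#' efficiency). The residual scale is re-estimated at every iteration as
#' the median absolute deviation (consistent for the Gaussian sd);
#' iteration stops when the largest coefficient change falls below `tol`
#' or after `maxit` iterations.
#'
#' @param y Response vector (here: the deletion LFC profile).
#' @param X Predictor matrix (columns: per-perturbation LFC profiles).
#' @param intercept Include an intercept column (default `TRUE`); the
#'   no-intercept mode reproduces a strict linear-combination model.
#' @param k Huber tuning constant (default 1.345).
#' @param tol Convergence tolerance on coefficients (default 1e-8).
#' @param maxit Maximum IRLS iterations (default 50).
#' @return A list of class `huber_fit`: `coefficients` (named, per
#'   predictor), `intercept`, `fitted`, `residuals`, `scale`,
#'   `iterations`, `converged`.
#' @export
huber_rlm <- function(y, X, intercept = TRUE, k = 1.345, tol = 1e-8,
                      maxit = 50L) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("rows of y and X differ")
  if (anyNA(y) || anyNA(X)) stop("missing values are not allowed")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xd <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qr_x$pivot[(qr_x$rank + 1):ncol(Xd)]]
    stop("rank-deficient predictor matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)                 # OLS start
  for (it in seq_len(maxit)) {
    r <- y - Xd %*% beta
    s <- stats::median(abs(r)) / 0.6744898  # MAD scale, re-estimated each step
    if (s < .Machine$double.eps) { it <- it; break }  # exact fit
    u <- abs(r / s)
    w <- ifelse(u <= k, 1, k / u)           # Huber weights
    beta_new <- qr.coef(qr(Xd * sqrt(as.numeric(w))), y * sqrt(as.numeric(w)))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) break
  }
  fitted <- as.numeric(Xd %*% beta)
  structure(list(
    coefficients = if (intercept) beta[-1] else beta,
    intercept = if (intercept) unname(beta[1]) else 0,
    fitted = fitted, residuals = y - fitted,
    scale = stats::median(abs(y - fitted)) / 0.6744898,
    iterations = it, converged = it < maxit), class = "huber_fit")
}

#' Distance correlation (biased V-statistic estimator)
#'
#' Computes the sample distance correlation of two vectors from
#' double-centered Euclidean distance matrices `A`, `B`:
#' `dCov^2 = mean(A * B)` and `dcor = dCov / sqrt(dVar_x dVar_y)`.
#' Returns 0 (with a flag attribute) when either variable is constant.
#' This is the classical biased estimator; the bias-corrected variant is
#' available via `unbiased = TRUE`.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`.
#' @param unbiased Use the U-statistic (bias-corrected) estimator.
#' @return Distance correlation in `[0, 1]` (the unbiased estimator can
#'   be slightly negative and is then reported as is).
#' @export
distance_correlation <- function(x, y, unbiased = FALSE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need n >= 4")
  a <- as.matrix(stats::dist(x))
  b <- as.matrix(stats::dist(y))
  if (all(a == 0) || all(b == 0)) {
    out <- 0
    attr(out, "constant_input") <- TRUE
    return(out)
  }
  if (!unbiased) {
    A <- a - outer(rowMeans(a), rep(1, n)) - outer(rep(1, n), colMeans(a)) + mean(a)
    B <- b - outer(rowMeans(b), rep(1, n)) - outer(rep(1, n), colMeans(b)) + mean(b)
    dcov2 <- mean(A * B)
    dvx <- mean(A * A); dvy <- mean(B * B)
    if (dvx <= 0 || dvy <= 0) return(0)
    sqrt(max(dcov2, 0)) / (dvx * dvy)^(1 / 4)
  } else {
    U <- function(d) {
      m <- d - outer(rowSums(d), rep(1, n)) / (n - 2) -
        outer(rep(1, n), colSums(d)) / (n - 2) + sum(d) / ((n - 1) * (n - 2))
      diag(m) <- 0
      m
    }
    A <- U(a); B <- U(b)
    h <- function(M1, M2) sum(M1 * M2) / (n * (n - 3))
    dcov2 <- h(A, B); dvx <- h(A, A); dvy <- h(B, B)
    if (dvx <= 0 || dvy <= 0) return(0)
    sign(dcov2) * sqrt(abs(dcov2)) / (dvx * dvy)^(1 / 4)
  }
}

#' Decompose a deletion LFC profile into perturbation signatures
#'
#' Models the deletion (aggregate-phenotype) log2 fold-change vector as a
#' linear combination of single-perturbation LFC vectors, fitted by Huber
#' robust regression on the shared expressed-gene universe, and scores
#' the fit by the distance correlation between observed and predicted
#' profiles. Also reports the top-`k` predicted genes ranked by absolute
#' predicted LFC.
#'
#' @param deletion_de `de_table` of the deletion-vs-wild-type contrast.
#' @param perturbation_des Named list of `de_table`s, one per
#'   perturbation.
#' @param genes Optional fixed gene universe; defaults to the
#'   intersection of all tables' genes (each already restricted to its
#'   dataset's expressed genes).
#' @param top_k Size of the predicted-gene table (default 100).
#' @param intercept Passed to [huber_rlm()].
#' @param ... Further arguments to [huber_rlm()].
#' @return A list of class `decomposition_result`: `coefficients`,
#'   `intercept`, `dcor`, `genes`, `predicted` (named vector),
#'   `observed`, `top_table` (gene, observed, per-perturbation and
#'   predicted LFC).
#' @export
decompose_deletion <- function(deletion_de, perturbation_des, genes = NULL,
                               top_k = 100, intercept = TRUE, ...) {
  stopifnot(length(perturbation_des) >= 1)
  if (is.null(names(perturbation_des)))
    names(perturbation_des) <- paste0("P", seq_along(perturbation_des))
  universe <- Reduce(intersect, c(list(deletion_de$gene),
                                  lapply(perturbation_des, `[[`, "gene")))
  if (!is.null(genes)) universe <- intersect(universe, genes)
  if (!length(universe)) stop("empty shared gene universe")
  y <- deletion_de$lfc_log2[match(universe, deletion_de$gene)]
  X <- vapply(perturbation_des,
              function(d) d$lfc_log2[match(universe, d$gene)],
              numeric(length(universe)))
  fit <- huber_rlm(y, X, intercept = intercept, ...)
  pred <- fit$fitted
  names(pred) <- universe
  d <- distance_correlation(y, pred)
  ord <- order(-abs(pred))[seq_len(min(top_k, length(pred)))]
  top <- data.frame(gene = universe[ord], observed_lfc = y[ord],
                    X[ord, , drop = FALSE], predicted_lfc = pred[ord],
                    row.names = NULL, check.names = FALSE)
  structure(list(coefficients = fit$coefficients, intercept = fit$intercept,
                 dcor = as.numeric(d), genes = universe, predicted = pred,
                 observed = stats::setNames(y, universe), top_table = top,
                 fit = fit),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("deletion-profile decomposition\n")
  cat("  coefficients:",
      paste(sprintf("%s = %.3f", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  intercept = %.4f, dcor = %.3f, genes = %d\n",
              x$intercept, x$dcor, length(x$genes)))
  invisible(x)
}
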