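#' Centered genomic kinship matrix
#'
#' `K = (1/L) sum_i (x_i - mean(x_i)) (x_i - mean(x_i))'` over loci, i.e.
#' the column-centered (not variance-scaled) genomic relationship matrix.
#' Missing dosages are mean-imputed per locus, the stand-in for a
#' dedicated genotype-imputation step; at >= 80% completeness the
#' difference is second-order for the kinship control.
#'
#' @param x a `genotype_table` with >= 2 polymorphic loci.
#' @return symmetric positive semi-definite samples x samples matrix.
#' @export
centered_kinship <- function(x) {
  g <- x$geno
  p <- allele_freqs(x)
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2L) stop("need >= 2 polymorphic loci for kinship")
  g <- g[, poly, drop = FALSE]
  X <- apply(g, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  Xc <- sweep(X, 2, colMeans(X), "-")
  K <- tcrossprod(Xc) / ncol(Xc)
  dimnames(K) <- list(rownames(g), rownames(g))
  K
}

## Profile ML log-likelihood pieces for one variance ratio lambda
## (lambda = sigma_g^2 / sigma_e^2) on data rotated into the (n-1)-dim
## complement of the intercept (the EMMA construction: covariates are
## projected out before the eigendecomposition, so the likelihood in
## lambda is well behaved at both ends). Vectorized across SNP columns.
lmm_profile <- function(lambda, d, ys, Xs) {
  m <- length(ys)
  v <- 1 / (lambda * d + 1)
  syy <- sum(v * ys * ys)
  vx <- v * Xs
  sxx <- colSums(vx * Xs)
  sxy <- colSums(vx * ys)
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 1e-300)
  ll <- -0.5 * (m * log(2 * pi * rss / m) + m + sum(log(lambda * d + 1)))
  list(beta = beta, rss = rss, ll = ll, sxx = sxx)
}

#' Per-SNP linear mixed-model association scan
#'
#' Fits, at every locus, the model `y = mu + x beta + u + e` with
#' `u ~ N(0, sigma_g^2 K)` and `e ~ N(0, sigma_e^2 I)` — the standard
#' kinship-controlled single-SNP mixed model. The intercept is projected
#' out and the restricted kinship eigendecomposed once on its orthogonal
#' complement; per SNP the likelihood is maximized over the variance ratio
#' `lambda = sigma_g^2 / sigma_e^2` on a log-spaced grid with local
#' refinement (ML, not REML), and `beta = 0` is tested by a Wald test with
#' p-values from `F(1, n - 2)`. The genome-wide Bonferroni threshold
#' `0.05 / L` is attached. With `K = I` every result collapses exactly to
#' the ordinary least-squares Wald test.
#'
#' The phenotype is the colony social form broadcast to its workers
#' (0 = monogyne, 1 = polygyne) and treated as quantitative, as the
#' standard mixed-model association tools do for binary traits; the
#' non-independence of nestmates is what `K` absorbs. Transect samples and
#' workers from undetermined colonies must be excluded by the caller.
#'
#' @param x a `genotype_table` (missing dosages mean-imputed internally).
#' @param phenotype named or positional numeric vector of 0/1 phenotypes,
#'   one per sample; must contain both classes.
#' @param K kinship matrix from [centered_kinship()] (computed from `x`
#'   when `NULL`).
#' @param lambda_grid grid of variance ratios searched (log-spaced).
#' @return data.frame of class `lmm_scan`: chrom, pos, beta, se, wald
#'   statistic, p, lambda, plus attributes `bonferroni` and `n`.
#'   Monomorphic loci are skipped and listed in attribute `skipped`.
#' @export
lmm_scan <- function(x, phenotype, K = NULL,
                     lambda_grid = 10^seq(-5, 5, length.out = 61)) {
  g <- x$geno
  n <- nrow(g)
  if (length(phenotype) != n) stop("phenotype length must match samples")
  if (!is.null(names(phenotype))) phenotype <- phenotype[rownames(g)]
  y <- as.numeric(phenotype)
  if (any(is.na(y))) stop("phenotype must be defined for all samples")
  if (length(unique(y)) < 2L) stop("phenotype is constant")
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary 0/1")
  if (is.null(K)) K <- centered_kinship(x)
  X <- apply(g, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  sdev <- apply(X, 2, stats::sd)
  usable <- sdev > 0
  skipped <- which(!usable)
  Xu <- X[, usable, drop = FALSE]
  L <- ncol(Xu)
  if (L == 0L) stop("no polymorphic loci to test")

  ## rotate into the orthogonal complement of the intercept, then
  ## eigendecompose the restricted kinship once (EMMA construction)
  Tb <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  e <- eigen(crossprod(Tb, K %*% Tb), symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  ys <- drop(crossprod(U, crossprod(Tb, y)))
  Xs <- crossprod(U, crossprod(Tb, Xu))
  m <- n - 1L

  ## grid search on the profiled ML likelihood, vectorized across SNPs
  ll_mat <- matrix(NA_real_, length(lambda_grid), L)
  for (i in seq_along(lambda_grid)) {
    ll_mat[i, ] <- lmm_profile(lambda_grid[i], d, ys, Xs)$ll
  }
  best <- max.col(t(ll_mat), ties.method = "first")

  beta <- se <- stat <- pval <- lam <- numeric(L)
  log_grid <- log10(lambda_grid)
  for (j in seq_len(L)) {
    xj <- Xs[, j]
    f <- function(lg) lmm_profile(10^lg, d, ys, matrix(xj))$ll
    lo <- log_grid[max(1L, best[j] - 1L)]
    hi <- log_grid[min(length(log_grid), best[j] + 1L)]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-4)
    cand_ll <- c(opt$objective, ll_mat[best[j], j])
    cand_lg <- c(opt$maximum, log_grid[best[j]])
    lam[j] <- 10^cand_lg[which.max(cand_ll)]
    fit <- lmm_profile(lam[j], d, ys, matrix(xj))
    sigma2 <- fit$rss / (m - 1)
    beta[j] <- fit$beta
    se[j] <- sqrt(sigma2 / fit$sxx)
    stat[j] <- (beta[j] / se[j])^2
    pval[j] <- stats::pf(stat[j], 1, m - 1, lower.tail = FALSE)
  }
  loci <- x$loci[usable, , drop = FALSE]
  bonf <- 0.05 / L
  out <- data.frame(chrom = loci$chrom, pos = loci$pos,
                    beta = beta, se = se, wald = stat, p = pval,
                    lambda = lam,
                    significant = pval < bonf,
                    stringsAsFactors = FALSE)
  attr(out, "bonferroni") <- bonf
  attr(out, "n") <- n
  attr(out, "skipped") <- skipped
  class(out) <- c("lmm_scan", class(out))
  out
}
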