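# Small builders shared across test files. Fixtures are constructed in
# code; nothing is read from disk except temp files a test writes itself.

mk_tab <- function(m, chrom = "chr1", pos = NULL, depths = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  }
  if (is.null(pos)) pos <- seq_len(ncol(m))
  loci <- data.frame(chrom = rep_len(chrom, ncol(m)), pos = pos,
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_table(m, loci, depths)
}

# random HWE dosage matrix
hwe_geno <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- sapply(p, function(pp) stats::rbinom(n, 2, pp))
  rownames(m) <- sprintf("s%03d", seq_len(n))
  m
}

# scalar-loop oracle implementations, deliberately written pair-by-pair
# and locus-by-locus so they share no code path with the package
oracle_ajk <- function(g) {
  p <- colMeans(g, na.rm = TRUE) / 2
  n <- nrow(g)
  A <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    num <- 0; cnt <- 0
    for (i in seq_len(ncol(g))) {
      if (p[i] <= 0 || p[i] >= 1) next
      xj <- g[j, i]; xk <- g[k, i]
      if (is.na(xj) || is.na(xk)) next
      d <- 2 * p[i] * (1 - p[i])
      if (j == k) {
        num <- num + (xj^2 - (1 + 2 * p[i]) * xj + 2 * p[i]^2) / d
      } else {
        num <- num + (xj - 2 * p[i]) * (xk - 2 * p[i]) / d
      }
      cnt <- cnt + 1
    }
    A[j, k] <- if (j == k) 1 + num / cnt else num / cnt
  }
  A
}

oracle_king <- function(g) {
  n <- nrow(g)
  phi <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    both_het <- 0; opp <- 0; het_j <- 0; het_k <- 0
    for (i in seq_len(ncol(g))) {
      xj <- g[j, i]; xk <- g[k, i]
      if (is.na(xj) || is.na(xk)) next
      if (xj == 1 && xk == 1) both_het <- both_het + 1
      if (abs(xj - xk) == 2) opp <- opp + 1
      if (xj == 1) het_j <- het_j + 1
      if (xk == 1) het_k <- het_k + 1
    }
    if (het_j + het_k > 0) {
      phi[j, k] <- (both_het - 2 * opp) / (het_j + het_k)
    }
  }
  phi
}

oracle_qg <- function(g) {
  p <- colMeans(g, na.rm = TRUE) / 2
  n <- nrow(g)
  r <- matrix(NA_real_, n, n)
  locus_terms <- function(x, y, pp) {
    qq <- 1 - pp
    ax <- x; rx <- 2 - x
    ay <- y; ry <- 2 - y
    S <- 0.5 * (ax * ay + rx * ry)
    num <- S - (ax * pp + rx * qq)
    den <- 1 + (x != 1) - (ax * pp + rx * qq)
    c(num, den)
  }
  for (j in seq_len(n)) for (k in seq_len(n)) {
    num <- 0; den <- 0
    for (i in seq_len(ncol(g))) {
      if (p[i] <= 0 || p[i] >= 1) next
      xj <- g[j, i]; xk <- g[k, i]
      if (is.na(xj) || is.na(xk)) next
      tj <- locus_terms(xj, xk, p[i])
      tk <- locus_terms(xk, xj, p[i])
      num <- num + tj[1] + tk[1]
      den <- den + tj[2] + tk[2]
    }
    if (den != 0) r[j, k] <- num / den
  }
  r
}

oracle_fis <- function(g) {
  p <- colMeans(g, na.rm = TRUE) / 2
  nall <- 2 * colSums(!is.na(g))
  f <- numeric(nrow(g))
  for (j in seq_len(nrow(g))) {
    O <- 0; E <- 0; L <- 0
    for (i in seq_len(ncol(g))) {
      if (is.na(g[j, i]) || is.na(p[i]) || nall[i] < 2) next
      L <- L + 1
      if (g[j, i] != 1) O <- O + 1
      E <- E + 1 - 2 * p[i] * (1 - p[i]) * nall[i] / (nall[i] - 1)
    }
    f[j] <- (O - E) / (L - E)
  }
  f
}

# independent per-locus Weir-Cockerham 1984 components, scalar transcription
oracle_wc_fst <- function(gA, gB, aggregate = c("ratio_of_sums",
                                                "mean_of_ratios")) {
  aggregate <- match.arg(aggregate)
  av <- bv <- cv <- c()
  for (i in seq_len(ncol(gA))) {
    la <- gA[, i]; lb <- gB[, i]
    la <- la[!is.na(la)]; lb <- lb[!is.na(lb)]
    nA <- length(la); nB <- length(lb)
    if (nA < 1 || nB < 1) next
    pA <- sum(la) / (2 * nA); pB <- sum(lb) / (2 * nB)
    ptot <- (2 * nA * pA + 2 * nB * pB) / (2 * nA + 2 * nB)
    if (ptot <= 0 || ptot >= 1) next
    hA <- mean(la == 1); hB <- mean(lb == 1)
    r <- 2
    nbar <- (nA + nB) / r
    nc <- (nA + nB - (nA^2 + nB^2) / (nA + nB)) / (r - 1)
    pbar <- (nA * pA + nB * pB) / (r * nbar)
    s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
    hbar <- (nA * hA + nB * hB) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    av <- c(av, a); bv <- c(bv, b); cv <- c(cv, cc)
  }
  if (aggregate == "ratio_of_sums") {
    sum(av) / sum(av + bv + cv)
  } else {
    mean(av / (av + bv + cv))
  }
}

# default-ish config scaled down for speed
quick_cfg <- function(...) {
  args <- utils::modifyList(
    list(colonies_per_region = 4, n_transect_per_region = 2, seed = 1L),
    list(...))
  do.call(sim_config, args)
}
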