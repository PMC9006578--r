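## Pairwise relatedness / kinship estimators.
##
## All estimators share the same conventions: allele frequencies are sample
## frequencies computed over the full table that is passed in (pass the
## complete filtered dataset, not a single colony, then subset the matrix);
## missing data are handled per pair by restricting each pairwise sum to
## loci non-missing in both members ("pairwise complete"), never by
## imputation. Matrix products on zero-filled masked matrices implement the
## pairwise-complete sums.

pairwise_matrix <- function(est, n_loci, estimator) {
  structure(list(estimate = est, n_loci = n_loci, estimator = estimator),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  off <- x$estimate[upper.tri(x$estimate)]
  cat(sprintf("pairwise_matrix (%s): %d samples, mean off-diagonal %.4f\n",
              x$estimator, nrow(x$estimate), mean(off, na.rm = TRUE)))
  invisible(x)
}

masked <- function(geno) {
  m <- !is.na(geno)
  z <- geno
  z[!m] <- 0
  list(m = 1 * m, z = z)
}

#' Genomic-relationship (Ajk) estimator
#'
#' The unadjusted genomic relationship of each pair of individuals j and k
#' from SNP dosages: for j != k,
#' `A_jk = (1/N) sum_i (x_ij - 2p_i)(x_ik - 2p_i) / (2 p_i (1-p_i))`,
#' and on the diagonal
#' `A_jj = 1 + (1/N) sum_i (x_ij^2 - (1+2p_i) x_ij + 2p_i^2) / (2p_i(1-p_i))`,
#' with `p_i` the sample ALT frequency. Individuals in the sample are the
#' base, so pairwise values average ~0 within a panmictic population and
#' the self values average ~1 for non-inbred individuals. Loci missing in
#' either member of a pair are skipped, with `N` the per-pair retained
#' locus count.
#'
#' @param x a `genotype_table` with at least 2 polymorphic loci.
#' @return a `pairwise_matrix` (diagonal defined).
#' @export
ajk <- function(x) {
  p <- allele_freqs(x)
  keep <- !is.na(p) & p > 0 & p < 1
  if (sum(keep) < 2L) stop("need >= 2 polymorphic loci")
  g <- x$geno[, keep, drop = FALSE]
  p <- p[keep]
  mk <- masked(g)
  denom <- 2 * p * (1 - p)
  z <- sweep(mk$z, 2, 2 * p, "-") / rep(sqrt(denom), each = nrow(g))
  z[mk$m == 0] <- 0
  N <- mk$m %*% t(mk$m)
  A <- (z %*% t(z)) / N
  ## diagonal has its own moment form
  selfterm <- mk$z^2 - sweep(mk$z, 2, 1 + 2 * p, "*") +
    matrix(2 * p^2, nrow(g), length(p), byrow = TRUE)
  selfterm <- sweep(selfterm, 2, denom, "/")
  selfterm[mk$m == 0] <- 0
  diag(A) <- 1 + rowSums(selfterm) / diag(N)
  A[N == 0] <- NA_real_
  dimnames(A) <- list(rownames(g), rownames(g))
  pairwise_matrix(A, N, "ajk")
}

#' KING kinship coefficient
#'
#' Robust within-family kinship from heterozygote concordance:
#' `phi_jk = (N_AaAa - 2 N_AAaa) / (N_Aa(j) + N_Aa(k))`
#' over loci non-missing in both members, where `N_AaAa` counts loci with
#' both members heterozygous, `N_AAaa` counts opposite-homozygote loci and
#' `N_Aa(.)` counts heterozygous loci of each member within the shared set.
#' The maximum is 0.5, attained by duplicate genotypes. Pairs with a zero
#' denominator are returned as `NA`.
#'
#' @param x a `genotype_table`.
#' @return a `pairwise_matrix` (diagonal set to `NA`; KING has no self
#'   form).
#' @export
king_phi <- function(x) {
  g <- x$geno
  m <- 1 * !is.na(g)
  H <- 1 * (!is.na(g) & g == 1L)
  A0 <- 1 * (!is.na(g) & g == 0L)
  A2 <- 1 * (!is.na(g) & g == 2L)
  N_hh <- H %*% t(H)
  N_opp <- A0 %*% t(A2) + A2 %*% t(A0)
  Hm <- H %*% t(m) # loci het in j and non-missing in k
  den <- Hm + t(Hm)
  phi <- (N_hh - 2 * N_opp) / den
  phi[den == 0] <- NA_real_
  diag(phi) <- NA_real_
  N <- m %*% t(m)
  dimnames(phi) <- list(rownames(g), rownames(g))
  pairwise_matrix(phi, N, "king_phi")
}

#' Method-of-moments pairwise relatedness (Queller-Goodnight)
#'
#' Symmetrized Queller-Goodnight relatedness computed with sample allele
#' frequencies. Per locus, with an individual's alleles a, b and partner
#' alleles c, d, the focal numerator is the average allele-sharing score
#' minus the focal allele frequencies, and the denominator is
#' `1 + I(a==b) - p_a - p_b`; locus terms are summed over pairwise-complete
#' loci and the two directed ratios are pooled:
#' `r_jk = (num_jk + num_kj) / (den_jk + den_kj)`.
#' Expectation is ~0 for unrelated pairs, ~0.75 for haplodiploid full
#' sisters and ~1 for duplicates.
#'
#' @param x a `genotype_table`.
#' @return a `pairwise_matrix` (diagonal 1 by construction, reported).
#' @export
moments_relatedness <- function(x) {
  p <- allele_freqs(x)
  keep <- !is.na(p) & p > 0 & p < 1
  if (sum(keep) < 2L) stop("need >= 2 polymorphic loci")
  g <- x$geno[, keep, drop = FALSE]
  p <- p[keep]
  q <- 1 - p
  mk <- masked(g)
  X <- mk$z           # ALT allele counts, zero-filled
  R <- (2 - mk$z) * mk$m # REF allele counts, zero-filled
  ## allele-sharing score S = 0.5 * (ax*ay + rx*ry); summed pairwise via
  ## masked cross-products
  S <- 0.5 * (X %*% t(X) + R %*% t(R))
  ## focal allele-frequency term u = ax*p + rx*q per locus
  U <- sweep(X, 2, p, "*") + sweep(R, 2, q, "*")
  Upair <- U %*% t(mk$m)
  num <- S - Upair # directed: row = focal individual
  D <- (1 + (g != 1L)) - (sweep(X, 2, p, "*") + sweep(R, 2, q, "*"))
  D[is.na(g)] <- 0
  Dpair <- D %*% t(mk$m)
  den <- Dpair + t(Dpair)
  r <- (num + t(num)) / den
  r[den == 0] <- NA_real_
  N <- mk$m %*% t(mk$m)
  dimnames(r) <- list(rownames(g), rownames(g))
  pairwise_matrix(r, N, "moments")
}

#' Proportion of genome identical by descent (pi-hat)
#'
#' Method-of-moments IBD-state probabilities (P0, P1, P2) from observed
#' identity-by-state sharing counts versus their Hardy-Weinberg
#' expectations, evaluated over pairwise-complete loci, bounded to `[0,1]`
#' and renormalized; `pi_hat = P1/2 + P2`.
#'
#' @param x a `genotype_table`.
#' @return a `pairwise_matrix` (diagonal 1).
#' @export
pi_hat <- function(x) {
  p <- allele_freqs(x)
  keep <- !is.na(p) & p > 0 & p < 1
  if (sum(keep) < 2L) stop("need >= 2 polymorphic loci")
  g <- x$geno[, keep, drop = FALSE]
  p <- p[keep]
  q <- 1 - p
  m <- 1 * !is.na(g)
  H <- 1 * (!is.na(g) & g == 1L)
  A0 <- 1 * (!is.na(g) & g == 0L)
  A2 <- 1 * (!is.na(g) & g == 2L)
  N <- m %*% t(m)
  I0 <- A0 %*% t(A2) + A2 %*% t(A0)
  I2 <- A0 %*% t(A0) + H %*% t(H) + A2 %*% t(A2)
  I1 <- N - I0 - I2
  ## per-locus HWE class probabilities, summed over the shared-locus mask
  pairsum <- function(const) (m %*% (const * t(m)))
  e00 <- pairsum(2 * p^2 * q^2)
  e10 <- pairsum(4 * p^3 * q + 4 * p * q^3)
  e20 <- pairsum(p^4 + 4 * p^2 * q^2 + q^4)
  e11 <- pairsum(2 * p * q)
  e21 <- pairsum(p^2 + q^2)
  Z0 <- I0 / e00
  Z1 <- (I1 - Z0 * e10) / e11
  Z2 <- (I2 - Z0 * e20 - Z1 * e21) / N
  Z0 <- pmin(pmax(Z0, 0), 1)
  Z1 <- pmin(pmax(Z1, 0), 1)
  Z2 <- pmin(pmax(Z2, 0), 1)
  tot <- Z0 + Z1 + Z2
  pihat <- (0.5 * Z1 + Z2) / tot
  pihat[N == 0] <- NA_real_
  dimnames(pihat) <- list(rownames(g), rownames(g))
  pairwise_matrix(pihat, N, "pi_hat")
}

#' Per-individual inbreeding coefficient F
#'
#' Observed versus expected homozygosity per individual:
#' `F_j = (O_hom(j) - E_hom(j)) / (L_j - E_hom(j))`, where over the `L_j`
#' loci non-missing in individual j, `O_hom` counts homozygous calls and
#' `E_hom = sum_i [1 - 2 p_i (1-p_i) n_i / (n_i - 1)]`, with `n_i` the
#' non-missing allele count at locus i (the small-sample correction used by
#' standard `--het`-style heterozygosity reports). Negative values flag
#' heterozygosity excess.
#'
#' @param x a `genotype_table`.
#' @return named numeric vector of F values (NA where undefined).
#' @export
individual_fis <- function(x) {
  p <- allele_freqs(x)
  n_allele <- 2 * colSums(!is.na(x$geno))
  keep <- !is.na(p) & n_allele >= 2
  g <- x$geno[, keep, drop = FALSE]
  p <- p[keep]
  n_allele <- n_allele[keep]
  if (ncol(g) < 1L) stop("need >= 1 usable locus")
  corr <- ifelse(n_allele > 1, n_allele / (n_allele - 1), NA_real_)
  ehom_locus <- 1 - 2 * p * (1 - p) * corr
  m <- !is.na(g)
  O <- rowSums(m & g != 1L)
  E <- as.vector(m %*% ehom_locus)
  L <- rowSums(m)
  f <- (O - E) / (L - E)
  f[L == E] <- NA_real_
  stats::setNames(f, rownames(g))
}
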