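#' Diversity subset: one individual per colony plus transect samples
#'
#' Builds the sample subset over which regional expected heterozygosity is
#' computed: the least-missing genotyped individual of every colony, plus
#' all transect samples. Computing diversity on one worker per colony
#' avoids the family pseudo-replication a full-colony sample would cause.
#'
#' @param x a `genotype_table`.
#' @param metadata sample metadata with `colony` and `origin`.
#' @return character vector of sample ids.
#' @export
diversity_subset <- function(x, metadata) {
  metadata <- metadata[metadata$sample %in% sample_ids(x), , drop = FALSE]
  miss <- rowMeans(is.na(x$geno))
  picks <- character(0)
  cmeta <- metadata[metadata$origin == "colony", , drop = FALSE]
  for (co in unique(cmeta$colony)) {
    ids <- cmeta$sample[cmeta$colony == co]
    picks <- c(picks, ids[which.min(miss[ids])])
  }
  c(picks, metadata$sample[metadata$origin != "colony"])
}

#' Regional expected heterozygosity
#'
#' Mean nucleotide diversity per variable site within each region:
#' `pi_i = 2 p q n_i / (n_i - 1)` with `n_i` the non-missing allele count,
#' averaged over the sites variable within the region's subset. Compute on
#' the table with the supergene chromosome excluded and on the subset from
#' [diversity_subset()].
#'
#' @param x a `genotype_table`.
#' @param metadata sample metadata (region assignment).
#' @param subset sample ids to use (default [diversity_subset()]).
#' @return data.frame: region, n_samples, n_variable_sites, exp_het
#'   (0 with a message when a region has no variable sites); regions with
#'   fewer than 2 samples are flagged `low_confidence`.
#' @export
expected_heterozygosity <- function(x, metadata,
                                    subset = diversity_subset(x, metadata)) {
  metadata <- metadata[match(subset, metadata$sample), , drop = FALSE]
  rows <- lapply(unique(metadata$region), function(rg) {
    ids <- metadata$sample[metadata$region == rg]
    g <- x$geno[ids, , drop = FALSE]
    n_allele <- 2 * colSums(!is.na(g))
    p <- colMeans(g, na.rm = TRUE) / 2
    variable <- !is.na(p) & p > 0 & p < 1 & n_allele >= 2
    pi_site <- 2 * p[variable] * (1 - p[variable]) *
      n_allele[variable] / (n_allele[variable] - 1)
    if (!any(variable)) {
      message("region ", rg, " has no variable sites; exp_het = 0")
    }
    data.frame(region = rg, n_samples = length(ids),
               n_variable_sites = sum(variable),
               exp_het = if (any(variable)) mean(pi_site) else 0,
               low_confidence = length(ids) < 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Per-locus Weir-Cockerham (1984) variance components for two groups.
## Returns vectors a, b, c over usable loci.
wc_components <- function(gA, gB) {
  nA <- colSums(!is.na(gA)); nB <- colSums(!is.na(gB))
  pA <- colMeans(gA, na.rm = TRUE) / 2
  pB <- colMeans(gB, na.rm = TRUE) / 2
  hA <- colMeans(gA == 1L, na.rm = TRUE)
  hB <- colMeans(gB == 1L, na.rm = TRUE)
  use <- nA >= 1 & nB >= 1
  pbar_all <- (nA * pA + nB * pB) / (nA + nB)
  use <- use & !is.na(pbar_all) & pbar_all > 0 & pbar_all < 1
  nA <- nA[use]; nB <- nB[use]; pA <- pA[use]; pB <- pB[use]
  hA <- hA[use]; hB <- hB[use]
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (nA + nB - (nA^2 + nB^2) / (nA + nB)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  ok <- is.finite(a) & is.finite(b) & is.finite(cc)
  list(a = a[ok], b = b[ok], c = cc[ok])
}

#' Weir-Cockerham FST between two groups of samples
#'
#' The 1984 variance-components estimator for two populations with the
#' observed-heterozygosity correction, aggregated across loci as the
#' ratio of sums `sum(a) / sum(a + b + c)` (the weighted multi-locus
#' convention). Only loci polymorphic across the union of the two groups
#' contribute; loci with an undefined denominator are skipped. The value
#' is not clipped: slightly negative estimates for undifferentiated
#' groups are reported as such.
#'
#' @param x a `genotype_table`.
#' @param samples_a,samples_b disjoint character vectors of sample ids
#'   (each >= 2 samples).
#' @return scalar FST estimate (`NA` if no usable loci).
#' @export
weir_cockerham_fst <- function(x, samples_a, samples_b) {
  if (length(intersect(samples_a, samples_b)) > 0) {
    stop("sample groups overlap")
  }
  stopifnot(length(samples_a) >= 2, length(samples_b) >= 2)
  gA <- x$geno[samples_a, , drop = FALSE]
  gB <- x$geno[samples_b, , drop = FALSE]
  comp <- wc_components(gA, gB)
  denom <- sum(comp$a + comp$b + comp$c)
  if (!length(comp$a) || denom == 0) return(NA_real_)
  sum(comp$a) / denom
}

#' Great-circle distance in meters
#'
#' Haversine distance on a sphere of radius 6,371,000 m. At the scale of
#' meters to a few thousand kilometers the sphere-vs-ellipsoid error is
#' sub-percent and irrelevant to isolation-by-distance regression.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return distance(s) in meters.
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("invalid coordinates")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000)
}

#' Rousset's genetic distance
#'
#' `FST / (1 - FST)`, linear in geographic distance under two-dimensional
#' isolation by distance. Strictly increasing on `[0, 1)`; continuous for
#' the slightly negative estimates an undifferentiated pair can produce.
#'
#' @param fst FST value(s) < 1.
#' @return transformed value(s).
#' @export
rousset_distance <- function(fst) {
  if (any(fst >= 1, na.rm = TRUE)) stop("Rousset transform needs FST < 1")
  fst / (1 - fst)
}

#' Pairwise colony FST and geographic distance matrices
#'
#' Computes the Weir-Cockerham FST between every pair of colonies with at
#' least `min_workers` genotyped workers, and the haversine distance
#' between colony coordinates.
#'
#' @param x a `genotype_table` (supergene chromosome excluded upstream).
#' @param metadata sample metadata.
#' @param min_workers minimum genotyped workers per colony (default 6).
#' @return list with symmetric matrices `fst` and `meters` (colony ids as
#'   dimnames) and the data.frame `colonies` used.
#' @export
colony_pairwise <- function(x, metadata, min_workers = 6) {
  md <- metadata[metadata$origin == "colony" &
                   metadata$sample %in% sample_ids(x), , drop = FALSE]
  counts <- table(md$colony)
  keep <- names(counts)[counts >= min_workers]
  if (length(keep) < 2L) stop("fewer than 2 colonies pass min_workers")
  info <- md[!duplicated(md$colony) & md$colony %in% keep, ,
             drop = FALSE]
  info <- info[order(info$colony), ]
  n <- nrow(info)
  fst <- matrix(0, n, n, dimnames = list(info$colony, info$colony))
  meters <- fst
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ids_i <- md$sample[md$colony == info$colony[i]]
      ids_j <- md$sample[md$colony == info$colony[j]]
      fst[i, j] <- fst[j, i] <- weir_cockerham_fst(x, ids_i, ids_j)
      meters[i, j] <- meters[j, i] <- great_circle_distance(
        info$lat[i], info$lon[i], info$lat[j], info$lon[j])
    }
  }
  list(fst = fst, meters = meters, colonies = info)
}

#' Isolation-by-distance regression with Mantel permutation
#'
#' Ordinary least squares of Rousset's distance `FST / (1 - FST)` on
#' linear geographic distance in meters across colony pairs, with
#' significance from a Mantel permutation: colony labels of the genetic
#' matrix are permuted jointly (preserving the dependence among pairs
#' sharing a colony) and the one-sided p-value for a positive association
#' is `(1 + #{r_perm >= r_obs}) / (n_permutations + 1)`.
#'
#' @param fst symmetric colony FST matrix; pairs with FST = 1 are dropped
#'   with a warning (transform undefined).
#' @param meters symmetric colony distance matrix (same order).
#' @param n_permutations Mantel permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @return list: slope, intercept, r_squared, p_mantel, n_pairs, and the
#'   pair table (`pairs`).
#' @export
ibd_regression <- function(fst, meters, n_permutations = 9999, seed = 1L) {
  stopifnot(all(dim(fst) == dim(meters)), nrow(fst) >= 3)
  if (any(fst[upper.tri(fst)] >= 1, na.rm = TRUE)) {
    warning("dropping pair(s) with FST = 1: Rousset transform undefined")
    fst[fst >= 1] <- NA_real_
  }
  lt <- lower.tri(fst)
  gd <- rousset_distance(fst[lt])
  dd <- meters[lt]
  ok <- !is.na(gd) & !is.na(dd)
  if (sum(ok) < 3L) stop("need >= 3 usable colony pairs")
  slope <- stats::cov(dd[ok], gd[ok]) / stats::var(dd[ok])
  intercept <- mean(gd[ok]) - slope * mean(dd[ok])
  r_obs <- suppressWarnings(stats::cor(gd[ok], dd[ok]))
  set.seed(seed)
  n <- nrow(fst)
  r_perm <- replicate(n_permutations, {
    perm <- sample.int(n)
    gp <- rousset_distance(fst[perm, perm][lt])
    suppressWarnings(stats::cor(gp, dd, use = "complete.obs"))
  })
  p <- (1 + sum(r_perm >= r_obs, na.rm = TRUE)) / (n_permutations + 1)
  pairs <- data.frame(
    colony_a = rownames(fst)[row(fst)[lt]][ok],
    colony_b = colnames(fst)[col(fst)[lt]][ok],
    fst = fst[lt][ok], rousset = gd[ok], meters = dd[ok],
    stringsAsFactors = FALSE)
  list(slope = slope, intercept = intercept,
       r_squared = r_obs^2,
       p_mantel = p, n_pairs = sum(ok), pairs = pairs)
}
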