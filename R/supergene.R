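#' PCA of the supergene window
#'
#' Variance-standardized genotype PCA of the chromosome-3 window loci:
#' missing dosages are mean-imputed per locus (PCA only — downstream
#' heterozygosity statistics use the raw calls), columns are centered by
#' `2 p-hat` and scaled by `sqrt(2 p-hat (1 - p-hat))`, and the sample x
#' sample covariance is eigendecomposed. Each component is oriented so
#' that its largest-magnitude locus loading is positive, making the sign
#' convention deterministic. With two divergent haplotypes segregating in
#' the window, PC1 separates the three diploid genotype classes into three
#' collinear clusters with heterozygotes at the midpoint.
#'
#' @param x `genotype_table` of window loci (>= 2 loci, >= 3 samples).
#' @param n_components number of components to return (default 3).
#' @return list of class `window_pca`: `scores` (samples x components),
#'   `loadings` (loci x components), `eigenvalue_share`, `loci`.
#' @export
window_pca <- function(x, n_components = 3) {
  g <- x$geno
  if (ncol(g) < 2L) stop("need >= 2 loci in the window")
  if (nrow(g) < 3L) stop("need >= 3 samples")
  p <- allele_freqs(x)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("window is monomorphic")
  g <- g[, poly, drop = FALSE]
  loci <- x$loci[poly, , drop = FALSE]
  p <- p[poly]
  X <- g
  for (i in seq_len(ncol(X))) {
    xi <- X[, i]
    xi[is.na(xi)] <- 2 * p[i]
    X[, i] <- xi
  }
  Z <- sweep(X, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  C <- tcrossprod(Z) / ncol(Z)
  e <- eigen(C, symmetric = TRUE)
  k <- min(n_components, nrow(g) - 1L, ncol(Z))
  vals <- pmax(e$values, 0)
  share <- vals[seq_len(k)] / sum(vals)
  scores <- e$vectors[, seq_len(k), drop = FALSE]
  loadings <- crossprod(Z, scores) # loci x k
  for (j in seq_len(k)) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(g)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  rownames(loadings) <- paste(loci$chrom, loci$pos, sep = ":")
  structure(list(scores = scores, loadings = loadings,
                 eigenvalue_share = share, loci = loci),
            class = "window_pca")
}

#' Three-way clustering along PC1
#'
#' Deterministic one-dimensional 3-means on the PC1 coordinates,
#' initialized at the minimum, median and maximum; labels are reordered by
#' cluster center so label 1 is the lowest-PC1 cluster. Three clusters are
#' imposed because a bi-allelic supergene admits exactly three diploid
#' genotype classes.
#'
#' @param pc1 numeric vector of PC1 coordinates.
#' @return integer vector of cluster labels in 1..3 (ordered by center).
#' @export
cluster_pc1 <- function(pc1) {
  if (length(unique(pc1)) < 3L) {
    stop("fewer than 3 distinct PC1 values: degenerate clustering")
  }
  centers <- matrix(c(min(pc1), stats::median(pc1), max(pc1)))
  if (any(duplicated(centers))) {
    centers <- matrix(stats::quantile(unique(pc1), c(0, 0.5, 1),
                                      names = FALSE))
  }
  km <- stats::kmeans(matrix(pc1), centers = centers,
                      algorithm = "Lloyd", iter.max = 200)
  ord <- order(km$centers)
  match(km$cluster, ord)
}

#' Fraction of reference-homozygous calls per sample
#'
#' Over non-missing window loci, the fraction at which the sample is
#' homozygous for the REF allele (dosage 0). Used to orient the two
#' homozygote clusters: the reference assembly carries the
#' monogyne-associated (M) haplotype, so the MM cluster aligns to REF.
#'
#' @param x `genotype_table` of window loci.
#' @return named numeric vector in `[0, 1]`.
#' @export
ref_hom_fraction <- function(x) {
  g <- x$geno
  stats::setNames(rowSums(!is.na(g) & g == 0L) / rowSums(!is.na(g)),
                  rownames(g))
}

#' Assign supergene genotype classes to clustered samples
#'
#' Labels the three PC1 clusters as MM / MP / PP: the cluster with the
#' lowest mean window F (heterozygosity excess, negative on clean data) is
#' the heterozygote MP; of the remaining two, the cluster with the higher
#' mean reference-homozygosity fraction is MM (REF aligns with the M
#' haplotype), the other PP. Per-sample conflicts with the cluster-level
#' call (a sample in the MP cluster with positive F, or a homozygote
#' cluster sample with negative F) are flagged, never overwritten.
#'
#' @param clusters integer labels from [cluster_pc1()].
#' @param window_fis per-sample window F from [individual_fis()].
#' @param ref_hom per-sample fraction from [ref_hom_fraction()].
#' @param scores optional PC score matrix carried into the output.
#' @return data.frame of class `supergene_calls`: sample, PC coordinates
#'   (when given), window_fis, ref_hom_fraction, cluster, class, flag.
#' @export
assign_supergene_genotypes <- function(clusters, window_fis, ref_hom,
                                       scores = NULL) {
  stopifnot(length(clusters) == length(window_fis),
            length(clusters) == length(ref_hom))
  if (length(unique(clusters)) != 3L) stop("need exactly 3 clusters")
  mean_fis <- tapply(window_fis, clusters, mean, na.rm = TRUE)
  het_cl <- as.integer(names(which.min(mean_fis)))
  hom_cl <- setdiff(sort(unique(clusters)), het_cl)
  mean_ref <- tapply(ref_hom, clusters, mean, na.rm = TRUE)
  rh <- mean_ref[as.character(hom_cl)]
  if (diff(range(rh)) < .Machine$double.eps^0.5 &&
      abs(diff(mean_fis[as.character(hom_cl)])) < .Machine$double.eps^0.5) {
    stop("homozygote clusters tie on both orientation criteria; ",
         "manual review required")
  }
  mm_cl <- hom_cl[which.max(rh)]
  pp_cl <- setdiff(hom_cl, mm_cl)
  class_map <- stats::setNames(c("MP", "MM", "PP"),
                               c(het_cl, mm_cl, pp_cl))
  cls <- unname(class_map[as.character(clusters)])
  flag <- rep("", length(clusters))
  flag[cls == "MP" & !is.na(window_fis) & window_fis > 0] <-
    "positive_fis_in_het_cluster"
  flag[cls != "MP" & !is.na(window_fis) & window_fis < 0] <-
    "negative_fis_in_hom_cluster"
  out <- data.frame(sample = names(window_fis),
                    window_fis = unname(window_fis),
                    ref_hom_fraction = unname(ref_hom),
                    cluster = clusters, class = cls, flag = flag,
                    stringsAsFactors = FALSE)
  if (!is.null(scores)) out <- cbind(out, as.data.frame(scores))
  class(out) <- c("supergene_calls", class(out))
  out
}

#' Full supergene genotyping of the window table
#'
#' Convenience wrapper: [window_pca()] then [cluster_pc1()] on PC1, window
#' F via [individual_fis()] on the raw window calls, orientation via
#' [ref_hom_fraction()], and [assign_supergene_genotypes()].
#'
#' @param x `genotype_table` of window loci (the `inside` part of
#'   [split_supergene_window()]).
#' @param n_components components to report (default 3).
#' @return a `supergene_calls` data.frame; the `window_pca` object is
#'   attached as attribute `pca`.
#' @export
supergene_calls <- function(x, n_components = 3) {
  pca <- window_pca(x, n_components)
  clusters <- cluster_pc1(pca$scores[, 1])
  fis <- individual_fis(x)
  rh <- ref_hom_fraction(x)
  out <- assign_supergene_genotypes(clusters, fis, rh, scores = pca$scores)
  attr(out, "pca") <- pca
  out
}

#' Per-colony supergene genotype composition
#'
#' Counts MM / MP / PP workers per colony and the P-haplotype frequency
#' `(2 PP + MP) / (2 n)`, ordered by region and then P frequency. Colonies
#' with undetermined social form are split out into a separate table
#' rather than silently mixed into the main composition.
#'
#' @param calls a `supergene_calls` data.frame.
#' @param metadata sample metadata (sample, colony, region, origin).
#' @param social_forms optional data.frame (colony, social_form), e.g. a
#'   [colony_report()]; colonies with form `"undetermined"` are split out.
#' @return list of data.frames `main` and `undetermined`, each with
#'   colony, region, social_form, n, MM, MP, PP, p_freq.
#' @export
colony_composition <- function(calls, metadata, social_forms = NULL) {
  md <- metadata[metadata$origin == "colony", , drop = FALSE]
  df <- merge(calls[, c("sample", "class")], md, by = "sample")
  colonies <- unique(df$colony)
  rows <- lapply(colonies, function(co) {
    d <- df[df$colony == co, ]
    n <- nrow(d)
    counts <- table(factor(d$class, levels = c("MM", "MP", "PP")))
    form <- if (!is.null(social_forms)) {
      f <- social_forms$social_form[match(co, social_forms$colony)]
      if (length(f) == 0 || is.na(f)) NA_character_ else f
    } else NA_character_
    data.frame(colony = co, region = d$region[1], social_form = form,
               n = n, MM = as.integer(counts["MM"]),
               MP = as.integer(counts["MP"]),
               PP = as.integer(counts["PP"]),
               p_freq = (2 * counts[["PP"]] + counts[["MP"]]) / (2 * n),
               stringsAsFactors = FALSE)
  })
  comp <- do.call(rbind, rows)
  comp <- comp[order(comp$region, comp$p_freq), , drop = FALSE]
  rownames(comp) <- NULL
  undet <- !is.na(comp$social_form) & comp$social_form == "undetermined"
  list(main = comp[!undet, , drop = FALSE],
       undetermined = comp[undet, , drop = FALSE])
}
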