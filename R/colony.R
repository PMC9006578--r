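#' Opposing homozygosity of a colony
#'
#' Counts the bi-allelic loci at which both homozygote classes occur among
#' a colony's workers: at least one worker homozygous REF (dosage 0) and at
#' least one homozygous ALT (dosage 2), missing calls ignored. Workers of a
#' single singly-mated diploid queen and one haploid father can never show
#' both homozygote classes at one locus, so for an error-free monogyne
#' colony the count is exactly 0; multiple unrelated queens push it up.
#'
#' @param geno worker x locus dosage matrix (or a `genotype_table`).
#' @return integer count of opposing-homozygous loci.
#' @export
opposing_homozygosity <- function(geno) {
  if (inherits(geno, "genotype_table")) geno <- geno$geno
  if (nrow(geno) < 2L) stop("opposing homozygosity needs >= 2 workers")
  has0 <- colSums(!is.na(geno) & geno == 0L) > 0
  has2 <- colSums(!is.na(geno) & geno == 2L) > 0
  sum(has0 & has2)
}

#' Partition a colony's workers into matrilines
#'
#' Stand-in for full-likelihood sibship reconstruction: single-linkage
#' clustering of workers on pairwise relatedness, merging clusters while
#' the maximum between-cluster relatedness is at least `threshold`. This
#' is equivalent to taking connected components of the graph whose edges
#' join pairs whose relatedness is at least `threshold`. The default 0.375 is the
#' midpoint between haplodiploid full sisters (r = 0.75) and
#' cross-matriline pairs of unrelated queens (r = 0). When allele
#' frequencies are pooled across diverged regions, cross-matriline pairs
#' are inflated well above 0 (roughly `2 F_ST / (1 + F_ST)`), so the
#' colony-level pipeline uses 0.5 — the midpoint under the default
#' regional divergence. Undefined pairwise estimates are treated as below
#' threshold and counted in the `n_undefined_pairs` attribute.
#'
#' @param r square pairwise relatedness matrix for one colony's workers
#'   (or a `pairwise_matrix`).
#' @param threshold merge threshold in (0, 1).
#' @return list with `count` (inferred matrilines) and `labels` (integer
#'   cluster per worker, ordered by first appearance).
#' @export
matriline_partition <- function(r, threshold = 0.375) {
  if (inherits(r, "pairwise_matrix")) r <- r$estimate
  stopifnot(is.matrix(r), nrow(r) == ncol(r),
            threshold > 0, threshold < 1)
  n <- nrow(r)
  und <- sum(is.na(r[upper.tri(r)]))
  adj <- !is.na(r) & r >= threshold
  diag(adj) <- TRUE
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    cl <- cl + 1L
    frontier <- i
    labels[i] <- cl
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) &
                    is.na(labels))
      labels[nb] <- cl
      frontier <- nb
    }
  }
  out <- list(count = cl, labels = labels)
  attr(out, "n_undefined_pairs") <- und
  out
}

#' Consensus social-form vote
#'
#' Combines three colony-level signals into a monogyne / polygyne /
#' undetermined call by unanimous vote:
#' * opposing homozygosity as a fraction of loci: monogyne if
#'   `<= oh_mono_max`, polygyne if `>= oh_poly_min`;
#' * mean within-colony relatedness: monogyne if `>= r_mono_min`,
#'   polygyne if `<= r_poly_max`;
#' * inferred matriline count: monogyne if 1, polygyne if >= 2.
#' Any conflicting votes, or any vote falling in the inner band between
#' the monogyne and polygyne cutoffs, yield `undetermined` — ambiguous
#' colonies (a polyandrous queen, or a few related queens) are surfaced,
#' never forced into a class.
#'
#' The default cutoffs are simulator-calibrated under the default study
#' conditions and fully configurable. `oh_mono_max` = 4% of loci: with 2%
#' allelic dropout a monogyne colony of 8 workers accrues false opposing
#' homozygosity at roughly 1-2% of loci, so the cutoff sits ~3 binomial
#' standard deviations above that mean. `oh_poly_min` = 8% of loci.
#' `r_mono_min` = 0.68 and `r_poly_max` = 0.62 on the moments estimator:
#' haplodiploid full sisters sit near 0.75 and multi-queen colonies below
#' ~0.55, both shifted upward when allele frequencies are pooled across
#' diverged regions (unrelated same-region pairs then average roughly
#' `2 F_ST / (1 + F_ST)`, ~0.26 at regional F_ST 0.15), which the band
#' accommodates.
#'
#' @param oh_frac opposing homozygosity / number of loci.
#' @param mean_r mean pairwise relatedness among the colony's workers.
#' @param matrilines inferred matriline count.
#' @param thresholds named list overriding any of `oh_mono_max`,
#'   `oh_poly_min`, `r_mono_min`, `r_poly_max`.
#' @return list with `form` and the three `votes`.
#' @export
classify_social_form <- function(oh_frac, mean_r, matrilines,
                                 thresholds = list()) {
  th <- utils::modifyList(list(oh_mono_max = 0.04, oh_poly_min = 0.08,
                               r_mono_min = 0.68, r_poly_max = 0.62),
                          thresholds)
  vote_oh <- if (is.na(oh_frac)) "band"
    else if (oh_frac <= th$oh_mono_max) "monogyne"
    else if (oh_frac >= th$oh_poly_min) "polygyne" else "band"
  vote_r <- if (is.na(mean_r)) "band"
    else if (mean_r >= th$r_mono_min) "monogyne"
    else if (mean_r <= th$r_poly_max) "polygyne" else "band"
  vote_m <- if (is.na(matrilines)) "band"
    else if (matrilines == 1L) "monogyne" else "polygyne"
  votes <- c(oh = vote_oh, relatedness = vote_r, matrilines = vote_m)
  form <- if (all(votes == "monogyne")) "monogyne"
    else if (all(votes == "polygyne")) "polygyne" else "undetermined"
  list(form = form, votes = votes)
}

#' Per-colony report: opposing homozygosity, relatedness, social form
#'
#' Runs the whole colony-level analysis on a genotype table of
#' non-supergene-chromosome loci: pairwise relatedness with every
#' estimator (allele frequencies from the full table, including transect
#' samples), opposing homozygosity, matriline partition, and the consensus
#' social-form vote. Colonies with fewer than `min_workers` genotyped
#' workers are reported but not classified. The input must come from
#' [split_supergene_window()]'s `outside` part; this is asserted so
#' supergene-linked loci can never influence social-form inference.
#'
#' @param x `genotype_table` with `window_role == "outside"`.
#' @param metadata sample metadata (colony assignment; transect samples,
#'   `origin != "colony"`, contribute to allele frequencies only).
#' @param min_workers minimum genotyped workers per colony (default 6).
#' @param matriline_threshold see [matriline_partition()]; the default
#'   0.5 accounts for structure-inflated cross-matriline relatedness.
#' @param thresholds see [classify_social_form()].
#' @param voting_estimator which relatedness estimator feeds the vote
#'   (default `"moments"`).
#' @return data.frame of class `colony_report`, one row per colony, with
#'   columns colony, region, n_workers, oh_count, oh_frac, mean relatedness
#'   per estimator, matrilines, the three votes, social_form and
#'   excluded_reason.
#' @export
colony_report <- function(x, metadata, min_workers = 6,
                          matriline_threshold = 0.5,
                          thresholds = list(),
                          voting_estimator = "moments") {
  role <- attr(x, "window_role")
  if (is.null(role) || role != "outside") {
    stop("colony_report requires the 'outside' table from ",
         "split_supergene_window() (window_role attribute)")
  }
  metadata <- metadata[metadata$sample %in% sample_ids(x), , drop = FALSE]
  r_moments <- moments_relatedness(x)$estimate
  r_ajk <- ajk(x)$estimate
  r_king <- king_phi(x)$estimate
  r_pihat <- pi_hat(x)$estimate
  voting <- switch(voting_estimator,
                   moments = r_moments, ajk = r_ajk,
                   king_phi = r_king, pi_hat = r_pihat,
                   stop("unknown voting estimator"))
  cmeta <- metadata[metadata$origin == "colony", , drop = FALSE]
  colonies <- unique(cmeta$colony)
  rows <- lapply(colonies, function(co) {
    ids <- cmeta$sample[cmeta$colony == co]
    region <- cmeta$region[match(co, cmeta$colony)]
    nw <- length(ids)
    base <- data.frame(colony = co, region = region, n_workers = nw,
                       oh_count = NA_integer_, oh_frac = NA_real_,
                       mean_r_moments = NA_real_, mean_r_ajk = NA_real_,
                       mean_phi_king = NA_real_, mean_pi_hat = NA_real_,
                       matrilines = NA_integer_,
                       vote_oh = NA_character_, vote_r = NA_character_,
                       vote_matrilines = NA_character_,
                       social_form = NA_character_,
                       excluded_reason = NA_character_,
                       stringsAsFactors = FALSE)
    if (nw < min_workers) {
      base$excluded_reason <- sprintf("fewer than %d workers", min_workers)
      return(base)
    }
    g <- x$geno[ids, , drop = FALSE]
    base$oh_count <- opposing_homozygosity(g)
    base$oh_frac <- base$oh_count / ncol(g)
    off <- function(mat) {
      m <- mat[ids, ids, drop = FALSE]
      mean(m[upper.tri(m)], na.rm = TRUE)
    }
    base$mean_r_moments <- off(r_moments)
    base$mean_r_ajk <- off(r_ajk)
    base$mean_phi_king <- off(r_king)
    base$mean_pi_hat <- off(r_pihat)
    part <- matriline_partition(voting[ids, ids, drop = FALSE],
                                matriline_threshold)
    base$matrilines <- part$count
    cls <- classify_social_form(base$oh_frac,
                                off(voting),
                                part$count, thresholds)
    base$vote_oh <- cls$votes[["oh"]]
    base$vote_r <- cls$votes[["relatedness"]]
    base$vote_matrilines <- cls$votes[["matrilines"]]
    base$social_form <- cls$form
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("colony_report", class(out))
  out
}
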