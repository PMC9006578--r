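#' Simulation configuration for haplodiploid colony sampling designs
#'
#' Builds and validates the parameter set for [simulate_population()]. The
#' defaults emulate a range-wide worker-sampling design for a socially
#' polymorphic ant: five regions spanning a large latitudinal gradient,
#' around thirty colonies of eight workers each plus a handful of transect
#' singletons per region, ~300 unlinked background SNPs off chromosome 3 and
#' 26 SNPs inside a non-recombining supergene window on chromosome 3
#' (2-12.5 Mbp) carrying two divergent haplotypes, M (monogyne-associated,
#' REF-aligned) and P (polygyne-associated).
#'
#' Colony classes: `monogyne` (one singly mated queen), `polyandrous` (one
#' queen, several mates), `oligogynous` (two full-sister queens), and
#' `polygynous` (several unrelated queens). Queens are diploid, mates are
#' haploid, and workers receive one Mendelian maternal allele plus the
#' paternal allele at every locus; supergene loci segregate as a single
#' non-recombining block.
#'
#' @param n_regions number of sampling regions.
#' @param region_coords matrix or data.frame of (lat, lon) per region.
#' @param colonies_per_region colonies sampled per region.
#' @param workers_per_colony workers sampled per colony.
#' @param n_transect_per_region unrelated transect singletons per region.
#' @param n_background_loci SNP count off chromosome 3.
#' @param n_supergene_loci SNP count inside the supergene window.
#' @param supergene_window list(chrom, start, end), 1-based inclusive.
#' @param background_chroms chromosome labels for background loci.
#' @param fst_regions Balding-Nichols divergence parameter in `[0, 1)` for
#'   regional allele frequencies.
#' @param social_mix named proportions over the four colony classes
#'   (must sum to 1).
#' @param n_queens_polygyne integer vector of possible queen counts for
#'   polygynous colonies (sampled uniformly).
#' @param n_mates_polyandrous integer vector of possible mate counts for
#'   polyandrous queens (sampled uniformly).
#' @param p_queen_genotype_by_form list mapping colony class to a named
#'   probability vector over queen supergene genotypes `c(MM=, MP=, PP=)`.
#' @param p_mate_P_by_form named vector: probability a mate carries the P
#'   haplotype, per colony class.
#' @param p_transect_P probability a transect individual's supergene
#'   haplotype copy is P.
#' @param haplotype_divergence fraction of supergene loci fixed-different
#'   between the M and P haplotypes.
#' @param ancestral_freq_range range for ancestral ALT frequencies.
#' @param dropout_rate probability a heterozygous call is miscalled as a
#'   random homozygote (allelic dropout).
#' @param missing_rate per-genotype missingness probability.
#' @param depth_mean optional mean of simulated Poisson read depths
#'   (`NULL` = no depths).
#' @param coord_jitter_sd s.d. (degrees) of colony coordinate jitter
#'   around the region coordinate.
#' @param freq_clamp clamp for region allele frequencies away from 0/1.
#' @param seed integer seed; the master stream also derives one documented
#'   substream seed per colony so truth tables are reproducible.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 5,
                       region_coords = NULL,
                       colonies_per_region = 6,
                       workers_per_colony = 8,
                       n_transect_per_region = 5,
                       n_background_loci = 300,
                       n_supergene_loci = 26,
                       supergene_window = list(chrom = "chr3",
                                               start = 2e6, end = 12.5e6),
                       background_chroms = c("chr1", "chr2", "chr4", "chr5"),
                       fst_regions = 0.15,
                       social_mix = c(monogyne = 0.45, polyandrous = 0.05,
                                      oligogynous = 0.05, polygynous = 0.45),
                       n_queens_polygyne = 2:4,
                       n_mates_polyandrous = 2:4,
                       p_queen_genotype_by_form = list(
                         monogyne = c(MM = 1, MP = 0, PP = 0),
                         polyandrous = c(MM = 1, MP = 0, PP = 0),
                         oligogynous = c(MM = 0.5, MP = 0.5, PP = 0),
                         polygynous = c(MM = 0.3, MP = 0.4, PP = 0.3)),
                       p_mate_P_by_form = c(monogyne = 0, polyandrous = 0.25,
                                            oligogynous = 0.25,
                                            polygynous = 0.5),
                       p_transect_P = 0.3,
                       haplotype_divergence = 0.8,
                       ancestral_freq_range = c(0.1, 0.9),
                       dropout_rate = 0.02,
                       missing_rate = 0.05,
                       depth_mean = NULL,
                       coord_jitter_sd = 0.2,
                       freq_clamp = 1e-6,
                       seed = 1L) {
  if (is.null(region_coords)) {
    default_coords <- cbind(lat = c(39.3, 44.2, 50.7, 51.1, 58.8),
                            lon = c(-120.6, -114.9, -121.9, -115.2, -124.2))
    region_coords <- default_coords[rep_len(seq_len(5), n_regions), ,
                                    drop = FALSE]
    if (n_regions > 5) {
      region_coords[, "lat"] <- region_coords[, "lat"] +
        seq(0, 2, length.out = n_regions)
    }
  }
  region_coords <- as.matrix(region_coords)
  colnames(region_coords) <- c("lat", "lon")
  cfg <- list(n_regions = as.integer(n_regions),
              region_coords = region_coords,
              colonies_per_region = as.integer(colonies_per_region),
              workers_per_colony = as.integer(workers_per_colony),
              n_transect_per_region = as.integer(n_transect_per_region),
              n_background_loci = as.integer(n_background_loci),
              n_supergene_loci = as.integer(n_supergene_loci),
              supergene_window = supergene_window,
              background_chroms = background_chroms,
              fst_regions = fst_regions,
              social_mix = social_mix,
              n_queens_polygyne = n_queens_polygyne,
              n_mates_polyandrous = n_mates_polyandrous,
              p_queen_genotype_by_form = p_queen_genotype_by_form,
              p_mate_P_by_form = p_mate_P_by_form,
              p_transect_P = p_transect_P,
              haplotype_divergence = haplotype_divergence,
              ancestral_freq_range = ancestral_freq_range,
              dropout_rate = dropout_rate,
              missing_rate = missing_rate,
              depth_mean = depth_mean,
              coord_jitter_sd = coord_jitter_sd,
              freq_clamp = freq_clamp,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

colony_classes <- c("monogyne", "polyandrous", "oligogynous", "polygynous")

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_regions >= 1, cfg$colonies_per_region >= 0,
            cfg$workers_per_colony >= 1)
  if (nrow(cfg$region_coords) != cfg$n_regions) {
    stop("region_coords must have one row per region")
  }
  if (abs(sum(cfg$social_mix) - 1) > 1e-8) {
    stop("social_mix proportions must sum to 1")
  }
  if (!all(colony_classes %in% names(cfg$social_mix))) {
    stop("social_mix must name all four colony classes")
  }
  if (cfg$fst_regions < 0 || cfg$fst_regions >= 1) {
    stop("fst_regions must be in [0, 1)")
  }
  rates <- c(cfg$dropout_rate, cfg$missing_rate, cfg$haplotype_divergence,
             cfg$p_transect_P, cfg$p_mate_P_by_form)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  w <- cfg$supergene_window
  if (!(w$start < w$end)) stop("supergene_window start must be < end")
  lat <- cfg$region_coords[, "lat"]; lon <- cfg$region_coords[, "lon"]
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("invalid region coordinates")
  }
  for (cl in colony_classes) {
    p <- cfg$p_queen_genotype_by_form[[cl]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-8) {
      stop("p_queen_genotype_by_form[['", cl, "']] must sum to 1")
    }
  }
  invisible(cfg)
}

#' Balding-Nichols regional allele frequencies
#'
#' Draws per-region allele frequencies around an ancestral frequency vector
#' under the Balding-Nichols model: with divergence `fst = F > 0`, the
#' frequency of each locus in each region is an independent
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` draw, which has mean `p` and variance
#' `F p (1-p)`. With `F = 0` the draw collapses to the ancestral frequency.
#'
#' @param ancestral_freqs vector of ancestral ALT frequencies in (0, 1).
#' @param fst divergence parameter in `[0, 1)`.
#' @param n_regions number of regions.
#' @param seed optional integer seed.
#' @param eps clamp keeping drawn frequencies inside `[eps, 1 - eps]`.
#' @return numeric matrix, `n_regions` rows x loci columns.
#' @export
draw_region_frequencies <- function(ancestral_freqs, fst, n_regions,
                                    seed = NULL, eps = 1e-6) {
  if (any(ancestral_freqs <= 0 | ancestral_freqs >= 1)) {
    stop("ancestral frequencies must lie strictly inside (0, 1)")
  }
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  L <- length(ancestral_freqs)
  if (fst == 0) {
    return(matrix(ancestral_freqs, nrow = n_regions, ncol = L, byrow = TRUE))
  }
  scale <- (1 - fst) / fst
  out <- matrix(NA_real_, n_regions, L)
  for (r in seq_len(n_regions)) {
    out[r, ] <- stats::rbeta(L, ancestral_freqs * scale,
                             (1 - ancestral_freqs) * scale)
  }
  pmin(pmax(out, eps), 1 - eps)
}

## One haploid genome: background alleles are independent Bernoulli draws
## from the region frequencies; the supergene block is a concrete sequence
## whose fixed-difference loci are set by the haplotype class (M carries the
## REF allele, P the ALT allele) and whose remaining window loci are drawn
## from the region frequencies.
draw_haplotype <- function(freqs_bg, freqs_sg, sg_fixed, sg_class) {
  bg <- stats::rbinom(length(freqs_bg), 1L, freqs_bg)
  sg <- stats::rbinom(length(freqs_sg), 1L, freqs_sg)
  sg[sg_fixed] <- if (sg_class == "P") 1L else 0L
  list(bg = bg, sg = sg, sg_class = sg_class)
}

queen_classes_from_genotype <- function(genotype) {
  switch(genotype,
         MM = c("M", "M"),
         MP = c("M", "P"),
         PP = c("P", "P"),
         stop("unknown supergene genotype ", genotype))
}

draw_queen <- function(genotype, freqs_bg, freqs_sg, sg_fixed) {
  cls <- queen_classes_from_genotype(genotype)
  h1 <- draw_haplotype(freqs_bg, freqs_sg, sg_fixed, cls[1])
  h2 <- draw_haplotype(freqs_bg, freqs_sg, sg_fixed, cls[2])
  list(h = list(h1, h2), genotype = genotype)
}

## Mendelian daughter of a diploid mother and haploid father. The supergene
## block is inherited whole: one coin decides which maternal copy is passed.
draw_daughter <- function(mother, father) {
  L_bg <- length(mother$h[[1]]$bg)
  pick_bg <- stats::rbinom(L_bg, 1L, 0.5)
  m_bg <- ifelse(pick_bg == 1L, mother$h[[2]]$bg, mother$h[[1]]$bg)
  pick_sg <- stats::rbinom(1L, 1L, 0.5) + 1L
  m_sg <- mother$h[[pick_sg]]$sg
  m_cls <- mother$h[[pick_sg]]$sg_class
  h1 <- list(bg = m_bg, sg = m_sg, sg_class = m_cls)
  list(h = list(h1, father), genotype = paste0(
    sort(c(m_cls, father$sg_class)), collapse = ""))
}

diploid_dosage <- function(ind) {
  c(ind$h[[1]]$bg + ind$h[[2]]$bg, ind$h[[1]]$sg + ind$h[[2]]$sg)
}

sg_genotype_of <- function(ind) {
  paste0(sort(c(ind$h[[1]]$sg_class, ind$h[[2]]$sg_class)), collapse = "")
}

#' Simulate one colony pedigree and its sampled workers
#'
#' Draws the queen(s) and mate(s) of a colony of the requested class from
#' the regional allele frequencies, then produces `n_workers` diploid
#' workers, each the Mendelian daughter of one queen and one of her mates.
#' Oligogynous colonies contain exactly two full-sister queens (daughters of
#' one simulated mother and one father); polygynous colonies contain
#' unrelated queens. Error processes (dropout, missingness) are applied at
#' the population level, not here.
#'
#' @param colony_class one of `monogyne`, `polyandrous`, `oligogynous`,
#'   `polygynous`.
#' @param freqs_bg regional ALT frequencies at background loci.
#' @param freqs_sg regional ALT frequencies at supergene-window loci.
#' @param sg_fixed logical: which window loci are fixed-different between
#'   the M and P haplotypes.
#' @param config a `sim_config` (class-conditional queen genotype and mate
#'   haplotype distributions are read from it).
#' @param seed integer substream seed for this colony.
#' @param n_workers number of workers to sample.
#' @return list with elements `geno_bg`, `geno_sg` (worker dosage matrices),
#'   `workers` (data.frame: matriline, patriline, true supergene genotype),
#'   `colony` (class, queen/mate counts, queen supergene genotypes) and
#'   `queens` (list with queen dosage vectors, for pedigree checks).
#' @export
simulate_colony <- function(colony_class, freqs_bg, freqs_sg, sg_fixed,
                            config, seed, n_workers = NULL) {
  if (!colony_class %in% colony_classes) {
    stop("unknown colony class: ", colony_class)
  }
  if (is.null(n_workers)) n_workers <- config$workers_per_colony
  stopifnot(n_workers >= 1)
  set.seed(seed)
  p_geno <- config$p_queen_genotype_by_form[[colony_class]]
  p_mate_P <- config$p_mate_P_by_form[[colony_class]]

  draw_queen_genotype <- function() {
    sample(names(p_geno), 1L, prob = p_geno)
  }
  draw_mate <- function() {
    cls <- if (stats::runif(1) < p_mate_P) "P" else "M"
    draw_haplotype(freqs_bg, freqs_sg, sg_fixed, cls)
  }

  if (colony_class == "monogyne") {
    queens <- list(draw_queen(draw_queen_genotype(), freqs_bg, freqs_sg,
                              sg_fixed))
    mates <- list(list(draw_mate()))
  } else if (colony_class == "polyandrous") {
    queens <- list(draw_queen(draw_queen_genotype(), freqs_bg, freqs_sg,
                              sg_fixed))
    n_mates <- if (length(config$n_mates_polyandrous) == 1L) {
      config$n_mates_polyandrous
    } else sample(config$n_mates_polyandrous, 1L)
    mates <- list(replicate(n_mates, draw_mate(), simplify = FALSE))
  } else if (colony_class == "oligogynous") {
    gm <- draw_queen(draw_queen_genotype(), freqs_bg, freqs_sg, sg_fixed)
    gf <- draw_mate()
    q1 <- draw_daughter(gm, gf)
    q2 <- draw_daughter(gm, gf)
    queens <- list(q1, q2)
    mates <- list(list(draw_mate()), list(draw_mate()))
  } else { # polygynous
    nq <- if (length(config$n_queens_polygyne) == 1L) {
      config$n_queens_polygyne
    } else sample(config$n_queens_polygyne, 1L)
    genos <- replicate(nq, draw_queen_genotype())
    queens <- lapply(genos, draw_queen, freqs_bg = freqs_bg,
                     freqs_sg = freqs_sg, sg_fixed = sg_fixed)
    mates <- replicate(nq, list(draw_mate()), simplify = FALSE)
  }

  nq <- length(queens)
  L_bg <- length(freqs_bg); L_sg <- length(freqs_sg)
  geno_bg <- matrix(NA_integer_, n_workers, L_bg)
  geno_sg <- matrix(NA_integer_, n_workers, L_sg)
  matriline <- integer(n_workers)
  patriline <- character(n_workers)
  sg_geno <- character(n_workers)
  for (w in seq_len(n_workers)) {
    q <- if (nq == 1L) 1L else sample.int(nq, 1L)
    m <- if (length(mates[[q]]) == 1L) 1L else sample.int(length(mates[[q]]), 1L)
    child <- draw_daughter(queens[[q]], mates[[q]][[m]])
    dos <- diploid_dosage(child)
    geno_bg[w, ] <- dos[seq_len(L_bg)]
    if (L_sg > 0) geno_sg[w, ] <- dos[L_bg + seq_len(L_sg)]
    matriline[w] <- q
    patriline[w] <- paste0(q, ".", m)
    sg_geno[w] <- child$genotype
  }
  list(
    geno_bg = geno_bg,
    geno_sg = geno_sg,
    workers = data.frame(matriline = matriline, patriline = patriline,
                         supergene_genotype = sg_geno,
                         stringsAsFactors = FALSE),
    colony = data.frame(
      class = colony_class,
      n_queens = nq,
      n_mates = sum(lengths(mates)),
      queen_genotypes = paste(vapply(queens, sg_genotype_of, ""),
                              collapse = ","),
      stringsAsFactors = FALSE),
    queens = lapply(queens, function(q) {
      list(dosage = diploid_dosage(q), genotype = sg_genotype_of(q))
    })
  )
}

#' Simulate a full multi-region population sample
#'
#' Assembles the whole sampling design: regional allele frequencies under
#' the Balding-Nichols model, colony pedigrees per region, transect
#' singletons, genotyping error (allelic dropout applied to heterozygotes,
#' then per-genotype missingness), jittered colony coordinates, and the
#' ground-truth tables used to validate downstream inference. Deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements:
#'   * `genotypes`: a [genotype_table()] (background loci first, then the
#'     chromosome-3 window loci);
#'   * `metadata`: data.frame (sample, colony, region, lat, lon, origin);
#'   * `truth`: list of `samples` (colony, matriline, patriline, true
#'     supergene genotype) and `colonies` (true class, queen/mate counts,
#'     queen supergene genotypes);
#'   * `region_freqs`: the drawn regional allele-frequency matrices.
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  L_bg <- config$n_background_loci
  L_sg <- config$n_supergene_loci
  w <- config$supergene_window

  ## locus map: background loci spread over non-window chromosomes,
  ## supergene loci uniform inside the window
  bg_chrom <- sort(rep_len(config$background_chroms, L_bg))
  bg_pos <- integer(L_bg)
  for (ch in unique(bg_chrom)) {
    k <- sum(bg_chrom == ch)
    bg_pos[bg_chrom == ch] <- sort(sample.int(2e7, k))
  }
  sg_span <- as.integer(w$end) - as.integer(w$start) + 1L
  sg_pos <- sort(sample.int(sg_span, L_sg)) + as.integer(w$start) - 1L
  loci <- data.frame(
    chrom = c(bg_chrom, rep(w$chrom, L_sg)),
    pos = c(bg_pos, sg_pos),
    ref = "A", alt = "T",
    stringsAsFactors = FALSE)

  rng <- config$ancestral_freq_range
  anc_bg <- stats::runif(L_bg, rng[1], rng[2])
  anc_sg <- stats::runif(L_sg, rng[1], rng[2])
  n_fixed <- round(config$haplotype_divergence * L_sg)
  sg_fixed <- rep(FALSE, L_sg)
  if (n_fixed > 0) sg_fixed[sample.int(L_sg, n_fixed)] <- TRUE

  freq_bg <- draw_region_frequencies(anc_bg, config$fst_regions,
                                     config$n_regions, eps = config$freq_clamp)
  freq_sg <- draw_region_frequencies(anc_sg, config$fst_regions,
                                     config$n_regions, eps = config$freq_clamp)

  n_col_total <- config$n_regions * config$colonies_per_region
  colony_seeds <- sample.int(.Machine$integer.max - 1L,
                             n_col_total + config$n_regions)

  geno <- NULL
  meta <- list(); truth_s <- list(); truth_c <- list()
  rows <- list()
  ci <- 0L
  for (r in seq_len(config$n_regions)) {
    region <- sprintf("R%d", r)
    rc <- config$region_coords[r, ]
    for (k in seq_len(config$colonies_per_region)) {
      ci <- ci + 1L
      colony_id <- sprintf("%sC%d", region, k)
      cls <- sample(colony_classes, 1L, prob = config$social_mix)
      sim <- simulate_colony(cls, freq_bg[r, ], freq_sg[r, ], sg_fixed,
                             config, seed = colony_seeds[ci])
      nw <- nrow(sim$workers)
      ids <- sprintf("%s_W%02d", colony_id, seq_len(nw))
      rows[[length(rows) + 1L]] <- cbind(sim$geno_bg, sim$geno_sg)
      lat <- unname(rc["lat"]) + stats::rnorm(1, 0, config$coord_jitter_sd)
      lon <- unname(rc["lon"]) + stats::rnorm(1, 0, config$coord_jitter_sd)
      meta[[length(meta) + 1L]] <- data.frame(
        sample = ids, colony = colony_id, region = region,
        lat = lat, lon = lon, origin = "colony", stringsAsFactors = FALSE)
      truth_s[[length(truth_s) + 1L]] <- data.frame(
        sample = ids, colony = colony_id,
        matriline = sim$workers$matriline,
        patriline = sim$workers$patriline,
        supergene_genotype = sim$workers$supergene_genotype,
        stringsAsFactors = FALSE)
      truth_c[[length(truth_c) + 1L]] <- cbind(
        data.frame(colony = colony_id, region = region,
                   stringsAsFactors = FALSE),
        sim$colony)
    }
    ## transect singletons: unrelated individuals scattered along the region
    nt <- config$n_transect_per_region
    if (nt > 0) {
      set.seed(colony_seeds[n_col_total + r])
      for (t in seq_len(nt)) {
        tid <- sprintf("%s_T%02d", region, t)
        h1 <- draw_haplotype(freq_bg[r, ], freq_sg[r, ], sg_fixed,
                             if (stats::runif(1) < config$p_transect_P)
                               "P" else "M")
        h2 <- draw_haplotype(freq_bg[r, ], freq_sg[r, ], sg_fixed,
                             if (stats::runif(1) < config$p_transect_P)
                               "P" else "M")
        ind <- list(h = list(h1, h2))
        rows[[length(rows) + 1L]] <- matrix(diploid_dosage(ind), nrow = 1)
        meta[[length(meta) + 1L]] <- data.frame(
          sample = tid, colony = tid, region = region,
          lat = unname(rc["lat"]) + stats::rnorm(1, 0, config$coord_jitter_sd),
          lon = unname(rc["lon"]) + stats::rnorm(1, 0, config$coord_jitter_sd),
          origin = "transect", stringsAsFactors = FALSE)
        truth_s[[length(truth_s) + 1L]] <- data.frame(
          sample = tid, colony = tid, matriline = NA_integer_,
          patriline = NA_character_,
          supergene_genotype = sg_genotype_of(ind),
          stringsAsFactors = FALSE)
      }
    }
  }
  geno <- do.call(rbind, rows)
  metadata <- do.call(rbind, meta)
  rownames(geno) <- metadata$sample
  truth_samples <- do.call(rbind, truth_s)
  truth_colonies <- do.call(rbind, truth_c)
  rownames(metadata) <- rownames(truth_samples) <-
    rownames(truth_colonies) <- NULL

  ## genotyping error: allelic dropout (het -> random homozygote), then
  ## missingness, then optional Poisson depths
  set.seed(config$seed + 1L)
  if (config$dropout_rate > 0) {
    het <- which(geno == 1L)
    flip <- het[stats::runif(length(het)) < config$dropout_rate]
    if (length(flip)) {
      geno[flip] <- 2L * stats::rbinom(length(flip), 1L, 0.5)
    }
  }
  if (config$missing_rate > 0) {
    miss <- which(stats::runif(length(geno)) < config$missing_rate)
    geno[miss] <- NA_integer_
  }
  depths <- NULL
  if (!is.null(config$depth_mean)) {
    depths <- matrix(stats::rpois(length(geno), config$depth_mean),
                     nrow(geno), ncol(geno))
  }

  list(genotypes = genotype_table(geno, loci, depths),
       metadata = metadata,
       truth = list(samples = truth_samples, colonies = truth_colonies),
       region_freqs = list(background = freq_bg, supergene = freq_sg,
                           supergene_fixed = sg_fixed))
}
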