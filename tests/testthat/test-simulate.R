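test_that("Balding-Nichols draws have the right moments and edge cases", {
  p <- c(0.2, 0.5, 0.8)
  # F = 0 collapses to the ancestral frequency exactly
  f0 <- draw_region_frequencies(p, 0, 4)
  expect_equal(f0, matrix(p, 4, 3, byrow = TRUE))

  # Monte-Carlo check of the Beta moments: mean p, variance F p (1-p)
  set.seed(11)
  many <- draw_region_frequencies(rep(0.5, 20000), 0.2, 1)
  expect_lt(abs(mean(many) - 0.5), 0.01)
  expect_lt(abs(stats::var(as.vector(many)) - 0.2 * 0.25), 0.005)

  # near-fixation regime: U-shaped draws pile up near the boundaries
  set.seed(12)
  extreme <- draw_region_frequencies(rep(0.5, 5000), 0.95, 1)
  expect_gt(mean(extreme < 0.05 | extreme > 0.95), 0.8)

  expect_error(draw_region_frequencies(p, 1.0, 2), "fst")
  expect_error(draw_region_frequencies(c(0, 0.5), 0.1, 2), "strictly")
})

test_that("simulation is deterministic given the seed", {
  cfg <- quick_cfg(seed = 42)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
})

test_that("error processes realize at their configured rates", {
  cfg <- quick_cfg(seed = 5, missing_rate = 0.1, dropout_rate = 0,
                   colonies_per_region = 8, n_background_loci = 400)
  sim <- simulate_population(cfg)
  expect_lt(abs(mean(is.na(sim$genotypes$geno)) - 0.1), 0.01)
})

test_that("workers are Mendelian daughters of their recorded queen", {
  cfg <- quick_cfg(dropout_rate = 0, missing_rate = 0)
  set.seed(8)
  fr <- runif(300, 0.1, 0.9)
  cs <- simulate_colony("monogyne", fr, numeric(0), logical(0), cfg,
                        seed = 99)
  g <- cs$geno_bg
  expect_true(all(g %in% 0:2))
  qd <- cs$queens[[1]]$dosage
  # where the queen is homozygous the maternal allele is forced, so the
  # worker dosage can differ from the maternal contribution by at most
  # the single paternal allele
  for (w in seq_len(nrow(g))) {
    expect_true(all(g[w, qd == 0] <= 1))
    expect_true(all(g[w, qd == 2] >= 1))
  }
})

test_that("full-sister relatedness matches an independent pedigree oracle", {
  # pedigree-only IBD oracle: label maternal alleles, share one father
  set.seed(13)
  reps <- 3000
  shared <- replicate(reps, {
    m1 <- sample(1:2, 1)
    m2 <- sample(1:2, 1)
    # sisters share the paternal allele always, the maternal allele iff
    # the same maternal copy was transmitted
    (1 + (m1 == m2)) / 2
  })
  expect_lt(abs(mean(shared) - 0.75), 0.02)

  # the generator reproduces it: genotype-based moments estimator on
  # error-free single-region monogyne colonies
  cfg <- sim_config(seed = 14, n_regions = 1, colonies_per_region = 12,
                    fst_regions = 0, n_background_loci = 500,
                    n_supergene_loci = 0, n_transect_per_region = 0,
                    dropout_rate = 0, missing_rate = 0,
                    social_mix = c(monogyne = 1, polyandrous = 0,
                                   oligogynous = 0, polygynous = 0))
  sim <- simulate_population(cfg)
  r <- moments_relatedness(sim$genotypes)$estimate
  md <- sim$metadata
  within <- unlist(lapply(unique(md$colony), function(co) {
    ids <- md$sample[md$colony == co]
    m <- r[ids, ids]
    m[upper.tri(m)]
  }))
  expect_lt(abs(mean(within) - 0.75), 0.03)
})

test_that("cross-matriline workers of unrelated queens are unrelated", {
  cfg <- sim_config(seed = 15, n_regions = 1, colonies_per_region = 10,
                    fst_regions = 0, n_background_loci = 500,
                    n_supergene_loci = 0, n_transect_per_region = 0,
                    dropout_rate = 0, missing_rate = 0,
                    n_queens_polygyne = 2,
                    social_mix = c(monogyne = 0, polyandrous = 0,
                                   oligogynous = 0, polygynous = 1))
  sim <- simulate_population(cfg)
  r <- moments_relatedness(sim$genotypes)$estimate
  md <- sim$metadata
  tr <- sim$truth$samples
  cross <- unlist(lapply(unique(md$colony), function(co) {
    ids <- md$sample[md$colony == co]
    ml <- tr$matriline[match(ids, tr$sample)]
    m <- r[ids, ids]
    m[outer(ml, ml, "!=") & upper.tri(m)]
  }))
  expect_lt(abs(mean(cross)), 0.05)
})

test_that("fixed haplotype divergence forces heterozygous MP workers", {
  cfg <- quick_cfg(seed = 16, haplotype_divergence = 1,
                   dropout_rate = 0, missing_rate = 0,
                   colonies_per_region = 6,
                   social_mix = c(monogyne = 0.2, polyandrous = 0,
                                  oligogynous = 0, polygynous = 0.8))
  sim <- simulate_population(cfg)
  sg <- sim$genotypes$loci$chrom == "chr3"
  tr <- sim$truth$samples
  mp <- tr$sample[tr$supergene_genotype == "MP"]
  expect_gt(length(mp), 0)
  expect_true(all(sim$genotypes$geno[mp, sg] == 1L))
})

test_that("true supergene heterozygotes have negative window F", {
  cfg <- quick_cfg(seed = 17, colonies_per_region = 8)
  sim <- simulate_population(cfg)
  parts <- split_supergene_window(sim$genotypes)
  fis <- individual_fis(parts$inside)
  tr <- sim$truth$samples
  mp <- tr$sample[tr$supergene_genotype == "MP"]
  expect_gt(length(mp), 5)
  expect_lt(mean(fis[mp]), 0)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(social_mix = c(monogyne = 0.6, polyandrous = 0.1,
                                         oligogynous = 0.1,
                                         polygynous = 0.1)),
               "sum to 1")
  expect_error(sim_config(fst_regions = 1), "\\[0, 1\\)")
  expect_error(sim_config(supergene_window = list(chrom = "chr3",
                                                  start = 5e6, end = 2e6)),
               "start")
  expect_error(sim_config(dropout_rate = 1.5), "rates")
  # monogyne truth: one queen, one mate
  cfg <- quick_cfg(seed = 18,
                   social_mix = c(monogyne = 1, polyandrous = 0,
                                  oligogynous = 0, polygynous = 0))
  sim <- simulate_population(cfg)
  expect_true(all(sim$truth$colonies$n_queens == 1))
  expect_true(all(sim$truth$colonies$n_mates == 1))
  expect_true(all(sim$truth$samples$colony %in%
                    c(sim$truth$colonies$colony,
                      sim$metadata$colony[sim$metadata$origin ==
                                            "transect"])))
})
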