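test_that("expected heterozygosity matches closed forms", {
  # single variable site, p = 0.5 from 2 diploids: 2*0.25*(4/3) = 2/3
  g <- rbind(c(0L), c(2L))
  md <- data.frame(sample = c("s01", "s02"), colony = c("c1", "c2"),
                   region = "R1", lat = 50, lon = -120, origin = "colony",
                   stringsAsFactors = FALSE)
  out <- expected_heterozygosity(mk_tab(g), md)
  expect_equal(out$exp_het, 2 / 3)
  # a fixed region is reported as 0, with a message
  g2 <- rbind(c(0L, 0L), c(0L, 0L))
  expect_message(out2 <- expected_heterozygosity(mk_tab(g2), md),
                 "no variable sites")
  expect_equal(out2$exp_het, 0)
  expect_equal(out2$n_variable_sites, 0L)
})

test_that("diversity subset takes the least-missing worker per colony", {
  g <- matrix(1L, 5, 8)
  g[2, 1:4] <- NA # worst in colony c1
  g[1, 1] <- NA
  rownames(g) <- sprintf("s%02d", 1:5)
  md <- data.frame(sample = rownames(g),
                   colony = c("c1", "c1", "c1", "c2", "t1"),
                   region = "R1", lat = 50, lon = -120,
                   origin = c("colony", "colony", "colony", "colony",
                              "transect"),
                   stringsAsFactors = FALSE)
  sub <- diversity_subset(mk_tab(g), md)
  expect_setequal(sub, c("s03", "s04", "s05")) # s03 clean, s04 only c2,
                                               # transect always in
})

test_that("Weir-Cockerham FST matches the frozen variance-component oracle", {
  dos <- rbind(c(0L, 1L, 2L), c(0L, 1L, 1L), c(1L, 0L, 2L), c(0L, 0L, 2L),
               c(2L, 0L, 0L), c(2L, 1L, 0L), c(1L, 1L, 1L), c(2L, 0L, 0L))
  tab <- mk_tab(dos)
  a <- sprintf("s%02d", 1:4); b <- sprintf("s%02d", 5:8)
  fst <- weir_cockerham_fst(tab, a, b)
  # value frozen from an independent transcription of the 1984
  # two-population variance components
  expect_equal(fst, 0.5268817204301075, tolerance = 1e-12)
  # the in-suite scalar oracle agrees, and ratio-of-sums differs from
  # mean-of-ratios (pinning the aggregation convention)
  expect_equal(fst, oracle_wc_fst(dos[1:4, ], dos[5:8, ]),
               tolerance = 1e-12)
  expect_equal(oracle_wc_fst(dos[1:4, ], dos[5:8, ], "mean_of_ratios"),
               0.4162962962962964, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fst, 0.4162962962962964)))
  # symmetric in group order
  expect_equal(weir_cockerham_fst(tab, b, a), fst, tolerance = 1e-14)
  expect_error(weir_cockerham_fst(tab, a, c(b, "s01")), "overlap")
})

test_that("FST endpoints behave: fixed differences and panmixia", {
  fixed <- mk_tab(rbind(matrix(0L, 4, 5), matrix(2L, 4, 5)))
  expect_equal(weir_cockerham_fst(fixed, sprintf("s%02d", 1:4),
                                  sprintf("s%02d", 5:8)), 1)
  set.seed(61)
  pan <- mk_tab(hwe_geno(40, runif(800, 0.2, 0.8)))
  est <- weir_cockerham_fst(pan, sprintf("s%03d", 1:20),
                            sprintf("s%03d", 21:40))
  # unbiased around zero; slightly negative values are legitimate
  expect_lt(abs(est), 0.01)
})

test_that("great-circle distance matches the haversine closed form", {
  expect_equal(great_circle_distance(50, -120, 50, -120), 0)
  expect_equal(great_circle_distance(0, 0, 0, 180), pi * 6371000,
               tolerance = 1e-9)
  # independent transcription of the haversine formula
  hav <- function(lat1, lon1, lat2, lon2) {
    to_rad <- pi / 180
    dlat <- (lat2 - lat1) * to_rad
    dlon <- (lon2 - lon1) * to_rad
    a <- sin(dlat / 2)^2 +
      cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
    2 * 6371000 * asin(sqrt(a))
  }
  expect_equal(great_circle_distance(51.05, -115.2, 39.3, -120.6),
               hav(51.05, -115.2, 39.3, -120.6), tolerance = 1e-6)
  expect_error(great_circle_distance(95, 0, 0, 0), "coordinates")
})

test_that("Rousset transform is increasing and defined for negatives", {
  x <- c(-0.05, 0, 0.1, 0.5, 0.9)
  y <- rousset_distance(x)
  expect_true(all(diff(y) > 0))
  expect_equal(rousset_distance(0.5), 1)
  expect_error(rousset_distance(1), "< 1")
})

test_that("IBD regression: exact fit, permutation reproducibility", {
  n <- 6
  meters <- as.matrix(stats::dist(seq_len(n) * 1000))
  fst <- 0.0001 * meters / (1 + 0.0001 * meters) # rousset exactly linear
  dimnames(fst) <- dimnames(meters) <- list(letters[1:n], letters[1:n])
  out <- ibd_regression(fst, meters, n_permutations = 199, seed = 1)
  expect_equal(out$r_squared, 1, tolerance = 1e-12)
  expect_equal(out$slope, 0.0001, tolerance = 1e-10)
  expect_lt(out$p_mantel, 0.05)
  out2 <- ibd_regression(fst, meters, n_permutations = 199, seed = 1)
  expect_identical(out$p_mantel, out2$p_mantel)
})

test_that("IBD on stepping-stone colonies is positive; shuffled geography is null", {
  set.seed(62)
  nr <- 5
  L <- 300
  anc <- runif(L, 0.2, 0.8)
  freqs <- matrix(NA_real_, nr, L)
  freqs[1, ] <- draw_region_frequencies(anc, 0.04, 1)
  for (r in 2:nr) {
    freqs[r, ] <- draw_region_frequencies(
      pmin(pmax(freqs[r - 1, ], 1e-4), 1 - 1e-4), 0.04, 1)
  }
  coords <- cbind(lat = seq(40, 52, length.out = nr), lon = -120)
  cfg <- quick_cfg()
  rows <- list(); meta <- list()
  k <- 0
  for (r in seq_len(nr)) for (cc in 1:3) {
    k <- k + 1
    cs <- simulate_colony("monogyne", freqs[r, ], numeric(0), logical(0),
                          cfg, seed = 7000 + k)
    ids <- sprintf("R%dC%d_W%02d", r, cc, 1:8)
    g <- cs$geno_bg; rownames(g) <- ids
    rows[[k]] <- g
    meta[[k]] <- data.frame(
      sample = ids, colony = sprintf("R%dC%d", r, cc),
      region = sprintf("R%d", r),
      lat = unname(coords[r, 1]) + stats::rnorm(1, 0, 0.03),
      lon = unname(coords[r, 2]) + stats::rnorm(1, 0, 0.03),
      origin = "colony", stringsAsFactors = FALSE)
  }
  tab <- mk_tab(do.call(rbind, rows))
  md <- do.call(rbind, meta)
  cp <- colony_pairwise(tab, md)
  ibd <- ibd_regression(cp$fst, cp$meters, n_permutations = 499, seed = 2)
  expect_gt(ibd$slope, 0)
  expect_lt(ibd$p_mantel, 0.05)
  # shuffling geography against genetics kills the signal
  set.seed(63)
  p_null <- replicate(10, {
    perm <- sample(nrow(cp$meters))
    m2 <- cp$meters[perm, perm]
    ibd_regression(cp$fst, m2, n_permutations = 199,
                   seed = sample.int(1e6, 1))$p_mantel
  })
  expect_gt(mean(p_null), 0.2)
})
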