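test_that("VCF write/read round-trips a simulated table", {
  sim <- simulate_population(quick_cfg(seed = 2, depth_mean = 30))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, path)
  back <- read_vcf(path)
  expect_identical(unname(back$geno), unname(sim$genotypes$geno))
  expect_identical(sample_ids(back), sample_ids(sim$genotypes))
  expect_equal(back$loci$pos, sim$genotypes$loci$pos)
  expect_equal(unname(back$depths), unname(sim$genotypes$depths * 1))
})

test_that("VCF parsing handles dosage, missing, phase, half and multi calls", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", "b", sep = "\t"),
    paste("chr1", "100", ".", "A", "T", ".", "PASS", ".", "GT",
          "0/1", "./.", sep = "\t"),
    paste("chr1", "200", ".", "G", "C", ".", "PASS", ".", "GT",
          "1|1", "0|0", sep = "\t"),
    paste("chr1", "300", ".", "A", "C,G", ".", "PASS", ".", "GT",
          "1/2", "0/0", sep = "\t"),
    paste("chr1", "400", ".", "T", "G", ".", "PASS", ".", "GT",
          "./1", "1/0", sep = "\t")), path)
  expect_message(expect_message(tab <- read_vcf(path), "multi-allelic"),
                 "half")
  expect_equal(ncol(tab$geno), 3L) # multi-allelic record dropped
  expect_equal(unname(tab$geno["a", ]), c(1L, 2L, NA))
  expect_equal(unname(tab$geno["b", ]), c(NA, 0L, 1L))
})

test_that("filters apply in the fixed order with pinned counts", {
  # 10 samples x 5 loci; locus 3 missing in 3/10 samples (dropped at the
  # missingness step); locus 4 monomorphic (dropped at MAF); sample 10
  # then misses 1/3 of retained loci (dropped); no monomorphic recheck
  # casualties
  g <- matrix(1L, 10, 5)
  g[, 1] <- c(0L, 0L, 1L, 2L, 1L, 0L, 1L, 2L, 0L, 1L)
  g[, 2] <- c(2L, 1L, 0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L)
  g[1:3, 3] <- NA
  g[, 4] <- 0L
  g[, 5] <- c(1L, 1L, 0L, 0L, 1L, 1L, 2L, 2L, 1L, 1L)
  g[10, c(2, 5)] <- NA
  tab <- mk_tab(g)
  out <- filter_genotypes(tab)
  log <- filter_log(out)
  first <- log[log$pass == 1L, ]
  expect_equal(first$step,
               c("depth_mask", "locus_missingness", "maf",
                 "sample_missingness", "monomorphic_recheck"))
  expect_equal(first$removed, c(0L, 1L, 1L, 1L, 0L))
  expect_equal(first$n_loci, c(5L, 4L, 3L, 3L, 3L))
  expect_equal(first$n_samples, c(10L, 10L, 10L, 9L, 9L))
  expect_false("s10" %in% sample_ids(out))
})

test_that("depth masking precedes the missingness filters", {
  g <- matrix(1L, 6, 4)
  d <- matrix(30L, 6, 4)
  d[1:2, 1] <- 3L # below the floor of 7 -> masked -> locus 33% missing
  g[, 2] <- c(0L, 0L, 1L, 2L, 1L, 2L)
  g[, 3] <- c(2L, 1L, 0L, 1L, 2L, 0L)
  g[, 4] <- c(1L, 0L, 2L, 1L, 0L, 2L)
  tab <- mk_tab(g, depths = d)
  out <- filter_genotypes(tab)
  log <- filter_log(out)
  expect_equal(log$removed[log$step == "depth_mask"], 2L)
  expect_equal(log$removed[log$step == "locus_missingness"], 1L)
  expect_equal(ncol(out$geno), 3L)
})

test_that("a low-frequency allele is removed at the MAF step", {
  rare <- c(1L, rep(0L, 9))                      # alt freq 1/20 = 0.05
  common <- rep(c(0L, 1L, 2L), length.out = 10)  # comfortably polymorphic
  tab <- mk_tab(cbind(rare, common, common))
  # exactly at the default threshold: kept (MAF < 0.05 is the drop rule)
  expect_equal(ncol(filter_genotypes(tab)$geno), 3L)
  # a frequency below the threshold is dropped
  expect_equal(ncol(filter_genotypes(tab, min_maf = 0.051)$geno), 2L)
})

test_that("filtering is idempotent", {
  sim <- simulate_population(quick_cfg(seed = 9, missing_rate = 0.15))
  once <- filter_genotypes(sim$genotypes)
  twice <- filter_genotypes(once)
  expect_identical(once$geno, twice$geno)
  expect_identical(once$loci, twice$loci)
})

test_that("window split is inclusive and drops the whole chromosome", {
  g <- matrix(1L, 4, 6)
  g[1, ] <- 0L; g[2, ] <- 2L
  loci <- data.frame(chrom = c("chr1", "chr3", "chr3", "chr3", "chr3",
                               "chr4"),
                     pos = c(5000L, 1999999L, 2000000L, 12500000L,
                             13000000L, 100L),
                     ref = "A", alt = "T")
  rownames(g) <- sprintf("s%d", 1:4)
  tab <- genotype_table(g, loci)
  parts <- split_supergene_window(tab)
  inside_keys <- paste(parts$inside$loci$chrom, parts$inside$loci$pos)
  outside_keys <- paste(parts$outside$loci$chrom, parts$outside$loci$pos)
  expect_setequal(inside_keys, c("chr3 2000000", "chr3 12500000"))
  expect_setequal(outside_keys, c("chr1 5000", "chr4 100"))
  # off-window chromosome-3 loci appear in neither part
  expect_false(any(grepl("1999999|13000000", c(inside_keys, outside_keys))))
  expect_length(intersect(inside_keys, outside_keys), 0)
  expect_identical(attr(parts$inside, "window_role"), "inside")
  expect_identical(attr(parts$outside, "window_role"), "outside")
})

test_that("metadata round-trips and is validated", {
  md <- data.frame(sample = c("a", "b"), colony = c("c1", "c1"),
                   region = "R1", lat = c(50.1, 50.2),
                   lon = c(-120, -120.1), origin = "colony",
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(md, path)
  expect_equal(read_metadata(path), md)
  md_bad <- md; md_bad$lat[1] <- 99
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(md_bad, path2)
  expect_error(read_metadata(path2), "coordinates")
})
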