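#' Read a VCF into a genotype table
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a [genotype_table()].
#' Multi-allelic records are dropped and half-calls (e.g. `./0`) set to
#' missing; both are reported via `message()`. Phase separators (`|`) are
#' ignored. Loci are returned in file order.
#'
#' @param path path to a VCF (plain or gzipped).
#' @return a `genotype_table` with depths if the VCF has a DP FORMAT field.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns: ", path)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message("dropping ", sum(multi), " multi-allelic record(s)")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no bi-allelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dosage[gt_clean %in% c("0/0")] <- 0L
  dosage[gt_clean %in% c("0/1", "1/0")] <- 1L
  dosage[gt_clean %in% c("1/1")] <- 2L
  half <- !is.na(gt_clean) & !(gt_clean %in% c("0/0", "0/1", "1/0", "1/1",
                                               "./."))
  if (any(half)) message("setting ", sum(half), " half/odd call(s) to missing")
  depths <- NULL
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DP" %in% fmt) {
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    depths <- t(dp)
  }
  loci <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  genotype_table(t(dosage), loci, depths)
}

#' Write a genotype table as VCF 4.2
#'
#' Emits a minimal bi-allelic SNP VCF with a GT FORMAT field (plus DP when
#' the table carries depths). Dosage 0/1/2/NA maps to `0/0`, `0/1`, `1/1`,
#' `./.`.
#'
#' @param x a `genotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  has_dp <- !is.null(x$depths)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=antsoc",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (has_dp) {
    hdr <- c(hdr, paste0('##FORMAT=<ID=DP,Number=1,Type=Integer,',
                         'Description="Read Depth">'))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", sample_ids(x)),
                      collapse = "\t"))
  gt <- matrix(c("0/0", "0/1", "1/1")[x$geno + 1L],
               nrow(x$geno), ncol(x$geno))
  gt[is.na(x$geno)] <- "./."
  if (has_dp) {
    dp <- x$depths
    dp_chr <- matrix(as.character(dp), nrow(dp), ncol(dp))
    dp_chr[is.na(dp)] <- "."
    gt <- matrix(paste(gt, dp_chr, sep = ":"), nrow(gt), ncol(gt))
  }
  fmt <- if (has_dp) "GT:DP" else "GT"
  body <- vapply(seq_len(ncol(x$geno)), function(i) {
    paste(c(x$loci$chrom[i], x$loci$pos[i], ".", x$loci$ref[i],
            x$loci$alt[i], ".", "PASS", ".", fmt, gt[, i]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write the sample-metadata table
#'
#' Tab-separated with header `sample, colony, region, lat, lon, origin`;
#' `origin` distinguishes colony samples from transect singletons.
#'
#' @param path file path.
#' @return data.frame (for `read_metadata`).
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "colony", "region", "lat", "lon")
  if (!all(need %in% names(md))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(md$sample)) stop("duplicate sample ids in metadata")
  if (any(abs(md$lat) > 90, na.rm = TRUE) ||
      any(abs(md$lon) > 180, na.rm = TRUE)) {
    stop("invalid coordinates in metadata")
  }
  if (is.null(md$origin)) md$origin <- "colony"
  md
}

#' @rdname read_metadata
#' @param md metadata data.frame.
#' @export
write_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the standard locus/sample filters
#'
#' Reproduces a fixed sequential genotype-filtering recipe for RAD-style
#' SNP matrices, in this order:
#' 1. mask genotype calls with read depth below `min_depth` (skipped when
#'    the table has no depths);
#' 2. drop loci whose missing fraction exceeds `max_locus_missing`;
#' 3. drop loci with minor allele frequency below `min_maf` (computed on
#'    non-missing dosages);
#' 4. drop samples whose missing fraction (over retained loci) exceeds
#'    `max_sample_missing`;
#' 5. drop loci left monomorphic by the sample removal.
#'
#' Fractions are always relative to the currently retained samples/loci.
#' Because removing samples can push a locus back over the missingness
#' threshold (and vice versa), steps 2-5 are repeated until a full pass
#' removes nothing, making the operation idempotent; the first pass
#' reproduces the one-shot sequential recipe exactly. The per-step counts
#' of every pass are recorded in a log retrievable with [filter_log()].
#'
#' @param x a `genotype_table`.
#' @param min_depth genotype-level depth floor (default 7).
#' @param max_locus_missing maximum per-locus missing fraction (default
#'   0.2, i.e. a locus must be present in at least 80% of samples).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param max_sample_missing maximum per-sample missing fraction
#'   (default 0.2).
#' @return the filtered `genotype_table` with a `filter_log` attribute.
#' @export
filter_genotypes <- function(x, min_depth = 7, max_locus_missing = 0.2,
                             min_maf = 0.05, max_sample_missing = 0.2) {
  stopifnot(min_depth >= 0, max_locus_missing >= 0, max_locus_missing <= 1,
            min_maf >= 0, min_maf <= 0.5,
            max_sample_missing >= 0, max_sample_missing <= 1)
  log <- list()
  note <- function(pass, step, removed, x) {
    log[[length(log) + 1L]] <<- data.frame(
      pass = pass, step = step, removed = removed,
      n_samples = nrow(x$geno), n_loci = ncol(x$geno),
      stringsAsFactors = FALSE)
  }
  geno <- x$geno
  depths <- x$depths
  if (!is.null(depths)) {
    mask <- !is.na(depths) & depths < min_depth & !is.na(geno)
    geno[mask] <- NA_integer_
    x <- genotype_table(geno, x$loci, depths)
    note(1L, "depth_mask", sum(mask), x)
  } else {
    note(1L, "depth_mask", 0L, x)
  }

  pass <- 0L
  repeat {
    pass <- pass + 1L
    removed_this_pass <- 0L
    mark <- length(log)

    lmiss <- colMeans(is.na(x$geno))
    keep <- lmiss <= max_locus_missing
    if (!any(keep)) stop("all loci removed at the locus-missingness step")
    x <- subset_loci(x, keep)
    removed_this_pass <- removed_this_pass + sum(!keep)
    note(pass, "locus_missingness", sum(!keep), x)

    p <- allele_freqs(x)
    maf <- pmin(p, 1 - p)
    keep <- !is.na(maf) & maf >= min_maf
    if (!any(keep)) stop("all loci removed at the MAF step")
    x <- subset_loci(x, keep)
    removed_this_pass <- removed_this_pass + sum(!keep)
    note(pass, "maf", sum(!keep), x)

    smiss <- rowMeans(is.na(x$geno))
    keep <- smiss <= max_sample_missing
    if (!any(keep)) stop("all samples removed at the sample-missingness step")
    x <- subset_samples(x, keep)
    removed_this_pass <- removed_this_pass + sum(!keep)
    note(pass, "sample_missingness", sum(!keep), x)

    p <- allele_freqs(x)
    keep <- !is.na(p) & p > 0 & p < 1
    if (!any(keep)) stop("all loci monomorphic after sample removal")
    x <- subset_loci(x, keep)
    removed_this_pass <- removed_this_pass + sum(!keep)
    note(pass, "monomorphic_recheck", sum(!keep), x)

    if (removed_this_pass == 0L) {
      if (pass > 1L) log <- log[seq_len(mark)] # drop the no-op pass
      break
    }
    if (pass >= 100L) break
  }

  attr(x, "filter_log") <- do.call(rbind, log)
  x
}

#' Retrieve the filter log of a filtered genotype table
#' @param x a `genotype_table` returned by [filter_genotypes()].
#' @return data.frame with columns step, removed, n_samples, n_loci.
#' @export
filter_log <- function(x) attr(x, "filter_log")

#' Split loci by the supergene window
#'
#' Partitions a genotype table for the two arms of the analysis:
#' * `inside`: loci on the window chromosome with
#'   `start <= pos <= end` (1-based, both ends inclusive) — the
#'   supergene-genotyping input;
#' * `outside`: loci on every *other* chromosome — the social-structure and
#'   population-genetics input. The whole window chromosome is excluded
#'   from `outside` (not just the window), so off-window loci on that
#'   chromosome appear in neither part.
#'
#' Both parts carry a `window_role` attribute; colony-level analyses check
#' it so that supergene-linked loci can never leak into social-form calls.
#'
#' @param x a `genotype_table`.
#' @param window list(chrom, start, end).
#' @return list with `genotype_table` elements `inside` and `outside`.
#' @export
split_supergene_window <- function(x, window = list(chrom = "chr3",
                                                    start = 2e6,
                                                    end = 12.5e6)) {
  on_chrom <- x$loci$chrom == window$chrom
  in_win <- on_chrom & x$loci$pos >= window$start & x$loci$pos <= window$end
  inside <- subset_loci(x, in_win)
  outside <- subset_loci(x, !on_chrom)
  attr(inside, "window_role") <- "inside"
  attr(outside, "window_role") <- "outside"
  attr(inside, "window") <- window
  attr(outside, "window") <- window
  list(inside = inside, outside = outside)
}
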