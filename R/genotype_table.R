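#' Genotype table
#'
#' The central container of the package: a samples x loci matrix of diploid
#' genotype dosages together with per-locus annotation. Dosage counts copies
#' of the ALT allele, so values are 0 (homozygous REF), 1 (heterozygous),
#' 2 (homozygous ALT) or `NA` (missing call). All loci are bi-allelic SNPs.
#'
#' @param geno integer matrix, samples in rows (rownames are sample ids),
#'   loci in columns; entries in `{0, 1, 2, NA}`.
#' @param loci data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; one row per column of `geno`. Positions must be strictly
#'   increasing within each chromosome.
#' @param depths optional matrix of per-genotype read depths, same shape
#'   as `geno`.
#' @return an object of class `genotype_table`: a list with elements
#'   `geno`, `loci` and (possibly `NULL`) `depths`.
#' @export
genotype_table <- function(geno, loci, depths = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno))) stop("geno must have sample ids as rownames")
  if (anyDuplicated(rownames(geno))) stop("duplicate sample ids")
  if (!is.data.frame(loci)) stop("loci must be a data.frame")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(loci))) {
    stop("loci must have columns chrom, pos, ref, alt")
  }
  if (nrow(loci) != ncol(geno)) stop("nrow(loci) must equal ncol(geno)")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  for (ch in unique(loci$chrom)) {
    p <- loci$pos[loci$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  if (!is.null(depths)) {
    depths <- as.matrix(depths)
    if (!all(dim(depths) == dim(geno))) stop("depths must match geno in shape")
  }
  rownames(loci) <- NULL
  colnames(geno) <- paste(loci$chrom, loci$pos, sep = ":")
  if (!is.null(depths)) dimnames(depths) <- dimnames(geno)
  structure(list(geno = geno, loci = loci, depths = depths),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf("genotype_table: %d samples x %d loci (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * miss))
  cat("chromosomes:", paste(unique(x$loci$chrom), collapse = ", "), "\n")
  if (!is.null(attr(x, "window_role"))) {
    cat("window role:", attr(x, "window_role"), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$geno)

#' Sample ids of a genotype table
#' @param x a `genotype_table`.
#' @return character vector of sample ids (row order).
#' @export
sample_ids <- function(x) rownames(x$geno)

#' Subset a genotype table by samples
#'
#' @param x a `genotype_table`.
#' @param samples character vector of sample ids or logical/integer index.
#' @return a `genotype_table` restricted to those samples; window-role
#'   provenance (see [split_supergene_window()]) is preserved.
#' @export
subset_samples <- function(x, samples) {
  g <- x$geno[samples, , drop = FALSE]
  d <- if (is.null(x$depths)) NULL else x$depths[samples, , drop = FALSE]
  out <- genotype_table(g, x$loci, d)
  attr(out, "window_role") <- attr(x, "window_role")
  attr(out, "window") <- attr(x, "window")
  out
}

#' Subset a genotype table by loci
#'
#' @param x a `genotype_table`.
#' @param idx logical or integer index over loci (columns).
#' @return a `genotype_table` restricted to those loci.
#' @export
subset_loci <- function(x, idx) {
  g <- x$geno[, idx, drop = FALSE]
  d <- if (is.null(x$depths)) NULL else x$depths[, idx, drop = FALSE]
  out <- genotype_table(g, x$loci[idx, , drop = FALSE], d)
  attr(out, "window_role") <- attr(x, "window_role")
  attr(out, "window") <- attr(x, "window")
  out
}

#' ALT allele frequencies
#'
#' Per-locus ALT allele frequency computed over non-missing genotype calls.
#'
#' @param x a `genotype_table`.
#' @return numeric vector, one frequency per locus (`NaN` where all calls
#'   are missing).
#' @export
allele_freqs <- function(x) {
  colMeans(x$geno, na.rm = TRUE) / 2
}
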