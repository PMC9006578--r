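#' Run the whole analysis pipeline
#'
#' Orchestrates the stages end to end: obtain genotypes (either read a
#' VCF + metadata or simulate a population), filter, split by the
#' supergene window, colony-level social-structure inference (outside
#' loci), supergene genotyping (window loci), optional mixed-model
#' association and population-genetic summaries. Every stage writes its
#' outputs as TSV/VCF into the run directory, plus a plain-text run log
#' with the realized filter counts and a machine-readable JSON summary.
#'
#' @param config a named list, or path to a YAML file, with keys:
#'   * exactly one of `simulate` (arguments for [sim_config()]) or
#'     `input` (list with `vcf` and `metadata` paths);
#'   * optional `filters` (arguments for [filter_genotypes()]);
#'   * optional `window` (list chrom/start/end; default chr3 2-12.5 Mbp);
#'   * optional `classifier` (list: `min_workers`, `matriline_threshold`,
#'     `thresholds`);
#'   * optional `association` (logical, default TRUE) and `popgen`
#'     (logical, default TRUE);
#'   * optional `seed` (default 1).
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list: the run summary plus the main result
#'   objects (`colony_report`, `supergene_calls`, `composition`,
#'   `association`, `popgen`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input)
  if (has_sim == has_input) {
    stop("config must contain exactly one of 'simulate' or 'input'")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  logf <- file.path(out_dir, "run_log.txt")
  log_lines <- c(sprintf("antsoc run, seed %d", seed),
                 sprintf("R %s", getRversion()))
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  fail_stage <- function(stage, e) {
    say("FAILED at stage %s: %s", stage, conditionMessage(e))
    writeLines(log_lines, logf)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }

  ## stage: input
  truth <- NULL
  tryCatch({
    if (has_sim) {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- seed
      cfg <- do.call(sim_config, sim_args)
      sim <- simulate_population(cfg)
      tab <- sim$genotypes
      md <- sim$metadata
      truth <- sim$truth
      write_vcf(tab, file.path(out_dir, "simulated.vcf"))
      write_metadata(md, file.path(out_dir, "metadata.tsv"))
      utils::write.table(truth$samples,
                         file.path(out_dir, "truth_samples.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(truth$colonies,
                         file.path(out_dir, "truth_colonies.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      say("simulated %d samples x %d loci", nrow(tab$geno), ncol(tab$geno))
    } else {
      if (!file.exists(config$input$vcf) ||
          !file.exists(config$input$metadata)) {
        stop("input paths do not exist")
      }
      tab <- read_vcf(config$input$vcf)
      md <- read_metadata(config$input$metadata)
      say("read %d samples x %d loci", nrow(tab$geno), ncol(tab$geno))
    }
  }, error = function(e) fail_stage("input", e))

  ## stage: filter
  tryCatch({
    filt_args <- c(list(tab), config$filters)
    tab <- do.call(filter_genotypes, filt_args)
    fl <- filter_log(tab)
    utils::write.table(fl, file.path(out_dir, "filter_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("filtering retained %d loci in %d samples",
        ncol(tab$geno), nrow(tab$geno))
    write_vcf(tab, file.path(out_dir, "filtered.vcf"))
    md <- md[md$sample %in% sample_ids(tab), , drop = FALSE]
  }, error = function(e) fail_stage("filter", e))

  ## stage: window split
  window <- if (is.null(config$window)) {
    list(chrom = "chr3", start = 2e6, end = 12.5e6)
  } else config$window
  parts <- split_supergene_window(tab, window)
  say("window split: %d loci inside, %d outside (chromosome %s dropped)",
      ncol(parts$inside$geno), ncol(parts$outside$geno), window$chrom)

  ## stage: colony social structure (outside loci only)
  cl_cfg <- config$classifier
  report <- NULL
  tryCatch({
    report <- colony_report(
      parts$outside, md,
      min_workers = if (is.null(cl_cfg$min_workers)) 6
        else cl_cfg$min_workers,
      matriline_threshold = if (is.null(cl_cfg$matriline_threshold)) 0.5
        else cl_cfg$matriline_threshold,
      thresholds = if (is.null(cl_cfg$thresholds)) list()
        else cl_cfg$thresholds)
    utils::write.table(report, file.path(out_dir, "colony_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("classified %d colonies: %d monogyne, %d polygyne, %d undetermined",
        nrow(report), sum(report$social_form == "monogyne", na.rm = TRUE),
        sum(report$social_form == "polygyne", na.rm = TRUE),
        sum(report$social_form == "undetermined", na.rm = TRUE))
  }, error = function(e) fail_stage("colony", e))

  ## stage: supergene genotyping (window loci)
  calls <- NULL; comp <- NULL
  tryCatch({
    if (ncol(parts$inside$geno) >= 2) {
      calls <- supergene_calls(parts$inside)
      utils::write.table(calls, file.path(out_dir, "supergene_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      pca <- attr(calls, "pca")
      utils::write.table(
        data.frame(locus = rownames(pca$loadings), pca$loadings),
        file.path(out_dir, "supergene_pc_loadings.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      comp <- colony_composition(calls, md, report)
      utils::write.table(comp$main,
                         file.path(out_dir, "colony_composition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(comp$undetermined,
                         file.path(out_dir,
                                   "colony_composition_undetermined.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      say("supergene calls: %s",
          paste(names(table(calls$class)), table(calls$class),
                sep = "=", collapse = " "))
    } else {
      say("supergene stage skipped: <2 window loci after filtering")
    }
  }, error = function(e) fail_stage("supergene", e))

  ## stage: association (colony workers with determined social form)
  assoc <- NULL
  run_assoc <- is.null(config$association) || isTRUE(config$association)
  if (run_assoc && !is.null(report)) tryCatch({
    determined <- report$colony[!is.na(report$social_form) &
                                  report$social_form != "undetermined"]
    keep <- md$origin == "colony" & md$colony %in% determined
    if (sum(keep) >= 10) {
      tab_a <- subset_samples(tab, md$sample[keep])
      pheno <- ifelse(
        report$social_form[match(md$colony[keep], report$colony)] ==
          "polygyne", 1, 0)
      names(pheno) <- md$sample[keep]
      if (length(unique(pheno)) == 2L) {
        ## kinship from loci off the supergene chromosome: keeping the
        ## candidate region out of K avoids proximal contamination of
        ## the scan
        K <- centered_kinship(
          subset_samples(parts$outside, sample_ids(tab_a)))
        assoc <- lmm_scan(tab_a, pheno, K)
        utils::write.table(
          cbind(assoc,
                neg_log10_p = -log10(assoc$p),
                bonferroni = attr(assoc, "bonferroni")),
          file.path(out_dir, "association.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        say("association scan: %d loci tested, %d above Bonferroni",
            nrow(assoc), sum(assoc$significant))
      } else say("association skipped: only one social form present")
    } else say("association skipped: too few classified workers")
  }, error = function(e) fail_stage("association", e))

  ## stage: popgen (outside loci)
  pg <- NULL
  run_pg <- is.null(config$popgen) || isTRUE(config$popgen)
  if (run_pg) tryCatch({
    div <- expected_heterozygosity(parts$outside, md)
    utils::write.table(div, file.path(out_dir, "expected_het.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cp <- colony_pairwise(parts$outside, md)
    ibd <- ibd_regression(cp$fst, cp$meters, n_permutations = 999,
                          seed = seed)
    utils::write.table(ibd$pairs, file.path(out_dir, "ibd_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pg <- list(diversity = div, ibd = ibd[c("slope", "intercept",
                                            "r_squared", "p_mantel",
                                            "n_pairs")])
    say("IBD: slope %.3g, r2 %.3f, Mantel p %.4f over %d pairs",
        ibd$slope, ibd$r_squared, ibd$p_mantel, ibd$n_pairs)
  }, error = function(e) fail_stage("popgen", e))

  summary <- list(
    seed = seed,
    n_samples = nrow(tab$geno), n_loci = ncol(tab$geno),
    n_loci_window = ncol(parts$inside$geno),
    social_forms = as.list(table(report$social_form)),
    supergene_classes = if (!is.null(calls))
      as.list(table(calls$class)) else NULL,
    association = if (!is.null(assoc)) list(
      n_tested = nrow(assoc),
      n_significant = sum(assoc$significant),
      bonferroni = attr(assoc, "bonferroni")) else NULL,
    popgen = if (!is.null(pg)) list(
      exp_het = stats::setNames(pg$diversity$exp_het,
                                pg$diversity$region),
      ibd = pg$ibd) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, logf)
  invisible(list(summary = summary, colony_report = report,
                 supergene_calls = calls, composition = comp,
                 association = assoc, popgen = pg,
                 genotypes = tab, metadata = md, truth = truth,
                 out_dir = out_dir))
}
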