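Package: antsoc
Title: Colony Social Structure and Supergene Genotyping from SNP Data in Ants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers colony-level social organization (monogyne versus polygyne)
    and per-individual social-supergene genotypes in socially polymorphic ants
    from bi-allelic SNP genotype matrices. Implements opposing homozygosity,
    several pairwise relatedness and kinship estimators tailored to
    haplodiploid worker samples, a consensus social-form classifier, PCA-based
    supergene genotyping with window-level inbreeding coefficients, a
    kinship-controlled linear mixed-model association scan, and regional
    population-genetic summaries (expected heterozygosity, Weir-Cockerham FST,
    isolation by distance with Mantel permutation). Ships a haplodiploid
    colony/population simulator with known pedigree and supergene ground truth
    so every stage of the pipeline can be validated without raw sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
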