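# antsoc

Colony social structure and supergene genotyping from SNP data in
socially polymorphic ants.

Many *Formica* ants vary in colony queen number: monogyne colonies are
headed by a single queen, polygyne colonies by several, and the
polymorphism is associated with a large non-recombining supergene on
chromosome 3 carrying two divergent haplotypes (M, monogyne-associated
and aligned with the reference assembly; P, polygyne-associated).
`antsoc` takes a bi-allelic SNP genotype matrix of worker samples (VCF)
plus sample metadata and infers:

* **colony social form** (monogyne / polygyne / undetermined) from three
  parallel signals computed on loci *off* chromosome 3 —
  * *opposing homozygosity*: the number of loci at which both homozygote
    classes occur among a colony's workers; exactly 0 for workers of one
    singly-mated queen, since one diploid mother and one haploid father
    carry at most three alleles,
  * *mean nestmate relatedness*: haplodiploid full sisters share ~0.75 of
    their genome (estimators: genomic relationship A<sub>jk</sub>, KING
    kinship φ, Queller–Goodnight moments r, and IBD-share π̂),
  * *matriline count* from single-linkage clustering on pairwise
    relatedness —
  combined by unanimous vote, with any conflict reported as
  `undetermined` rather than forced;
* **per-worker supergene genotype** (MM / Sm-Sp-style MP / PP) from a
  standardized PCA of the chromosome-3 window (2–12.5 Mbp): PC1 separates
  three clusters, the cluster with negative window F<sub>IS</sub>
  (heterozygosity excess) is MP, and reference-allele homozygosity
  orients MM vs PP;
* **association** between each SNP and colony social form via a
  per-SNP linear mixed model `y = μ + xβ + u + ε`, `u ~ N(0, σ²_g K)`,
  with a centered kinship matrix, ML variance-ratio profiling, Wald
  tests and a Bonferroni threshold;
* **population structure**: regional expected heterozygosity
  2p̂q̂·n/(n−1), pairwise Weir–Cockerham F<sub>ST</sub> between colonies,
  haversine distances, and isolation by distance as an OLS fit of
  Rousset's F<sub>ST</sub>/(1−F<sub>ST</sub>) on meters with a Mantel
  permutation p-value.

A haplodiploid colony/population simulator (`simulate_population()`)
with Balding–Nichols regional structure, explicit pedigrees, a
non-recombining supergene block, allelic dropout and missingness
provides ground truth for every stage; the whole pipeline is validated
against it in the test suite. See `vignette("social-structure")` for the
methods account.

## Worked example

Simulate a five-region design (30 colonies × 8 workers plus transect
singletons, 300 background SNPs + 26 supergene-window SNPs, regional
F<sub>ST</sub> 0.15, 2% dropout, 5% missingness), then run the stages:

```r
library(antsoc)

cfg <- sim_config(seed = 2024)
sim <- simulate_population(cfg)

tab <- filter_genotypes(sim$genotypes)
tab
#> genotype_table: 265 samples x 325 loci (5.1% missing)
#> chromosomes: chr1, chr2, chr4, chr5, chr3

parts <- split_supergene_window(tab)   # inside window / outside chr3
rep <- colony_report(parts$outside, sim$metadata)
table(rep$social_form)
#> monogyne polygyne
#>       16       14
head(rep[, c("colony", "n_workers", "oh_count", "oh_frac",
             "mean_r_moments", "matrilines", "social_form")], 4)
#>   colony n_workers oh_count    oh_frac mean_r_moments matrilines social_form
#> 1   R1C1         8        3 0.01003344      0.7986450          1    monogyne
#> 2   R1C2         8       75 0.25083612      0.3762610          3    polygyne
#> 3   R1C3         8       73 0.24414716      0.4141110          3    polygyne
#> 4   R1C4         8       58 0.19397993      0.4525215          3    polygyne

calls <- supergene_calls(parts$inside)
table(calls$class)
#>  MM  MP  PP
#> 184  60  21

cp <- colony_pairwise(parts$outside, sim$metadata)
ibd <- ibd_regression(cp$fst, cp$meters, n_permutations = 999, seed = 2024)
#> IBD: slope=9.11e-08  r2=0.078  Mantel p=0.0010 over 435 pairs
```

Reading the output: colony `R1C1` shows near-zero opposing homozygosity
(3 of 299 loci, attributable to dropout), full-sister-level mean
relatedness (0.80) and a single matriline — a unanimous monogyne call —
while `R1C2` shows OH at 25% of loci, relatedness diluted to 0.38 and
three matrilines: polygyne. Against the simulator's truth tables, both
the social-form calls and all 265 supergene genotype calls are correct
in this run, and the positive Mantel-significant IBD slope reflects the
built-in regional divergence.

The same stages run end to end from a config (YAML or list) with
`run_pipeline()`, which writes the filtered VCF, colony report,
supergene calls and composition, association results, population-genetic
tables, a run log with realized filter counts, and a JSON summary into a
run directory — from a real VCF + metadata pair exactly as from a
simulate block.

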