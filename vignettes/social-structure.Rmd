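---
title: "Inferring ant colony social structure and supergene genotypes from SNPs"
author: "antsoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ant colony social structure and supergene genotypes from SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many *Formica* ants are socially polymorphic: some colonies are headed by a
single queen (monogyne), others by several (polygyne), and the difference is
associated with a large non-recombining "social supergene" on chromosome 3
carrying two divergent haplotypes, M (monogyne-associated, aligned with the
reference assembly) and P (polygyne-associated). Given a reduced-
representation SNP matrix of worker genotypes — a few hundred bi-allelic
loci in a few hundred workers sampled as ~8 nestmates per colony across
several regions — `antsoc` answers three questions:

1. **Which colonies are monogyne, which polygyne?** Workers are
   haplodiploid full sisters under one singly-mated queen; multiple queens
   or multiple mates dilute relatedness and create *opposing
   homozygosity*.
2. **Which supergene genotype (MM / MP / PP) does each worker carry?**
3. **How are the populations structured geographically?**

Because the raw field data cannot be regenerated at will, the package also
contains a pedigree-explicit simulator whose ground truth exercises every
stage; all quantitative guarantees quoted below are properties of that
simulator and are recomputed by the test suite.

## Colony-level inference

All colony-level statistics use only loci *off* the supergene chromosome
(the whole chromosome is excluded, not just the window), so social-form
calls stay independent of the supergene genotyping. `split_supergene_window()`
stamps a provenance attribute on its outputs and `colony_report()` refuses
tables that do not carry it.

**Opposing homozygosity (OH).** A locus shows opposing homozygosity within
a colony when one worker is homozygous REF and another homozygous ALT.
One diploid mother and one haploid father can jointly carry at most three
alleles and can never produce both homozygote classes, so an error-free
monogyne colony has OH exactly 0. Each additional queen (or, to a lesser
degree, mate) adds segregating parental alleles and pushes OH up. Two
caveats carry over from the field: allelic dropout (a heterozygote
miscalled as a random homozygote) creates false OH in monogyne colonies at
roughly 1–2% of loci for 8 workers at a 2% dropout rate, and the maximum
OH of a *polyandrous* colony is capped by the number of loci at which its
single queen is heterozygous (an inbred queen bounds OH from above; the
suite checks this cap explicitly).

**Relatedness.** Four pairwise estimators are implemented from their
moment definitions, all using sample allele frequencies from the complete
filtered dataset and pairwise-complete loci:

* `ajk()` — the genomic-relationship statistic; ~0 between unrelated
  individuals, ~1 on the diagonal for non-inbred individuals;
* `king_phi()` — the heterozygote-concordance kinship coefficient with
  maximum 0.5 (duplicates) and ~0.25 for mother–daughter pairs;
* `moments_relatedness()` — a Queller–Goodnight-style symmetrized
  method-of-moments relatedness. This is the designated voting axis and
  the documented stand-in for the Huang diploid moments estimator, whose
  published program invocation does not pin down a formula;
* `pi_hat()` — IBD-state probabilities (P0, P1, P2) from IBS counts
  against Hardy–Weinberg expectations, with `pi = P1/2 + P2`.

Haplodiploidy makes full sisters share the entire paternal genome, so
within-matriline relatedness is ~0.75 rather than 0.5; maternal half
sisters sit near 0.25 and cross-matriline pairs of unrelated queens near
0. One structural effect matters for thresholds: when allele frequencies
are pooled across diverged regions, unrelated pairs *within* a region are
inflated to roughly `2*Fst/(1+Fst)` (~0.26 at regional Fst 0.15), and all
pedigree values shift up with them. The estimator tests pin the clean
pedigree values; the classifier thresholds below absorb the shift.

**Matrilines.** Full-likelihood sibship reconstruction is out of scope;
`matriline_partition()` instead takes connected components of the graph
joining worker pairs with relatedness at or above a threshold (equivalent
to single-linkage merging). The structure-free midpoint between full
sisters (0.75) and unrelated matrilines (0) is 0.375, the function's
default; the colony pipeline passes 0.5, the midpoint once the pooled-
frequency inflation above is accounted for. Undefined pairs count as
below-threshold and are logged.

**Consensus call.** `classify_social_form()` takes three binary votes —
OH fraction, mean moments relatedness, matriline count — each with a
monogyne cutoff, a polygyne cutoff and an inner band. A colony is called
monogyne or polygyne only on a unanimous vote; any disagreement or
in-band vote yields `undetermined`. Ambiguous biologies (one polyandrous
queen; two sister queens) produce exactly the intermediate signatures the
band is for, and are surfaced rather than forced. Default cutoffs are
calibrated on the simulator's default conditions (8 workers, ~300
background loci, 2% dropout, 5% missingness, regional Fst 0.15):

| vote | monogyne | polygyne | rationale |
|------|----------|----------|-----------|
| OH / loci | ≤ 0.04 | ≥ 0.08 | ~3 binomial SD above dropout-induced false OH |
| mean r | ≥ 0.68 | ≤ 0.62 | full sisters ~0.75+, multi-queen ≲0.55, both inflated by pooling |
| matrilines | = 1 | ≥ 2 | threshold 0.5, see above |

Under those conditions the suite verifies ≥95% correct calls for both
pure monogyne and pure polygyne (unrelated queens) colonies, with
conflicted colonies always labeled undetermined. Colonies with fewer than
6 genotyped workers are excluded with a logged reason. All cutoffs are
arguments; nothing is hard-wired.

## Supergene genotyping

`window_pca()` runs a variance-standardized genotype PCA of the window
loci (mean imputation for PCA only), with a deterministic sign convention
(each component oriented so its largest-magnitude loading is positive).
With two divergent haplotypes, PC1 separates three collinear clusters and
the heterozygote cluster sits at the midpoint — an algebraic consequence
of standardized dosages at fixed differences. `cluster_pc1()` is a
deterministic 1-D 3-means (initialized at min/median/max); exactly three
clusters because a bi-allelic supergene admits exactly three diploid
classes. `assign_supergene_genotypes()` labels the cluster with the
lowest mean window inbreeding coefficient F (heterozygosity excess,
negative on clean data) as MP, then orients the homozygote clusters by
mean reference-homozygosity: the reference assembly carries the M
haplotype, so the REF-aligned cluster is MM. Relabeling REF/ALT at every
window locus therefore swaps MM and PP and leaves MP fixed, which the
suite asserts as a symmetry. Per-sample conflicts (e.g. positive F inside
the MP cluster) are flagged, never overwritten.

At 26 window loci and haplotype divergence ≥ 0.5 the full chain recovers
simulated truth at ≥99% per-individual accuracy under default error
rates. `colony_composition()` tabulates MM/MP/PP per colony with the
P-haplotype frequency `(2*PP + MP) / (2n)`, ordering colonies by region
and P frequency and splitting out colonies of undetermined social form.

## Mixed-model association

`lmm_scan()` fits, per SNP, `y = mu + x*beta + u + e` with
`u ~ N(0, sg2*K)`, `e ~ N(0, se2*I)`, where `y` is colony social form
(0/1) broadcast to workers and treated as quantitative — nestmate
non-independence is exactly what `K` absorbs. The implementation projects
out the intercept, eigendecomposes the restricted kinship once, profiles
the ML likelihood over the variance ratio on a log grid with local
refinement, and reports a Wald test with `F(1, n-2)` p-values plus the
Bonferroni threshold `0.05/L`. With `K = I` every statistic collapses to
the ordinary least-squares test exactly (a pinned identity in the suite),
and the null type-I error on colony-permuted phenotypes is at its nominal
level within binomial error at 2000 loci.

Two modeling choices deserve note. ML (not REML) is used for the
variance-ratio profile; the OLS-limit identity pins the convention.
And the kinship matrix fed to the scan is computed from loci *off* the
supergene chromosome. Including the candidate window in `K` lets the
random effect absorb a colony-constant phenotype almost completely
(proximal contamination): in the causal simulation the strongest window
locus drops from p ≈ 1e-13 to p ≈ 0.02 when the window is folded into
`K`. Leave-candidate-region-out kinship is therefore the pipeline
default. `centered_kinship()` itself is agnostic: it builds the centered
(not variance-scaled) Gram matrix of whatever table it is given, with
mean-dosage imputation standing in for a dedicated imputation tool —
at ≥80% completeness the difference is second order for a kinship
control.

## Population genetics

* `expected_heterozygosity()`: per-region mean nucleotide diversity per
  variable site, `2*p*q*n/(n-1)`, computed on one least-missing worker
  per colony plus all transect singletons (avoiding family
  pseudo-replication), supergene chromosome excluded.
* `weir_cockerham_fst()`: the 1984 two-population variance-components
  estimator with the observed-heterozygosity correction, aggregated as
  the weighted ratio of sums `sum(a)/sum(a+b+c)`. A fixture pins both
  this and the mean-of-ratios alternative so a silent convention change
  cannot pass. Negative estimates for undifferentiated pairs are
  reported unclipped: clipping would bias the IBD regression.
* `great_circle_distance()`: haversine on a 6,371,000 m sphere; the
  sphere-vs-ellipsoid error is sub-percent and irrelevant from meters to
  thousands of kilometers.
* `ibd_regression()`: OLS of Rousset's transform `Fst/(1-Fst)` on meters
  across colony pairs. Because pairs sharing a colony are dependent, the
  p-value is a one-sided Mantel permutation (colony labels of the
  genetic matrix permuted jointly), lower-bounded by
  `1/(n_permutations+1)`; pairs with Fst = 1 are dropped with a warning
  since the transform is undefined there.

## The simulator

`simulate_population()` draws, per region, allele frequencies from the
Balding–Nichols model (`Beta(p(1-F)/F, (1-p)(1-F)/F)`, mean `p`,
variance `F*p*(1-p)`), then builds colony pedigrees: diploid queens,
haploid mates, workers as Mendelian daughters with the supergene block
inherited intact. Colony classes are monogyne (1 queen x 1 mate),
polyandrous (1 queen x 2–4 mates), oligogynous (exactly two full-sister
queens — the conventional reading of ambiguous two-matriline colonies),
and polygynous (2–4 unrelated queens). Queen supergene genotypes follow a
configurable class-conditional distribution; the default gives monogyne
and polyandrous queens MM and draws polygyne queens from
{MM 0.3, MP 0.4, PP 0.3}, reproducing the pattern in which monogyne
colonies are pure MM while polygyne colonies can contain all three
classes. Mate haplotypes are M for monogyne (0% P), 25% P for
polyandrous/oligogynous and 50% P for polygynous colonies; polyandrous
mate numbers (2–4) are a free choice where no field estimate exists.
Genotyping error is applied in two stages — heterozygote dropout to a
random homozygote, then uniform missingness — matching the dominant RAD
error mode (non-detection of one allele). Defaults: 5 regions at real
western-North-American coordinates spanning ~39–59° N, 6 colonies x 8
workers plus 5 transect singletons per region, 300 background SNPs on
four non-supergene chromosomes, 26 window SNPs on chr3 2–12.5 Mbp with
haplotype divergence 0.8, regional Fst 0.15, dropout 0.02, missingness
0.05. Randomness is one master stream keyed by `seed`, from which one
documented substream seed per colony is drawn, so truth tables are
byte-reproducible.

What the simulator deliberately does **not** emulate: linkage among
background loci, batch effects between sequencing libraries, read-level
error profiles, queen turnover, inbreeding gradients, and spatially
autocorrelated sampling within regions. Passing tests therefore show the
statistics are implemented correctly and behave as designed under the
stated generative model — not that the classifier thresholds transfer
unchanged to a dataset whose error structure violates those assumptions;
on real data the thresholds should be inspected against the OH-vs-r
scatter.

## Numerical and edge-case conventions

* Filtering (`filter_genotypes()`) applies depth masking, locus
  missingness ≤ 0.2, MAF ≥ 0.05, sample missingness ≤ 0.2 and a
  monomorphism recheck, in that order, with fractions relative to the
  currently retained data; the cycle repeats until a fixed point so the
  operation is idempotent (the first pass reproduces the one-shot
  recipe, and the log records every pass). Whether MAF filtering should
  precede or follow sample removal is genuinely underdetermined in the
  original tool chain; the chosen order is pinned by a fixture rather
  than inferred.
* Window boundaries are 1-based inclusive at both ends, matching VCF
  convention; dosage counts the ALT allele so "reference-allele
  fraction" is well defined.
* Estimator edge cases (pairs sharing zero loci, zero denominators,
  monomorphic windows, fewer than three distinct PC1 values, constant
  phenotypes, overlapping FST groups, FST = 1 pairs) raise errors or
  return flagged `NA`s rather than silently degrading; tests cover each.
* Problem sizes in the suite (hundreds of workers, 300–2000 loci,
  199–999 Mantel permutations) were chosen as the smallest scales at
  which the Monte-Carlo tolerances quoted above are comfortably
  resolvable.

## Known limitations

* The matriline partition is a relatedness-threshold heuristic, not a
  likelihood pedigree model; its mistakes surface as `undetermined`
  calls rather than as confident errors, by construction.
* The moments stand-in for the named diploid estimator reproduces its
  role (a frequency-weighted moments relatedness), not its exact output.
* Binary phenotypes in a Gaussian LMM are a deliberate convention
  inherited from the standard association tools; effect sizes are on
  the linear-probability scale.
* With very few colonies the mixed model's Wald test inflates mildly
  (effective sample size is the colony count when the phenotype is
  colony-constant); the calibration guarantee is stated at 50 colonies.
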