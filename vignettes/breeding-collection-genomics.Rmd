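---
title: "Characterizing a breeding collection from RNA-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a breeding collection from RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpgem)
```

# The problem

Candidate crops — here, the archetype is a perennial, tuber-bearing,
open-pollinated legume collection of ~50 genotypes — typically lack a
reference genome, dense genotyping assays, and complete pedigrees. Leaf
RNA-seq of the collection supplies, in a single assay, (i) allele-specific
read counts at transcript positions, from which SNP genotypes can be
called, and (ii) per-genotype transcript abundances, which can themselves
serve as markers ("gene expression markers", GEMs). `snpgem` implements
the full desk side of that strategy: genotype calling with an explicit
filter cascade, diversity/inbreeding/relatedness estimation, population
structure from both marker types, synteny-projected linkage
disequilibrium, and marker-trait association — together with a simulator
that generates collections of exactly this shape with known truth.

# Genotype calling and the filter cascade

The caller works on per-sample, per-site allele depths (reference count,
variant count, mean variant base quality). Site discovery requires one
sample with at least 2 variant reads, variant fraction ≥ 20% and mean
variant base quality ≥ 10. Calls then require total depth ≥ 5; the variant
read fraction f is banded into dosage 0 (f < 0.2), 1 (0.2 ≤ f ≤ 0.8) and 2
(f > 0.8). The upper bound 0.8 is chosen symmetric with the documented 20%
heterozygote floor — standard practice for expressed-SNP calling, where
allelic imbalance in expression makes a wider het band hazardous. A sample
that meets the depth rule with f ≥ 0.2 but quality < 10 is set missing
rather than trusted. Site-level filters retain minor allele frequency
strictly above 0.1% (a fraction of 0.001, following the text rather than
the percent-scale table shorthand) and missingness strictly below 10%.
All thresholds are arguments.

Replicate reproducibility is the unweighted mean, over sites, of the
per-site agreement fraction across within-group replicate pairs (pairs
first, then sites; the averaging order is not canonical, so it is fixed
here and documented). Sites reproducible in *all* replicate groups are
reported separately, supporting a conservative marker subset for
relatedness work.

# Diversity, inbreeding and relatedness

Per segregating site with n non-missing allele copies and variant
frequency p, π_site = n/(n−1) · 2p(1−p); π averages π_site over assayed
sites, and θ = S/(a₁L) with a₁ = Σ 1/i. Both use the assayed SNP-site
count as denominator — values are per variant site, matching how diversity
is reported when the assayed base space is unknown (transcriptome-derived
markers). Tajima's D uses the standard constants with n equal to the total
allele-copy count. The test suite pins π to a brute-force oracle that
enumerates all C(n,2) allele-copy pairs per site; within-individual copy
pairs are included, which is what makes the frequency formula exact rather
than approximate.

Inbreeding uses the method-of-moments estimator
F = (O(hom) − E(hom)) / (L − E(hom)), with E(hom) summing
1 − 2p(1−p)·n/(n−1) over a genotype's non-missing sites. On complete data
F is affine in the heterozygous-site count, so its correlation with
per-genotype heterozygosity is exactly −1 — a sharp internal consistency
check that the acceptance suite exercises at 52 × 10,000.

IBD estimation equates observed IBS-state proportions with their
frequency-conditional expectations under IBD states 0/1/2 and solves
sequentially for Z0, Z1, Z2 (negatives clipped, triple renormalized,
PI-HAT = Z2 + Z1/2). No small-sample bias corrections are applied; the
estimator is validated against pedigree simulations (duplicates,
parent-offspring, unrelated) at ±0.05. Relationship boxes default to
parent-child (Z1 ≥ 0.7, Z0 ≤ 0.2) and half-sib (Z0, Z1 ∈ [0.35, 0.65]);
the cut-offs are arguments because no canonical values exist.

# Population structure

Three complementary views: Ward clustering of 1−IBS distances, PCA of
GRM-standardized dosages, and Ward clustering of genotype expression
profiles (log₂(x+1), top 1000 transcripts by variance, Euclidean
distance). `hclust` is run with `method = "ward.D"`, the behavior of R's
"Ward" option at the time this style of analysis became standard;
`ward.D2` is available via the `method` argument. PCA coordinates are
U·√λ from the GRM eigendecomposition, so their inner products reconstruct
the (truncated) GRM — a property the tests verify algebraically. The
log₂(x+1) offset handles exact zeros in FPKM-like matrices, which a bare
log cannot. Concordance against pedigree counts co-clustered parent-child
and half-sib pairs; when full reference labels exist the adjusted Rand
index is reported as well, because "everything in one cluster" trivially
maximizes pair concordance but not ARI — both numbers are emitted.

Admixture-proportion models and ML phylogenies are deliberately out of
scope; they are cited external tools in the workflow this package
reimplements, not part of its contribution.

# Linkage disequilibrium on a proxy genome

Transcript SNPs get provisional genome coordinates through synteny
anchors: position = start + offset − 1 on the + strand, and
start + transcript_length − offset on the − strand. Minus-strand anchors
without a transcript length place the SNP at the anchor start with a
warning — a flagged approximation, not silence. Unplaced SNPs stay in the
matrix and are excluded from positional analyses only.

Pairwise LD uses EM over unphased diploid genotype counts (tolerance
1e-10, ≤1000 iterations) to resolve the double-heterozygote phase
ambiguity, then r² = D²/(p_A q_A p_B q_B). A caution worth recording: the
squared *dosage* correlation equals this r² only in expectation under
random mating; the exact identity is at the allele-copy level, and that is
what the tests assert.

D′ confidence intervals follow the likelihood-grid convention: allele
frequencies fixed at their MLEs, |D′| scanned on a 0.001 grid, the
normalized likelihood treated as a posterior-like weight, and the 5th/95th
cut points reported. Strong LD means ci_low > 0.7 and ci_high ≥ 0.98;
strong recombination means ci_high < 0.9 (the classical defaults — the
upper-limit rule is stated in the source procedure, the recombination
bound follows the Gabriel convention). Haplotype blocks are contiguous
spans (≤ 2 Mb) whose strong-LD pairs exceed 95% of informative pairs,
accepted greedily by span length; block-eligible SNPs need MAF ≥ 0.05
(the usual default; configurable). The windowed implementation is pinned
to an exhaustive span-enumeration oracle on small instances.

Background LD is the 90th percentile of r² over subsampled
inter-chromosome pairs (seeded; all-pairs is quadratic and statistically
unnecessary). Decay distance at a threshold is the midpoint of the first
distance bin whose mean r² falls below the threshold *and stays below it*
— the "stays below" clause is this package's precise rendering of a decay
range, guarding against single noisy bins.

# Association

SNP association fits a single-random-effect mixed model per trait:
variance components by exact profile REML on the eigendecomposed kinship
(EMMA scheme), estimated once under the null and reused across SNPs — the
standard approximation, trading a negligible power loss for a ~M-fold
speedup. Each SNP is tested by GLS with covariance σ²_g K + σ²_e I; with
K = I the whole scan collapses to ordinary regression, which the tests
require to 1e-6. Significance follows the unadjusted p < 1e-4 convention
of small-collection association work; a BH-FDR column is emitted alongside
for transparency. Missing dosages drop the sample for that SNP rather than
being imputed, avoiding attenuation. QQ diagnostics report λ =
median(χ²₁(1−p))/0.4549; on structured null traits the mixed model's λ
sits closer to 1 than a naive scan's, which the acceptance suite checks on
a paired simulation.

GEM association regresses expression on trait (that orientation keeps the
estimate/SE/adjusted-r² scale of conventional expression-marker tables; t
and p are orientation-invariant). The family for Bonferroni control is all
GEMs within a trait. The published workflow screened Bonferroni survivors
visually for linearity violations; the package automates that screen with
two rules — (a) the association must survive removal of the single
highest-leverage genotype, and (b) an added quadratic term must not be
significant at 0.01. The thresholds are arguments and the screen always
returns plotting coordinates, because an automated proxy should invite,
not replace, a human look.

# The synthetic collection

The generator's defaults state the world the pipeline targets: 52
genotypes, 12 founders in 6 genotypic clusters, 11 chromosomes, an
open-pollination history in which each offspring records its mother and a
short list of candidate fathers (father drawn uniformly among them;
selfing probability 0.05, reflecting partial self-incompatibility),
Poisson(1) crossovers per chromosome with uniform breakpoints (no genetic
map is assumed, so the simplest exchangeable model is used), founder
allele frequencies Beta(0.5, 0.5) (high heterozygosity), cluster
divergence Balding-Nichols with F = 0.15, ~20% of transcripts polymorphic
with ~6 SNPs each, read depth negative-binomial with mean 30 and
dispersion 0.3, 1% sequencing error, base qualities ~N(30, 2), ~81% of
transcripts anchored, 20 traits with 2 planted SNPs each plus a polygenic
background scaled to heritability 0.5, and per-trait trait-linked
transcripts (slope 5, noise SD 1). Where the source material states a
value (collection size, chromosome number, cluster count, anchored
fraction, replicate count) the default is that value; where it is silent
(depth model, error rate, expression noise) the default is a realistic
choice fixed once, and the parameters are knobs, not estimates.

With these defaults the called collection lands near the published
diversity regime (π ≈ 0.34, θ ≈ 0.23, Tajima's D ≈ 1.9 on the worked
example) without any tuning toward those numbers — a consequence of the
stated founder spectrum and breeding history, and a useful sanity check
that the stated world is coherent.

What the generator does *not* emulate: read-level artifacts (mapping bias,
duplicates), splice isoforms, allele-specific expression, triploidy, and
realistic expression covariance beyond cluster shifts and planted links. A
green test therefore establishes correctness of the estimators on an
idealized but structurally faithful collection, not robustness to every
real-data pathology.

# Numerical choices and degenerate inputs

- EM: tolerance 1e-10, 1000 iterations; monomorphic members of a pair are
  skipped with a reason rather than producing NaN.
- D′ grid: step 0.001; haplotype frequencies floored at 1e-12 inside logs.
- REML: δ searched on log-scale grid [−10, 10] then refined by golden
  section; K jittered only within a declared tolerance, otherwise an
  error.
- Zero-variance traits, all-missing samples, empty replicate groups,
  pairs with no overlapping sites: all produce warnings or flagged NA
  results, never silent numbers.
- All randomness flows from a single integer seed per entry point; the
  pipeline stamps outputs with the package version, a config hash and the
  seed.

# Known limitations

Association power at n ≈ 52 is intrinsically low and the package reports
unadjusted p < 1e-4 findings as candidates, not discoveries. IBD estimates
assume a homogeneous population; in a structured collection PI-HAT between
same-cluster pairs is biased upward, which is why relationship boxes are
configurable. The LD machinery treats projected positions as true positions;
projection error from imperfect synteny translates directly into decay and
block error, and unanchored SNPs are simply invisible to it.
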