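---
title: "Models and methods in panelgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in panelgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`panelgwas` implements the analysis path of a SNP-array diversity panel of
a clonally propagated crop: QC and clone detection, genetic structure,
runs-of-homozygosity inbreeding, LD decay, BLUP phenotype modelling, mixed
model GWAS under additive and non-additive genotype encodings, and
LD-bounded candidate-gene analysis. This vignette documents the models,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## Data representation

Genotypes are biallelic SNP calls stored as alt-allele dosage (0 = a1a1,
1 = a1a2, 2 = a2a2, `NA` = missing) with a marker map of 1-based physical
positions; all coordinate arithmetic in the package is 1-based inclusive,
the VCF/GFF3 convention. Missing calls are never silently imputed: each
stage states its own missing-data rule (kinship excludes missing pairs
from the denominator, PCA mean-imputes for the projection only, the GWAS
tests each marker on its called subset, and markers below 80% coverage
are skipped).

## Quality control and clones

The filtering cascade removes samples called at ≤ 82% of markers first,
then applies SNP-level filters on the survivors: call rate > 90%, minor
allele frequency > 5% (computed on called genotypes as mean dosage / 2,
folded), and — for association datasets only — presence of all three
genotypic classes, each at frequency > 5%. All "higher than" thresholds
are strict, which fixes the boundary semantics; the cascade is idempotent,
and analysis datasets are assembled by subsetting the filtered panel and
re-filtering, so their marker sets can only shrink.

Identity-by-state between two samples is the fraction of jointly called
markers with identical calls. Clonal groups are the connected components
of the graph with edges at IBS > 0.98 (strict). Transitive closure is the
natural reading of "groups with two or more accessions": clone chains a–b
and b–c imply one group even if a–c falls below the threshold. Each group
is represented by its member with the most non-missing calls.

## Ancestry by masked matrix factorization

Ancestry is estimated by factorizing the half-dosage matrix,
$X/2 \approx QG$, with $Q$ rows on the probability simplex (membership
coefficients) and $G \in [0,1]$ (ancestral allele frequencies). This is
the same model class as sparse NMF ancestry estimators; we fit it by
alternating least squares with Euclidean simplex projection for $Q$,
clipping for $G$, an EM-style fill of unobserved entries with the current
prediction, and a backtracking interpolation toward each ALS candidate
that makes the observed-entry residual monotonically non-increasing — a
property the test suite asserts. Convergence is a relative residual change
below 1e-6 or 500 iterations. $K = 1$ is handled in closed form.

Model choice masks 5% of called entries per repetition and scores each
$K$ by the Bernoulli cross-entropy of the fitted frequencies on the masked
half-dosages; the chosen $K$ minimizes the mean masked cross-entropy over
repetitions, and the scores for all candidates are returned so a plateau
is visible to the user rather than silently resolved. A sample is assigned
to its argmax group only when that coefficient exceeds 0.60; otherwise it
is reported admixed — a flat true ancestry (e.g. 0.5/0.5) can never pass
this rule.

## Kinship, PCA, UPGMA

Additive kinship is the VanRaden estimator: dosages centered by $2p_m$,
cross-products scaled by $2\sum_m p_m(1-p_m)$ over the markers called in
both samples of a pair. The matrix is symmetrized and eigenvalues floored
at 1e-8, so $2K$ is a valid covariance for the polygenic effect in the
mixed model. PCA is the SVD of the centered, unit-variance-scaled,
mean-imputed dosage matrix. The UPGMA tree is average-linkage clustering
of $1 - \mathrm{IBS}$, returned ultrametric with branch lengths equal to
half the merge heights (so the cophenetic distance between two tips equals
their merge-height distance).

## Runs of homozygosity

Detection is the sliding-window method: 20-SNP windows are homozygous when
they contain at most 0 heterozygous and 1 missing call; each SNP is scored
by the proportion of overlapping homozygous windows and enters a run when
that proportion exceeds 0.05; runs split at inter-SNP gaps above the gap
allowance and are kept when they span the class minimum length with at
least 20 SNPs. Window size, gap and the two length classes are the stated
parameters of the method; the het/miss allowances and the 0.05 proportion
are the conventional defaults of sliding-window ROH detection and are all
exposed. Run length is measured SNP-to-SNP (first to last SNP position),
matching marker-based length reporting.

The two classes target recent and ancient inbreeding: minimum lengths of
2% and 0.25% of the genome with 1 Mb and 100 kb gap allowances. With the
reference genome length of 208,184,300 bp these are 4,163,686 bp and
520,461 bp (the second is exactly an eighth of the first, up to rounding).
Per-sample inbreeding is $F = \sum \text{run length} / \text{genome
length}$; per-SNP frequencies count the fraction of samples whose runs
cover the SNP. Detection needs marker spacing well below the gap
allowance; on sparse maps (e.g. 50 kb spacing) short-class runs fragment
and the method is honestly uninformative, which is why the recovery
checks run on dense maps.

## LD decay

$r^2$ is the squared Pearson correlation of dosage vectors (composite LD,
appropriate for unphased array data) for all pairs within a 250 kb window
per chromosome, skipping pairs with fewer than 10 joint calls or a
constant vector. The decay curve is a loess fit (degree 1, span 0.1,
widened automatically only if the local fit is degenerate) evaluated on a
200-point grid; the decay distance is the first grid point where the
smoothed curve drops below $r^2 = 0.2$, scanning from zero. A curve that
never crosses is reported censored at the window bound. The first-crossing
convention is ours; the crossing rule is recorded in the output.

## BLUP and heritability

For traits scored over years, the model is $P_{ijk} = \mu + Y_i + G_j +
e_{ijk}$ with year fixed and genotype random, fitted by REML (`lme4`).
"Repetition within year" is ambiguous as a fixed effect; the default is
one level per year, with the year × repetition interaction available via
`year_rep = TRUE`, and the choice is recorded in the fit. Traits without a
year structure use $P_{jk} = \mu + G_j + e_{jk}$. The reported BLUP is the
mean fixed-effect value plus the genotype's shrunken random effect; the
genotype variance $\sigma^2_G$, residual variance $\sigma^2_\varepsilon$,
and mean observation count $n$ give broad-sense heritability
$h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_\varepsilon / n)$. Crack-out is
stored as the fraction $(NW - KW)/NW$ internally; percent is display only.

## Non-additive GWAS

Dosages are encoded per effect mode — additive $(1, 0, -1)$, dominant
$(1, 1, -1)$, recessive $(1, -1, -1)$, overdominant $(1, 0, 1)$ for
$(0, 1, 2)$ — so the dominant and recessive codes cover the two
orientations of a dominant–recessive interaction, and swapping the allele
labels maps each encoding to (minus) its partner without changing any
p-value. The association model is
$$Y = \mu + X\beta + Qv + Zu + \varepsilon,\qquad u \sim N(0,\, 2K V_g),$$
with $Y$ the BLUPs, $X$ the encoded marker, and the first $K-1$ columns of
$Q$ as fixed covariates under the Q and K+Q corrections (the last column
is dropped for the sum-to-one redundancy). Variance components are
estimated once under the null by REML via the eigendecomposition of $2K$
and reused for every marker (the P3D approximation, orders of magnitude
faster than per-marker REML and the default of the standard
implementations); each marker is then tested by generalized least squares
on its called subset with Wald t p-values. Under the Q-only correction the
covariance is the identity and the scan is ordinary regression — with an
identity kinship the mixed scan collapses to OLS exactly, which the tests
assert to 1e-8.

The correction (Q, K or K+Q) is chosen by closeness of the genomic
inflation factor $\lambda = \mathrm{median}(\chi^2)/0.4549$ to 1, with the
Kolmogorov–Smirnov distance to Uniform(0,1) as tie-breaker and the
canonical order Q, K, K+Q as the final tie rule. Significance is
Bonferroni at 5% over the dataset's marker count. Significant markers
within twice the chromosome's LD decay of each other share a peak (an
artifact decision that prevents double-counting one signal); the peak
maximum is the top SNP, ties broken toward the lower position.

The published workflow confirmed candidate associations by visual
inspection of the phenotype-by-genotype distribution; reproducibility
needs a computable rule, so the package instead computes, for the top
SNP, the regression R² of the BLUPs on each of the four encodings and
requires the argmax to equal the scanned encoding; otherwise the record is
flagged a false positive. VE is the simple-regression R² of the BLUPs on
the top SNP's encoding (BLUPs, not raw means, are the declared GWAS
phenotype, so they are also the VE response); the per-trait combined VE is
the R² of the joint regression on all confirmed top SNPs, which reduces
exactly to VE for a single QTL and can only grow as regressors are added.

## Candidate genes and enrichment

A QTL region is the top SNP position ± the chromosome's LD decay, clamped
to the chromosome. A gene belongs to the region when its gap to the
region is strictly below 2000 bp — the assumed regulatory reach — i.e. a
gene ending exactly 2000 bp before the region is excluded. Enrichment
takes the candidate genes' coexpression subnetwork (first neighbors by
default; the depth is a parameter since "coexpressing genes" does not fix
a depth), tests each term hypergeometrically against the background of
all annotated genes in the network, adjusts by Benjamini–Hochberg, and
flags top enriched terms at q < 0.05 annotating at least 2% of the
subnetwork's annotated genes (annotated-only is the denominator, the
stricter and better-defined choice).

## The synthetic-data generator

The generator emulates the study design the pipeline targets: $K$
ancestral populations (Balding–Nichols beta drift around shared
Uniform(0.1, 0.9) ancestral frequencies, divergence parameter in (0,1)),
admixed individuals with flat-Dirichlet ancestry, clonal copies with
per-genotype error, planted autozygous segments, independent 1% per-call
missingness, and phenotypes built from planted QTLs that use exactly the
scan's encodings, plus year effects, an optional kinship-structured
polygenic term, and Gaussian residuals. All randomness flows from one
seed through named per-component streams, so stages regenerate
independently and identical configurations are bit-identical.

LD is induced without coalescent machinery: each chromosome is split into
blocks of exponential mean length `ld_block_bp`, and each individual
draws, per block and haploid copy, a population of origin from its Q row
and then one haplotype from that population's block pool. The pool holds
4 haplotypes by default: within-block allelic $r^2$ then averages roughly
$1/(H-1) \approx 0.3$–0.5, and since two markers at distance $d$ share a
block with probability $e^{-d/L}$, the expected $r^2$ curve decays on the
scale of `ld_block_bp` and crosses 0.2 near it — the generator's decay
estimates track the block length, as the tests verify on a grid. A
consequence of pool sampling is that the frequencies individuals are
actually drawn from are the realized pool frequencies, not the
Balding–Nichols draws; the truth record therefore stores both (`freqs`
and `freqs_model`), and law-of-large-numbers checks compare empirical
frequencies to `freqs`.

The polygenic option scales the kinship-structured term so that its
variance is `polygenic_h2 / (1 - polygenic_h2)` times the residual
variance at the single-observation level; a `target_h2` design entry
instead derives the residual SD from the realized genetic variance so the
planted broad-sense heritability at $n$ observations is exact.

What the generator does *not* emulate: recombination maps and
coalescent genealogies (blocks are independent, so there is no long-range
LD and no background relatedness beyond population membership), strand
ambiguity of array calls, genotyping batch effects, non-Gaussian trait
distributions (bounded percentage traits are treated as Gaussian on the
analysis scale), and epistasis. Passing recovery tests on this generator
therefore demonstrates correctness of the estimators under their model
assumptions, not robustness to every artifact of real array data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on a
195-sample, 8-chromosome, 4000-marker synthetic study (structure,
clones, ROH, LD, BLUP, two-mode GWAS, candidate regions), with denser
single-chromosome maps (400–500 markers on 1–2 Mb) wherever a quantity —
ROH boundaries, LD decay — is only meaningful at high marker density, and
20-seed replicates for the stochastic recovery checks (heritability at
planted 0.5/0.9, QTL detection power by encoding, type-I calibration at
1000+ markers). These sizes were chosen as the smallest at which the
estimators operate in their intended regime. Numerical details: REML
grid-plus-Bracket optimization of the variance ratio on
$\log\delta \in [-10, 10]$; kinship eigenvalue floor 1e-8; ALS tolerance
1e-6; simplex projection by the sorted-cumulative-sum algorithm;
Bonferroni on the per-dataset marker count (not the per-encoding
informative subset).

## Known limitations

The admixture fit is a deterministic least-squares emulation of the
stochastic sparse-NMF estimators: same model class and model-choice logic,
but coefficients need not match any specific tool run-for-run. P3D holds
variance components fixed across markers, which slightly deflates
significance at very strong QTLs. Peak grouping by twice the LD decay is
a pragmatic rule, not an inference of causal-signal boundaries. The ROH
detector requires marker spacing well below the gap allowance, and the
enrichment background excludes unannotated genes by construction.
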