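# panelgwas

Population genomics and non-additive GWAS for SNP-array diversity panels of
clonally propagated crops (almond-style nut and tree-fruit collections).

Such panels share a common analysis path: genotype calls on a few hundred
accessions must be cleaned and de-duplicated (clonally propagated cultivars
circulate under many names), their genetic structure estimated, inbreeding
quantified, and genotype–phenotype associations scanned — where much of the
interesting variation is *non-additive* (dominant, recessive or
overdominant), which standard additive GWAS models miss. `panelgwas`
implements every stage of that path behind one consistent container, plus a
synthetic-data generator that plants known structure and QTL effects so each
stage can be validated by parameter recovery.

## What it computes

* **QC and clone detection** — the filtering cascade (sample call rate >
  0.82, SNP call rate > 0.90, MAF > 0.05, optional three-genotype-class and
  class-frequency > 0.05 criteria for association datasets), pairwise
  identity-by-state, and clonal groups as connected components at IBS >
  0.98.
* **Genetic structure** — ancestry coefficients `Q` by masked alternating
  least squares on the half-dosage matrix (`X/2 ≈ QG` with simplex-projected
  `Q`, best `K` by cross-entropy on held-out entries; samples with no
  coefficient above 0.60 are "admixed"); VanRaden additive kinship with
  eigenvalue flooring so `2K` is a valid polygenic covariance; PCA; UPGMA
  trees on `1 − IBS`.
* **Runs of homozygosity** — sliding 20-SNP-window detection at two length
  classes (2% and 0.25% of the genome: minimum lengths 4,163,686 bp and
  520,461 bp, gap allowances 1 Mb and 100 kb), per-sample inbreeding
  `F = Σ run length / genome length`, and per-SNP ROH coverage frequencies.
* **LD decay** — pairwise dosage `r²` within 250 kb windows per chromosome,
  loess-smoothed (span 0.1), decay distance at the first crossing below
  `r² = 0.2`.
* **BLUP and heritability** — REML mixed models with genotype random and
  year fixed (`P = μ + Y + G + e`, or intercept-only for unstructured
  traits), and broad-sense heritability `h² = σ²G / (σ²G + σ²ε/n)`.
* **Non-additive GWAS** — genotype encodings additive `(1, 0, −1)`,
  dominant `(1, 1, −1)`, recessive `(1, −1, −1)`, overdominant `(1, 0, 1)`
  for dosages `(0, 1, 2)`; the mixed model
  `Y = μ + Xβ + Qv + Zu + ε`, `u ~ N(0, 2K·Vg)`, fitted P3D-style (one
  EMMA-type REML under the null, GLS per marker) under corrections Q, K and
  K+Q; correction choice by closeness of λ to 1; Bonferroni calling; a
  quantitative mode-consistency check (encoding with the best class-means
  R² must match the scanned encoding) replacing visual true-positive
  inspection; VE and per-trait combined VE by simple and joint regression
  R².
* **Candidate genes** — QTL regions `top SNP ± LD decay`, gene overlap with
  a strict <2000 bp regulatory flank, coexpression-subnetwork
  hypergeometric enrichment with BH q < 0.05 and the ≥2% top-enriched-term
  rule.

## Worked example

```r
library(panelgwas)

cfg <- population_config(n_pops = 3, n_per_pop = 30, n_admixed = 6,
                         n_chrom = 2, snps_per_chrom = 150,
                         chrom_length_bp = 2e6, fst_like_divergence = 0.3,
                         clone_spec = list(list(source = "P1_01", n = 2,
                                                error_rate = 0)),
                         seed = 1)
sim <- simulate_genotypes(cfg)
sim$geno
#> genotype_matrix: 98 samples x 300 markers on 2 chromosome(s)
#>   missing calls: 0.93%

groups <- clone_groups(ibs_matrix(sim$geno),
                       rowSums(!is.na(sim$geno$calls)))
length(groups)          # the planted clonal group
#> [1] 1

fit <- estimate_admixture(sim$geno, K_range = 1:5, reps = 3, seed = 2)
fit
#> ancestry_fit: K = 3 (candidates: 1-5 )
#>   assignments: admixed=2, G1=34, G2=30, G3=32
```

The generator planted three ancestral populations with six admixed samples
and one clonal pair; the masked factorization selects `K = 3` by held-out
cross-entropy, assigns the pure samples to their groups and leaves flat-Q
samples admixed, and the IBS threshold recovers the clonal group. From
here, `compute_kinship()`, `fit_blup()`, `scan_association()` /
`call_qtls()` and `candidate_genes()` continue the pipeline; see the
vignette (`vignettes/panelgwas-methods.Rmd`) for the full model
descriptions.

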