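test_that("generator is deterministic and validates its config", {
  cfg <- population_config(n_pops = 2, n_per_pop = 10, n_chrom = 2,
                           snps_per_chrom = 50, chrom_length_bp = 1e6,
                           seed = 9)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1$geno$calls, s2$geno$calls)
  expect_identical(s1$truth$Q, s2$truth$Q)
  expect_error(population_config(fst_like_divergence = 0), "divergence")
  expect_error(population_config(
    chrom_length_bp = 1e6,
    roh_spec = list(list(sample = "P1_01", chrom = "chr1",
                         start = 9e5, length = 2e5))), "bounds")
})

test_that("without admixture every true Q row is one-hot", {
  cfg <- population_config(n_pops = 3, n_per_pop = 5, n_admixed = 0,
                           n_chrom = 1, snps_per_chrom = 30,
                           chrom_length_bp = 1e5, seed = 2)
  sim <- simulate_genotypes(cfg)
  expect_true(all(apply(sim$truth$Q, 1, function(q)
    sum(q == 1) == 1 && sum(q == 0) == ncol(sim$truth$Q) - 1)))
})

test_that("error-free clones are identical by state; IBS decays with error rate", {
  base <- list(n_pops = 1, n_per_pop = 8, n_chrom = 1, snps_per_chrom = 200,
               chrom_length_bp = 1e6, missing_rate = 0)
  cfg0 <- do.call(population_config, c(base, list(
    clone_spec = list(list(source = "P1_01", n = 1, error_rate = 0)),
    seed = 4)))
  sim0 <- simulate_genotypes(cfg0)
  ibs0 <- ibs_matrix(sim0$geno)["P1_01", "P1_01_clone1"]
  expect_equal(ibs0, 1)
  mean_ibs <- function(err) {
    mean(vapply(1:10, function(s) {
      cfg <- do.call(population_config, c(base, list(
        clone_spec = list(list(source = "P1_01", n = 1, error_rate = err)),
        seed = s)))
      sim <- simulate_genotypes(cfg)
      ibs_matrix(sim$geno)["P1_01", "P1_01_clone1"]
    }, numeric(1)))
  }
  m <- c(mean_ibs(0.01), mean_ibs(0.05), mean_ibs(0.2))
  expect_true(all(diff(m) < 0))
})

test_that("empirical population frequencies converge to the truth record", {
  cfg <- population_config(n_pops = 2, n_per_pop = 200, n_chrom = 1,
                           snps_per_chrom = 200, chrom_length_bp = 2e6,
                           fst_like_divergence = 0.1, missing_rate = 0,
                           seed = 1)
  sim <- simulate_genotypes(cfg)
  for (k in 1:2) {
    idx <- which(sim$truth$pop == paste0("G", k))
    emp <- colMeans(sim$geno$calls[idx, ]) / 2
    rms <- sqrt(mean((emp - sim$truth$freqs[k, ])^2))
    expect_lt(rms, 0.05)
  }
})

test_that("within-block marker pairs carry more LD than between-block pairs", {
  cfg <- population_config(n_pops = 1, n_per_pop = 300, n_chrom = 1,
                           snps_per_chrom = 250, chrom_length_bp = 1e6,
                           ld_block_bp = 20000, missing_rate = 0, seed = 6)
  sim <- simulate_genotypes(cfg)
  g <- sim$geno
  blocks <- sim$truth$block_of
  same <- c(); diff_b <- c()
  pos <- g$map$pos
  for (i in seq_len(ncol(g$calls) - 1)) for (j in (i + 1):ncol(g$calls)) {
    d <- pos[j] - pos[i]
    if (d > 30000) next
    r2 <- suppressWarnings(stats::cor(g$calls[, i], g$calls[, j])^2)
    if (is.na(r2)) next
    if (blocks[i] == blocks[j]) same <- c(same, r2) else diff_b <- c(diff_b, r2)
  }
  expect_gt(mean(same), mean(diff_b))
  expect_gt(mean(same), 0.15)
  expect_lt(mean(diff_b), 0.05)
})

test_that("planted autozygous segments contain no heterozygous calls", {
  cfg <- population_config(n_pops = 1, n_per_pop = 5, n_chrom = 1,
                           snps_per_chrom = 300, chrom_length_bp = 2e6,
                           missing_rate = 0,
                           roh_spec = list(list(sample = "P1_02",
                                                chrom = "chr1",
                                                start = 5e5, length = 1e6)),
                           seed = 13)
  sim <- simulate_genotypes(cfg)
  idx <- sim$geno$map$pos >= 5e5 & sim$geno$map$pos <= 15e5
  seg <- sim$geno$calls["P1_02", idx]
  expect_true(all(seg != 1L, na.rm = TRUE))
})

test_that("noise-free phenotypes reproduce the planted effect geometry", {
  g <- make_geno(rbind(s1 = rep(0L, 4), s2 = rep(1L, 4), s3 = rep(2L, 4)))
  des <- list(years = 1, reps = 1, year_effect_sd = 0, residual_sd = 0,
              polygenic_h2 = 0, mean = 10)
  add <- simulate_phenotypes(g, data.frame(marker = "M0001",
                                           mode = "additive", effect = 1),
                             des, seed = 1)
  v <- tapply(add$pheno$value, add$pheno$accession, mean)[c("s1", "s2", "s3")]
  expect_equal(as.numeric(diff(v)), c(-1, -1))  # adjacent classes 1 apart
  ov <- simulate_phenotypes(g, data.frame(marker = "M0001",
                                          mode = "overdominant", effect = 2),
                            des, seed = 1)
  w <- tapply(ov$pheno$value, ov$pheno$accession, mean)[c("s1", "s2", "s3")]
  expect_equal(unname(w["s1"]), unname(w["s3"]))  # homozygotes equal
  expect_false(isTRUE(all.equal(unname(w["s2"]), unname(w["s1"]))))
  expect_error(simulate_phenotypes(g, data.frame(marker = "M0001",
                                                 mode = "epistatic",
                                                 effect = 1), des, 1),
               "mode")
})

test_that("annotation fixture has the requested gene counts and planted module", {
  cfg <- population_config(n_pops = 1, n_per_pop = 4, n_chrom = 3,
                           snps_per_chrom = 20, chrom_length_bp = 1e6,
                           seed = 3)
  sim <- simulate_genotypes(cfg)
  fx1 <- make_annotation_fixture(sim$geno$map, genes_per_chrom = 1,
                                 terms = character(0), seed = 1)
  expect_equal(nrow(fx1$genes), 3)            # one gene per chromosome
  expect_equal(nrow(fx1$annotations), 0)
  fx <- make_annotation_fixture(sim$geno$map, genes_per_chrom = 40,
                                terms = c("T1", "T2"), seed = 2,
                                module_size = 30)
  expect_equal(nrow(fx$genes), 120)
  expect_true(all(fx$genes$start <= fx$genes$end))
  # genes on one chromosome do not overlap
  for (ch in unique(fx$genes$chrom)) {
    gg <- fx$genes[fx$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
  # the first term is strongly concentrated in the planted module
  t1 <- fx$annotations$gene[fx$annotations$term == "T1"]
  expect_gt(mean(fx$module %in% t1), 0.5)
  expect_lt(mean(setdiff(fx$genes$gene, fx$module) %in% t1), 0.2)
})
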