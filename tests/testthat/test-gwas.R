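test_that("the four encodings map dosages as defined", {
  expect_equal(encode_dosage(c(0L, 1L, 2L), "additive"), c(1, 0, -1))
  expect_equal(encode_dosage(c(0L, 1L, 2L), "dominant"), c(1, 1, -1))
  expect_equal(encode_dosage(c(0L, 1L, 2L), "recessive"), c(1, -1, -1))
  expect_equal(encode_dosage(c(0L, 1L, 2L), "overdominant"), c(1, 0, 1))
  expect_equal(encode_dosage(c(NA, 1L), "additive"), c(NA, 0))
  expect_error(encode_dosage(0L, "epistatic"), "unknown mode")
  # an all-heterozygous marker is non-informative under recessive coding
  g <- make_geno(cbind(rep(1L, 10), sample(0:2, 10, TRUE)))
  E <- encode_genotypes(g, "recessive")
  expect_false(attr(E, "informative")[1])
})

test_that("allele-swap involution: additive negates, dominant and recessive swap", {
  g <- sample(c(0:2, NA), 50, TRUE)
  swapped <- 2L - g
  expect_equal(encode_dosage(swapped, "additive"), -encode_dosage(g, "additive"))
  # dominant and recessive exchange roles (up to the sign, which cannot
  # change a p-value)
  expect_equal(encode_dosage(swapped, "dominant"), -encode_dosage(g, "recessive"))
  expect_equal(encode_dosage(swapped, "recessive"), -encode_dosage(g, "dominant"))
  expect_equal(encode_dosage(swapped, "overdominant"),
               encode_dosage(g, "overdominant"))
})

test_that("allele swap leaves scan p-values invariant", {
  g <- random_geno(60, 30, miss = 0.02, seed = 44)
  set.seed(1)
  y <- rnorm(60); names(y) <- g$samples
  Q1 <- matrix(1, 60, 1, dimnames = list(g$samples, "G1"))
  s1 <- scan_association(y, g, "additive", "Q", Q = Q1)
  gs <- g
  gs$calls <- 2L - gs$calls
  s2 <- scan_association(y, gs, "additive", "Q", Q = Q1)
  expect_equal(s1$minus_log10_p, s2$minus_log10_p, tolerance = 1e-10)
  expect_equal(s1$beta, -s2$beta, tolerance = 1e-10)
})

test_that("with identity kinship the mixed scan collapses to ordinary regression", {
  g <- random_geno(50, 40, miss = 0.03, seed = 55)
  set.seed(2)
  y <- rnorm(50) + 0.5 * encode_dosage(g$calls[, 5], "additive")
  y[is.na(y)] <- rnorm(sum(is.na(y)))
  names(y) <- g$samples
  idk <- diag(50)
  dimnames(idk) <- list(g$samples, g$samples)
  class(idk) <- c("kinship_matrix", "matrix")
  sK <- scan_association(y, g, "additive", "K", kinship = idk)
  for (j in seq_len(40)) {
    if (is.na(sK$minus_log10_p[j])) next
    p_ols <- oracle_ols_p(y, NULL, encode_dosage(g$calls[, j], "additive"))
    expect_equal(10^(-sK$minus_log10_p[j]), p_ols, tolerance = 1e-8)
  }
})

test_that("low-coverage and constant markers are skipped", {
  calls <- cbind(sample(0:2, 20, TRUE), sample(0:2, 20, TRUE))
  calls[1:10, 1] <- NA                     # 50% coverage
  g <- make_geno(calls)
  set.seed(3)
  y <- rnorm(20); names(y) <- g$samples
  Q1 <- matrix(1, 20, 1, dimnames = list(g$samples, "G1"))
  s <- scan_association(y, g, "additive", "Q", Q = Q1, min_coverage = 0.8)
  expect_true(is.na(s$minus_log10_p[1]))
  expect_false(is.na(s$minus_log10_p[2]))
})

test_that("a planted QTL is found by its matching encoding and confirmed", {
  cfg <- population_config(n_pops = 1, n_per_pop = 150, n_chrom = 2,
                           snps_per_chrom = 150, chrom_length_bp = 2e6,
                           missing_rate = 0.01, seed = 60)
  g <- filter_dataset(simulate_genotypes(cfg)$geno,
                      filter_spec(require_three_classes = TRUE))
  causal <- g$map$marker[25]
  sim <- simulate_phenotypes(
    g, data.frame(marker = causal, mode = "recessive", effect = 1.2),
    design = list(years = 3, reps = 2, year_effect_sd = 0.5,
                  residual_sd = 1.2, trait = "NW"), seed = 61)
  blup <- fit_blup(sim$pheno, "NW")$blup
  kin <- compute_kinship(g)
  scan <- scan_association(blup, g, "recessive", "K", kinship = kin)
  dec <- ld_decay(g)
  recs <- call_qtls(scan, blup, g, dec, trait = "NW")
  expect_gte(nrow(recs), 1)
  top <- recs[which.max(recs$minus_log10_p), ]
  expect_lt(abs(top$pos - g$map$pos[g$map$marker == causal]), 20000)
  expect_true(top$true_positive)
  expect_equal(top$mode, "recessive")
  expect_true(top$ve > 0 && top$ve <= 1)
})

test_that("correction selection scores lambda first and respects canonical order", {
  g <- random_geno(40, 50, seed = 70)
  set.seed(4)
  y <- rnorm(40); names(y) <- g$samples
  Q1 <- matrix(1, 40, 1, dimnames = list(g$samples, "G1"))
  s <- scan_association(y, g, "additive", "Q", Q = Q1)
  picked <- select_correction(list(Q = s, K = s, "K+Q" = s))
  expect_equal(picked$correction, "Q")    # identical scans: first canonical
  expect_error(select_correction(list(Q = s)), "two")
})

test_that("QTL calling applies the Bonferroni threshold strictly", {
  # 22928 markers -> -log10 threshold 5.66; 5.5 stays, 6.0 passes
  df <- data.frame(marker = c("m1", "m2"), chrom = "chr2",
                   pos = c(1e6, 5e6), beta = 1, se = 0.1,
                   minus_log10_p = c(5.5, 6.0), n_used = 100L)
  scan <- structure(df, class = c("gwas_scan", "data.frame"),
                    mode = "additive", correction = "Q", lambda = 1,
                    bonferroni = 0.05 / 22928, n_markers = 22928L)
  calls <- cbind(sample(0:2, 30, TRUE), sample(0:2, 30, TRUE))
  rownames(calls) <- sprintf("s%02d", 1:30)
  map <- data.frame(marker = c("m1", "m2"), chrom = "chr2",
                    pos = c(1e6, 5e6), a1 = "A", a2 = "G")
  colnames(calls) <- map$marker
  g <- genotype_matrix(calls, map)
  set.seed(5)
  y <- rnorm(30) + encode_dosage(calls[, 2], "additive")
  names(y) <- rownames(calls)
  recs <- call_qtls(scan, y, g, c(chr2 = 5000), trait = "NW")
  expect_equal(recs$marker, "m2")
})

test_that("naming and combined variance explained follow the joint regression", {
  cfg <- population_config(n_pops = 1, n_per_pop = 120, n_chrom = 2,
                           snps_per_chrom = 100, chrom_length_bp = 2e6,
                           missing_rate = 0, seed = 80)
  g <- filter_dataset(simulate_genotypes(cfg)$geno,
                      filter_spec(require_three_classes = TRUE))
  m1 <- g$map$marker[10]
  m2 <- g$map$marker[ncol(g$calls) - 10]   # other chromosome
  sim <- simulate_phenotypes(
    g, data.frame(marker = c(m1, m2), mode = c("additive", "dominant"),
                  effect = c(1, 1)),
    design = list(years = 2, reps = 2, residual_sd = 0.8,
                  year_effect_sd = 0, trait = "CRO"), seed = 81)
  blup <- fit_blup(sim$pheno, "CRO")$blup
  kin <- compute_kinship(g)
  dec <- ld_decay(g)
  recs <- rbind(
    call_qtls(scan_association(blup, g, "additive", "K", kinship = kin),
              blup, g, dec, trait = "CRO"),
    call_qtls(scan_association(blup, g, "dominant", "K", kinship = kin),
              blup, g, dec, trait = "CRO"))
  recs <- recs[recs$true_positive, ]
  out <- qtl_summary(recs, list(CRO = blup), g)
  expect_true(all(grepl("^qCRO", out$name)))
  conf <- out[out$true_positive, ]
  # CVE is shared within trait and at least the best single VE
  expect_true(all(abs(conf$cve - conf$cve[1]) < 1e-12))
  expect_gte(conf$cve[1] + 1e-12, max(conf$ve))
  # single confirmed QTL: CVE equals VE exactly
  one <- qtl_summary(recs[1, , drop = FALSE], list(CRO = blup), g)
  expect_equal(one$cve, one$ve)
})
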