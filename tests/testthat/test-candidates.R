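test_that("QTL regions are the decay-bounded symmetric interval", {
  qtl <- data.frame(chrom = "chr2", pos = 19131932)
  r <- define_region(qtl, c(chr2 = 6904))
  expect_equal(r$start, 19125028L)
  expect_equal(r$end, 19138836L)
  expect_equal(r$length_bp, 13809L)
  # clamped at the chromosome start
  r2 <- define_region(data.frame(chrom = "chr1", pos = 100), c(chr1 = 6000))
  expect_equal(r2$start, 1L)
  # zero decay: single position
  r3 <- define_region(data.frame(chrom = "chr1", pos = 500), c(chr1 = 0))
  expect_equal(r3$start, r3$end)
  expect_error(define_region(qtl, c(chr9 = 100)), "decay")
})

test_that("the 2000-bp regulatory flank uses strict gap semantics", {
  genes <- data.frame(gene = c("gA", "gB", "gC", "gD"), chrom = "chr1",
                      start = c(1000L, 6000L, 10500L, 20000L),
                      end = c(3000L, 7000L, 11000L, 21000L), strand = "+")
  region <- list(chrom = "chr1", start = 5000L, end = 12000L)
  hits <- genes_in_region(region, genes)
  # gA ends exactly 2000 bp before the region: gap not < 2000, excluded
  expect_false("gA" %in% hits$gene)
  expect_true(all(c("gB", "gC") %in% hits$gene))
  expect_false("gD" %in% hits$gene)
  # a gene ending 1999 bp before the region start is included
  genes$end[1] <- 3001L
  expect_true("gA" %in% genes_in_region(region, genes)$gene)
})

test_that("a region planted around a single gene returns exactly that gene", {
  cfg <- population_config(n_pops = 1, n_per_pop = 4, n_chrom = 2,
                           snps_per_chrom = 50, chrom_length_bp = 1e6,
                           seed = 90)
  sim <- simulate_genotypes(cfg)
  fx <- make_annotation_fixture(sim$geno$map, genes_per_chrom = 8,
                                terms = "T1", seed = 91,
                                gene_length_bp = 1500)
  target <- fx$genes[3, ]
  region <- list(chrom = target$chrom,
                 start = as.integer(target$start - 100),
                 end = as.integer(target$end + 100))
  hits <- genes_in_region(region, fx$genes, flank = 100)
  expect_equal(hits$gene, target$gene)
})

test_that("enrichment matches the hypergeometric tail and applies the TET rule", {
  # planted module with a strongly enriched term
  set.seed(7)
  genes <- sprintf("g%03d", 1:200)
  module <- genes[1:50]
  edges <- data.frame(gene1 = module, gene2 = c(module[-1], module[1]))
  edges <- rbind(edges, data.frame(gene1 = sample(genes[51:200], 150, TRUE),
                                   gene2 = sample(genes[51:200], 150, TRUE)))
  edges <- edges[edges$gene1 != edges$gene2, ]
  net <- igraph::simplify(igraph::graph_from_data_frame(edges,
                                                        directed = FALSE))
  ann <- rbind(data.frame(gene = module[1:40], term = "T1"),
               data.frame(gene = sample(genes[51:200], 8), term = "T1"),
               data.frame(gene = sample(genes, 30), term = "T2"))
  ann <- unique(ann)
  res <- enrich_subnetwork(module[1:5], net, ann,
                           background = igraph::V(net)$name)
  t1 <- res[res$term == "T1", ]
  expect_lt(t1$q, 0.05)
  expect_true(t1$tet)
  # direct hypergeometric tail sum as oracle
  p_direct <- sum(dhyper(t1$hits:t1$subnetwork_size, t1$bg_hits,
                         t1$bg_size - t1$bg_hits, t1$subnetwork_size))
  expect_equal(t1$p, p_direct, tolerance = 1e-12)
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("rare hits are never top enriched terms and empty inputs warn", {
  genes <- sprintf("g%03d", 1:250)
  edges <- data.frame(gene1 = genes[1:249], gene2 = genes[2:250])
  net <- igraph::graph_from_data_frame(edges, directed = FALSE)
  # term with a single subnetwork hit out of >200: below the 2% rule
  ann <- data.frame(gene = c(genes[1], sample(genes, 40)), term = "T1")
  ann <- unique(ann)
  query <- genes[seq(1, 249, by = 2)]
  res <- enrich_subnetwork(query, net, ann)
  small <- res[res$hits / res$subnetwork_size < 0.02, ]
  if (nrow(small)) expect_false(any(small$tet))
  expect_warning(r0 <- enrich_subnetwork("absent", net, ann), "no query")
  expect_equal(nrow(r0), 0)
})

test_that("enrichment p decreases as the hit count grows", {
  p_at <- vapply(c(5, 10, 20), function(k)
    phyper(k - 1, 40, 160, 50, lower.tail = FALSE), numeric(1))
  expect_true(all(diff(p_at) < 0))
  # same monotonicity through the package computation
  genes <- sprintf("g%03d", 1:200)
  ring <- data.frame(gene1 = genes[1:50], gene2 = c(genes[2:50], genes[1]))
  net <- igraph::graph_from_data_frame(ring, directed = FALSE)
  # same carrier count, different subnetwork overlap
  res_few <- enrich_subnetwork(genes[1:3], net,
                               data.frame(gene = genes[c(1, 100:123)],
                                          term = "T1"),
                               background = genes)
  res_many <- enrich_subnetwork(genes[1:3], net,
                                data.frame(gene = genes[c(1:3, 100:121)],
                                           term = "T1"),
                                background = genes)
  expect_equal(res_few$bg_hits, res_many$bg_hits)
  expect_lt(res_many$p, res_few$p)
})

test_that("candidate_genes ties regions, genes and enrichment together", {
  cfg <- population_config(n_pops = 1, n_per_pop = 4, n_chrom = 1,
                           snps_per_chrom = 60, chrom_length_bp = 1e6,
                           seed = 95)
  sim <- simulate_genotypes(cfg)
  fx <- make_annotation_fixture(sim$geno$map, genes_per_chrom = 20,
                                terms = c("T1", "T2"), seed = 96)
  net <- igraph::simplify(igraph::graph_from_data_frame(fx$edges,
                                                        directed = FALSE))
  recs <- data.frame(trait = "NW", mode = "recessive", correction = "Q",
                     marker = "m", chrom = "chr1",
                     pos = fx$genes$start[5] + 100,
                     minus_log10_p = 7.5, ve = 0.3, best_mode = "recessive",
                     true_positive = TRUE, name = "qNW1", cve = 0.3)
  out <- candidate_genes(recs, c(chr1 = 10000), fx$genes, net,
                         fx$annotations)
  expect_named(out, "qNW1")
  expect_gte(nrow(out$qNW1$genes), 1)
  # below the -log10 p gate nothing is analyzed
  recs$minus_log10_p <- 5
  expect_length(candidate_genes(recs, c(chr1 = 10000), fx$genes), 0)
})
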