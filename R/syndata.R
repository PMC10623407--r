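#' Configuration for the synthetic genotype generator
#'
#' Describes a study design of K ancestral populations with optional admixed
#' individuals, clonal duplicates and planted autozygous (run-of-homozygosity)
#' segments. Ancestral allele frequencies follow a Balding--Nichols drift
#' model; intra-chromosomal LD is induced by drawing each haplotype block
#' from a small per-population haplotype pool, giving kb-scale LD decay
#' controlled by `ld_block_bp`.
#'
#' @param n_pops number of ancestral populations (>= 1)
#' @param n_per_pop samples per population
#' @param n_admixed admixed samples (ancestry drawn from a flat Dirichlet)
#' @param n_chrom chromosomes (default 8)
#' @param snps_per_chrom markers per chromosome
#' @param chrom_length_bp physical chromosome length in bp
#' @param ld_block_bp mean haplotype-block length (bp); sets the LD decay
#'   scale
#' @param fst_like_divergence Balding--Nichols drift parameter in (0, 1)
#' @param haplotypes_per_pool haplotypes per population per block; smaller
#'   pools give stronger within-block LD
#' @param clone_spec list of `list(source =, n =, error_rate =)` entries;
#'   each adds `n` clonal copies of sample `source` with independent
#'   per-genotype error
#' @param roh_spec list of `list(sample =, chrom =, start =, length =)`
#'   entries; each forces the segment homozygous in that sample
#' @param missing_rate independent per-call missingness probability
#' @param seed integer seed; all generator randomness derives from it
#' @return A `population_config` list.
#' @export
population_config <- function(n_pops = 3, n_per_pop = 50, n_admixed = 0,
                              n_chrom = 8, snps_per_chrom = 100,
                              chrom_length_bp = 4e7, ld_block_bp = 6000,
                              fst_like_divergence = 0.15,
                              haplotypes_per_pool = 4,
                              clone_spec = list(), roh_spec = list(),
                              missing_rate = 0.01, seed = 1) {
  stopifnot(n_pops >= 1, n_per_pop >= 0, n_admixed >= 0, n_chrom >= 1,
            snps_per_chrom >= 1, chrom_length_bp >= snps_per_chrom,
            ld_block_bp > 0, haplotypes_per_pool >= 2,
            missing_rate >= 0, missing_rate < 1)
  if (fst_like_divergence <= 0 || fst_like_divergence >= 1)
    stop("fst_like_divergence must be in (0, 1)")
  for (r in roh_spec) {
    if (r$start < 1 || r$start + r$length - 1 > chrom_length_bp)
      stop("roh_spec segment outside chromosome bounds")
  }
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop,
                 n_admixed = n_admixed, n_chrom = n_chrom,
                 snps_per_chrom = snps_per_chrom,
                 chrom_length_bp = chrom_length_bp,
                 ld_block_bp = ld_block_bp,
                 fst_like_divergence = fst_like_divergence,
                 haplotypes_per_pool = haplotypes_per_pool,
                 clone_spec = clone_spec, roh_spec = roh_spec,
                 missing_rate = missing_rate, seed = seed),
            class = "population_config")
}

rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}

#' Simulate structured genotypes with known truth
#'
#' Generates a [genotype_matrix()] under the design in `config` together
#' with a truth record for parameter-recovery tests: the true ancestry
#' matrix Q, per-population allele frequencies, clone groups and planted
#' ROH intervals.
#'
#' Ancestral frequencies are Uniform(0.1, 0.9); each population drifts away
#' from them by Balding--Nichols beta sampling with parameter
#' `fst_like_divergence`. Chromosomes are partitioned into blocks of
#' exponential mean length `ld_block_bp`; each individual draws, per block
#' and per haploid copy, a population of origin from its Q row and then one
#' haplotype from that population's block pool, so markers within a block
#' are in LD while blocks are independent.
#'
#' @param config a [population_config()]
#' @return list with elements `geno` (a `genotype_matrix`) and `truth`
#'   (list: `Q` (true ancestry), `freqs` (per-population sampling
#'   frequencies realized in the haplotype pools, the frequencies that
#'   empirical data converge to), `freqs_model` (the Balding--Nichols
#'   draws the pools were built from), `pop`, `clone_groups`, `roh`,
#'   `block_of`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(stream_seed(config$seed, "genotypes"))
  K <- config$n_pops
  n_base <- K * config$n_per_pop + config$n_admixed
  if (n_base < 1) stop("design has no samples")
  H <- config$haplotypes_per_pool

  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  map <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(sample.int(config$chrom_length_bp, config$snps_per_chrom))
    data.frame(marker = sprintf("S%s_%d", sub("chr", "", ch), pos),
               chrom = ch, pos = pos, a1 = "A", a2 = "G",
               stringsAsFactors = FALSE)
  }))
  rownames(map) <- NULL
  M <- nrow(map)

  # Balding-Nichols drift around a shared ancestral frequency
  p_anc <- stats::runif(M, 0.1, 0.9)
  Fd <- config$fst_like_divergence
  freqs <- t(vapply(seq_len(K), function(k) {
    stats::rbeta(M, p_anc * (1 - Fd) / Fd, (1 - p_anc) * (1 - Fd) / Fd)
  }, numeric(M)))

  ids <- c(unlist(lapply(seq_len(K), function(k)
    sprintf("P%d_%02d", k, seq_len(config$n_per_pop)))),
    if (config$n_admixed > 0) sprintf("ADM_%02d", seq_len(config$n_admixed)))
  Q <- matrix(0, n_base, K, dimnames = list(ids, paste0("G", seq_len(K))))
  pop <- character(n_base)
  i <- 0
  for (k in seq_len(K)) for (j in seq_len(config$n_per_pop)) {
    i <- i + 1; Q[i, k] <- 1; pop[i] <- paste0("G", k)
  }
  if (config$n_admixed > 0) for (j in seq_len(config$n_admixed)) {
    i <- i + 1; Q[i, ] <- rdirichlet1(K); pop[i] <- "admixed"
  }

  # block structure per chromosome: exponential lengths, mean ld_block_bp
  block_of <- integer(M)
  nb <- 0L
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    bounds <- cumsum(stats::rexp(ceiling(config$chrom_length_bp /
                                           config$ld_block_bp) * 3 + 10,
                                 rate = 1 / config$ld_block_bp))
    block_of[idx] <- nb + findInterval(map$pos[idx], bounds) + 1L
    nb <- max(block_of[idx])
  }
  blocks <- unique(block_of)

  # per-sample, per-block, per-copy population of origin
  B <- length(blocks)
  origin <- array(0L, c(n_base, B, 2))
  for (s in seq_len(n_base))
    origin[s, , ] <- sample.int(K, 2L * B, replace = TRUE, prob = Q[s, ])

  G <- matrix(0L, n_base, M, dimnames = list(ids, map$marker))
  freqs_real <- matrix(NA_real_, K, M)
  for (b in seq_len(B)) {
    idx <- which(block_of == blocks[b])
    mb <- length(idx)
    pools <- lapply(seq_len(K), function(k)
      matrix(stats::rbinom(H * mb, 1L, rep(freqs[k, idx], each = H)), H, mb))
    for (k in seq_len(K)) freqs_real[k, idx] <- colMeans(pools[[k]])
    for (cp in 1:2) {
      o <- origin[, b, cp]
      h <- sample.int(H, n_base, replace = TRUE)
      hap <- matrix(0L, n_base, mb)
      for (k in seq_len(K)) {
        rows <- which(o == k)
        if (length(rows))
          hap[rows, ] <- pools[[k]][h[rows], , drop = FALSE]
      }
      G[, idx] <- G[, idx] + hap
    }
  }

  # planted autozygous segments (before cloning so clones inherit them)
  roh_truth <- list()
  for (r in config$roh_spec) {
    idx <- which(map$chrom == r$chrom & map$pos >= r$start &
                   map$pos <= r$start + r$length - 1)
    het <- idx[G[r$sample, idx] == 1L]
    if (length(het))
      G[r$sample, het] <- 2L * stats::rbinom(length(het), 1L, 0.5)
    roh_truth[[length(roh_truth) + 1]] <-
      data.frame(sample = r$sample, chrom = r$chrom, start = r$start,
                 end = r$start + r$length - 1, stringsAsFactors = FALSE)
  }
  roh_truth <- if (length(roh_truth)) do.call(rbind, roh_truth) else NULL

  # clonal copies with per-genotype error
  clone_groups <- list()
  for (cs in config$clone_spec) {
    if (!cs$source %in% ids) stop("clone source not found: ", cs$source)
    members <- cs$source
    for (j in seq_len(cs$n)) {
      g <- G[cs$source, ]
      if (cs$error_rate > 0) {
        err <- which(stats::runif(M) < cs$error_rate)
        if (length(err))
          g[err] <- (g[err] + sample.int(2L, length(err), replace = TRUE)) %% 3L
      }
      id <- sprintf("%s_clone%d", cs$source, j)
      G <- rbind(G, g)
      rownames(G)[nrow(G)] <- id
      Q <- rbind(Q, Q[cs$source, ])
      rownames(Q)[nrow(Q)] <- id
      pop <- c(pop, pop[match(cs$source, ids)])
      members <- c(members, id)
    }
    clone_groups[[length(clone_groups) + 1]] <- members
  }
  ids <- rownames(G)

  if (config$missing_rate > 0)
    G[stats::runif(length(G)) < config$missing_rate] <- NA_integer_

  list(geno = genotype_matrix(G, map),
       truth = list(Q = Q, freqs = freqs_real, freqs_model = freqs,
                    pop = pop, clone_groups = clone_groups, roh = roh_truth,
                    block_of = block_of, p_anc = p_anc))
}

#' Simulate phenotypes from planted QTLs
#'
#' Each observation is `mean + sum(encoded genotype x effect) + polygenic +
#' year effect + residual`, replicated over `years x reps`. QTL action uses
#' exactly the genotype encodings of [encode_genotypes()], so a QTL planted
#' as e.g. overdominant is detectable by the overdominant scan. A missing
#' genotype contributes zero to the genetic value.
#'
#' @param geno a [genotype_matrix()]
#' @param qtls data.frame with columns `marker`, `mode`, `effect` (and
#'   optionally `trait`); modes are `additive`, `dominant`, `recessive`,
#'   `overdominant`
#' @param design list with elements `years`, `reps`, `year_effect_sd`,
#'   `residual_sd`, `polygenic_h2`, `mean`, `trait`, and optionally
#'   `target_h2`. If `target_h2` is given, `residual_sd` is derived so the
#'   planted broad-sense heritability at `n = years * reps` observations
#'   equals it.
#' @param seed integer seed
#' @return list with `pheno` (a `phenotype_table`) and `truth` (genetic
#'   values, variance components, year effects).
#' @export
simulate_phenotypes <- function(geno, qtls, design = list(), seed = 1) {
  d <- utils::modifyList(list(years = 3, reps = 2, year_effect_sd = 1,
                              residual_sd = 1, polygenic_h2 = 0, mean = 10,
                              trait = "TRAIT", target_h2 = NULL), design)
  stopifnot(d$years >= 1, d$reps >= 1, d$year_effect_sd >= 0,
            d$residual_sd >= 0, d$polygenic_h2 >= 0, d$polygenic_h2 < 1)
  qtls <- as.data.frame(qtls)
  if (!all(qtls$marker %in% geno$map$marker))
    stop("QTL marker not present in the map")
  if (!all(qtls$mode %in% gwas_modes()))
    stop("unknown QTL mode; must be one of ", paste(gwas_modes(), collapse = ", "))
  set.seed(stream_seed(seed, "phenotypes"))
  n <- nrow(geno$calls)
  ids <- geno$samples

  g <- numeric(n)
  for (r in seq_len(nrow(qtls))) {
    code <- encode_dosage(geno$calls[, qtls$marker[r]], qtls$mode[r])
    code[is.na(code)] <- 0
    g <- g + code * qtls$effect[r]
  }

  if (d$polygenic_h2 > 0) {
    Kmat <- compute_kinship(geno)
    L <- chol(2 * unclass(Kmat) + diag(1e-6, n))
    u <- drop(t(L) %*% stats::rnorm(n))
    vp <- d$residual_sd^2 * d$polygenic_h2 / (1 - d$polygenic_h2)
    u <- u / stats::sd(u) * sqrt(vp)
    g <- g + u
  }

  n_obs <- d$years * d$reps
  if (!is.null(d$target_h2)) {
    vg <- stats::var(g)
    if (vg == 0) stop("cannot target h2 with zero genetic variance")
    d$residual_sd <- sqrt(vg * n_obs * (1 - d$target_h2) / d$target_h2)
  }
  year_eff <- stats::rnorm(d$years, 0, d$year_effect_sd)

  rows <- expand.grid(rep = seq_len(d$reps), year = seq_len(d$years),
                      accession = ids, stringsAsFactors = FALSE)
  value <- d$mean + g[match(rows$accession, ids)] + year_eff[rows$year] +
    stats::rnorm(nrow(rows), 0, d$residual_sd)
  pheno <- phenotype_table(data.frame(
    accession = rows$accession, trait = d$trait,
    year = 2000L + rows$year, rep = rows$rep, value = value,
    stringsAsFactors = FALSE))
  list(pheno = pheno,
       truth = list(genetic_values = stats::setNames(g, ids),
                    var_g = stats::var(g), residual_sd = d$residual_sd,
                    year_effects = year_eff, n_obs = n_obs,
                    h2 = stats::var(g) / (stats::var(g) +
                                            d$residual_sd^2 / n_obs)))
}

#' Generate a gene annotation, coexpression network and term fixture
#'
#' Places non-overlapping genes along each chromosome of a marker map,
#' builds a coexpression graph with one densely connected planted module,
#' and annotates terms so that the first term is strongly enriched inside
#' the module against a low background rate.
#'
#' @param marker_map the `map` of a [genotype_matrix()] (defines chromosome
#'   names and lengths)
#' @param genes_per_chrom genes per chromosome (>= 1)
#' @param terms character vector of term ids; may be empty
#' @param seed integer seed
#' @param gene_length_bp gene length in bp
#' @param module_size genes in the planted coexpression module
#' @param module_term_rate fraction of module genes carrying the first term
#' @param background_term_rate background annotation rate for every term
#' @return list with `genes` (data.frame as [read_annotation()]), `edges`
#'   (two-column data.frame), `annotations` (data.frame `gene`, `term`),
#'   and `module` (gene ids of the planted module).
#' @export
make_annotation_fixture <- function(marker_map, genes_per_chrom, terms,
                                    seed = 1, gene_length_bp = 2000,
                                    module_size = 50,
                                    module_term_rate = 0.8,
                                    background_term_rate = 0.05) {
  stopifnot(genes_per_chrom >= 1)
  set.seed(stream_seed(seed, "fixtures"))
  chroms <- unique(marker_map$chrom)
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    L <- max(marker_map$pos[marker_map$chrom == ch])
    if (L <= 0) stop("zero chromosome length")
    span <- max(L - gene_length_bp, genes_per_chrom)
    starts <- unique(floor(seq(1, span, length.out = genes_per_chrom)))
    len <- min(gene_length_bp, max(1, floor(diff(c(starts, L))[1] / 2)))
    data.frame(gene = sprintf("GENE_%s_%03d", ch, seq_along(starts)),
               chrom = ch, start = starts, end = starts + len - 1,
               strand = "+", stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  if (any(genes$start > genes$end)) stop("degenerate gene interval")

  n_genes <- nrow(genes)
  module <- genes$gene[seq_len(min(module_size, n_genes))]
  rest <- setdiff(genes$gene, module)
  # dense planted module: ring for connectivity plus random chords
  ring <- if (length(module) > 1)
    cbind(module, c(module[-1], module[1])) else NULL
  chord_pairs <- if (length(module) > 2) t(utils::combn(module, 2)) else NULL
  chords <- if (!is.null(chord_pairs))
    chord_pairs[stats::runif(nrow(chord_pairs)) < 0.3, , drop = FALSE]
  else NULL
  bg <- if (length(rest) > 1) {
    m_bg <- 2L * length(rest)
    cbind(sample(rest, m_bg, replace = TRUE),
          sample(genes$gene, m_bg, replace = TRUE))
  } else NULL
  edges <- rbind(ring, chords, bg)
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  edges <- as.data.frame(unique(edges), stringsAsFactors = FALSE)
  names(edges) <- c("gene1", "gene2")

  ann <- NULL
  if (length(terms)) {
    recs <- list()
    for (ti in seq_along(terms)) {
      carriers <- genes$gene[stats::runif(n_genes) < background_term_rate]
      if (ti == 1) {
        planted <- module[stats::runif(length(module)) < module_term_rate]
        carriers <- union(carriers, planted)
      }
      if (length(carriers))
        recs[[length(recs) + 1]] <- data.frame(gene = carriers,
                                               term = terms[ti],
                                               stringsAsFactors = FALSE)
    }
    ann <- if (length(recs)) do.call(rbind, recs) else
      data.frame(gene = character(), term = character())
  } else {
    ann <- data.frame(gene = character(), term = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(ann) <- NULL
  list(genes = genes, edges = edges, annotations = ann, module = module)
}
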