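#' Define a QTL region from the top SNP and the LD decay
#'
#' The region is the symmetric interval `[top SNP - decay, top SNP +
#' decay]` (1-based inclusive), clamped to the chromosome bounds.
#'
#' @param qtl one `qtl_record` row (needs `chrom`, `pos`)
#' @param decay per-chromosome decay: data.frame from [ld_decay()] or named
#'   vector of `decay_bp`
#' @param chrom_length_bp optional named vector of chromosome lengths for
#'   right clamping
#' @return list with `chrom`, `start`, `end`, `length_bp`, `qtl`.
#' @export
define_region <- function(qtl, decay, chrom_length_bp = NULL) {
  if (is.data.frame(decay))
    decay <- stats::setNames(decay$decay_bp, decay$chrom)
  ch <- as.character(qtl$chrom)
  d <- decay[ch]
  if (is.null(d) || is.na(d)) stop("no LD decay estimate for ", ch)
  start <- max(1, qtl$pos - round(d))
  end <- qtl$pos + round(d)
  if (!is.null(chrom_length_bp) && !is.na(chrom_length_bp[ch]))
    end <- min(end, chrom_length_bp[ch])
  list(chrom = ch, start = as.integer(start), end = as.integer(end),
       length_bp = as.integer(end - start + 1), qtl = qtl)
}

#' Genes in (or regulatory-adjacent to) a QTL region
#'
#' A gene belongs to the region when its gap to the region is strictly less
#' than `flank` bp (default 2000, the assumed regulatory reach), i.e. the
#' gene overlaps the open interval `(start - flank, end + flank)`.
#'
#' @param region list from [define_region()]
#' @param genes gene table from [read_annotation()]
#' @param flank regulatory flank in bp
#' @return The rows of `genes` inside or within `flank` of the region.
#' @export
genes_in_region <- function(region, genes, flank = 2000) {
  hit <- genes$chrom == region$chrom &
    genes$end > region$start - flank &
    genes$start < region$end + flank
  genes[hit, , drop = FALSE]
}

#' Coexpression-subnetwork term enrichment
#'
#' Extracts the coexpression subnetwork of the query genes (the genes plus
#' their graph neighbors up to `depth` steps), then tests every annotation
#' term for over-representation among the subnetwork's annotated genes with
#' a hypergeometric test against the background (by default all annotated
#' genes present in the network). P-values are Benjamini-Hochberg adjusted;
#' terms with q < 0.05 that annotate at least `tet_fraction` (default 2%)
#' of the subnetwork's annotated genes are flagged top enriched terms
#' (TET).
#'
#' @param query_genes character vector of candidate gene ids
#' @param network \pkg{igraph} graph from [read_network()]
#' @param annotations data.frame with columns `gene`, `term`
#' @param background optional character vector; defaults to all annotated
#'   genes in the network
#' @param depth neighborhood order for the subnetwork (default 1 = first
#'   neighbors)
#' @param q_threshold significance threshold on the BH q-value
#' @param tet_fraction minimum annotated fraction for the TET flag
#' @return data.frame with `term`, `hits`, `subnetwork_size`, `bg_hits`,
#'   `bg_size`, `p`, `q`, `tet`, sorted by p; empty (with a warning) if the
#'   subnetwork has no annotated gene.
#' @export
enrich_subnetwork <- function(query_genes, network, annotations,
                              background = NULL, depth = 1,
                              q_threshold = 0.05, tet_fraction = 0.02) {
  empty <- data.frame(term = character(), hits = integer(),
                      subnetwork_size = integer(), bg_hits = integer(),
                      bg_size = integer(), p = numeric(), q = numeric(),
                      tet = logical(), stringsAsFactors = FALSE)
  present <- intersect(query_genes, igraph::V(network)$name)
  if (!length(present)) {
    warning("no query gene present in the network")
    return(empty)
  }
  nb <- igraph::ego(network, order = depth,
                    nodes = present, mode = "all")
  subnet <- unique(c(present, unlist(lapply(nb, names))))
  if (is.null(background))
    background <- intersect(unique(annotations$gene),
                            igraph::V(network)$name)
  sub_ann <- intersect(subnet, background)
  if (!length(sub_ann) || !nrow(annotations)) {
    if (!length(sub_ann)) warning("subnetwork contains no annotated gene")
    return(empty)
  }
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  N <- length(background)
  n_s <- length(sub_ann)
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    carriers <- unique(ann$gene[ann$term == tm])
    k <- length(intersect(carriers, sub_ann))
    Kbg <- length(carriers)
    p <- stats::phyper(k - 1, Kbg, N - Kbg, n_s, lower.tail = FALSE)
    data.frame(term = tm, hits = k, subnetwork_size = n_s, bg_hits = Kbg,
               bg_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$tet <- out$q < q_threshold & out$hits / out$subnetwork_size >= tet_fraction
  out[order(out$p), , drop = FALSE]
}

#' Candidate-gene analysis for a set of called QTLs
#'
#' For each QTL record, defines the LD-bounded region, collects genes in or
#' near it, and (when a network and annotations are supplied) runs the
#' coexpression enrichment of the candidate genes.
#'
#' @param records `qtl_record` rows, typically from [qtl_summary()]
#' @param decay per-chromosome decay (see [define_region()])
#' @param genes gene table from [read_annotation()]
#' @param network optional \pkg{igraph} graph
#' @param annotations optional data.frame `gene`, `term`
#' @param flank regulatory flank in bp
#' @param min_log10p only QTLs above this -log10 p enter the analysis
#'   (default 6.5)
#' @return list of per-QTL results: `region`, `genes`, and `enrichment`
#'   (NULL when no network is given).
#' @export
candidate_genes <- function(records, decay, genes, network = NULL,
                            annotations = NULL, flank = 2000,
                            min_log10p = 6.5) {
  keep <- records$true_positive & records$minus_log10_p > min_log10p
  out <- list()
  for (i in which(keep)) {
    region <- define_region(records[i, ], decay)
    hits <- genes_in_region(region, genes, flank)
    enr <- NULL
    if (!is.null(network) && !is.null(annotations) && nrow(hits))
      enr <- enrich_subnetwork(hits$gene, network, annotations)
    out[[records$name[i] %||% records$marker[i]]] <-
      list(region = region, genes = hits, enrichment = enr)
  }
  out
}
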