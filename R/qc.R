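#' Genotype filtering thresholds
#'
#' The standard SNP-array filtering cascade: sample call rate, SNP call
#' rate, minor-allele frequency, and (for association datasets) the
#' requirement that a marker shows all three genotypic classes, each above a
#' minimum class frequency. All "higher than" thresholds are strict (`>`).
#'
#' @param min_sample_call_rate samples must be called at more than this
#'   fraction of markers (default 0.82)
#' @param min_snp_call_rate markers must be called in more than this
#'   fraction of surviving samples (default 0.90)
#' @param min_maf minor-allele frequency must exceed this (default 0.05)
#' @param require_three_classes require all three genotypic classes present
#' @param min_class_freq with `require_three_classes`, every class frequency
#'   must exceed this (default 0.05)
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(min_sample_call_rate = 0.82,
                        min_snp_call_rate = 0.90,
                        min_maf = 0.05,
                        require_three_classes = FALSE,
                        min_class_freq = 0.05) {
  vals <- c(min_sample_call_rate, min_snp_call_rate, min_maf, min_class_freq)
  if (any(vals < 0 | vals > 1)) stop("filter rates must be in [0, 1]")
  structure(list(min_sample_call_rate = min_sample_call_rate,
                 min_snp_call_rate = min_snp_call_rate,
                 min_maf = min_maf,
                 require_three_classes = require_three_classes,
                 min_class_freq = min_class_freq),
            class = "filter_spec")
}

#' Apply the filtering cascade to a genotype matrix
#'
#' Samples below the call-rate cut are removed first; the SNP-level filters
#' (call rate, MAF, and optionally three-classes / class frequency) are then
#' computed on the surviving samples. Filtering is idempotent: re-filtering
#' a filtered dataset removes nothing.
#'
#' @param geno a [genotype_matrix()]
#' @param spec a [filter_spec()]
#' @return The filtered `genotype_matrix`, with a `"report"` attribute
#'   listing per-step removal counts.
#' @export
filter_dataset <- function(geno, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (nrow(geno$calls) == 0 || ncol(geno$calls) == 0) stop("empty matrix")
  report <- list(input_samples = nrow(geno$calls),
                 input_snps = ncol(geno$calls))

  cr_sample <- rowMeans(!is.na(geno$calls))
  keep_s <- cr_sample > spec$min_sample_call_rate
  report$samples_removed_call_rate <- sum(!keep_s)
  geno <- subset_genotypes(geno, samples = keep_s)
  if (nrow(geno$calls) == 0) stop("all samples removed by call-rate filter")

  cr_snp <- colMeans(!is.na(geno$calls))
  keep <- cr_snp > spec$min_snp_call_rate
  report$snps_removed_call_rate <- sum(!keep)
  geno <- subset_genotypes(geno, markers = keep)

  keep <- maf(geno) > spec$min_maf
  keep[is.na(keep)] <- FALSE
  report$snps_removed_maf <- sum(!keep)
  geno <- subset_genotypes(geno, markers = keep)

  if (spec$require_three_classes) {
    cls <- apply(geno$calls, 2, function(g) {
      g <- g[!is.na(g)]
      tab <- tabulate(g + 1L, 3L) / length(g)
      sum(tab > 0) == 3L && all(tab > spec$min_class_freq)
    })
    report$snps_removed_class <- sum(!cls)
    geno <- subset_genotypes(geno, markers = cls)
  }
  report$output_samples <- nrow(geno$calls)
  report$output_snps <- ncol(geno$calls)
  attr(geno, "report") <- report
  geno
}

#' Assemble an analysis dataset by subsetting then re-filtering
#'
#' Subsets a full genotype matrix to the requested samples (e.g. the
#' landraces for structure analysis, or the phenotyped accessions for a
#' GWAS) and re-applies the filtering cascade on the subset, optionally
#' with the association-specific three-class / class-frequency criteria.
#'
#' @param geno the full (already filtered) [genotype_matrix()]
#' @param sample_ids samples to keep
#' @param spec a [filter_spec()]; for GWAS datasets pass one with
#'   `require_three_classes = TRUE`
#' @return The filtered subset, with the filtering report attached.
#' @export
assemble_dataset <- function(geno, sample_ids, spec = filter_spec()) {
  filter_dataset(subset_genotypes(geno, samples = sample_ids), spec)
}

#' Pairwise identity-by-state matrix
#'
#' IBS between two samples is the fraction of markers, among those called
#' in both, where the genotype calls are identical. Pairs with no jointly
#' called marker are `NA`.
#'
#' @param geno a [genotype_matrix()] with at least two samples
#' @return Symmetric samples x samples matrix with unit diagonal.
#' @export
ibs_matrix <- function(geno) {
  if (nrow(geno$calls) < 2) stop("need at least two samples")
  X <- geno$calls
  called <- !is.na(X)
  eq <- matrix(0, nrow(X), nrow(X))
  for (g in 0:2) {
    Ig <- (X == g) & called
    mode(Ig) <- "numeric"
    eq <- eq + tcrossprod(Ig)
  }
  joint <- tcrossprod(called * 1)
  ibs <- eq / joint
  ibs[joint == 0] <- NA_real_
  diag(ibs) <- 1
  dimnames(ibs) <- list(geno$samples, geno$samples)
  ibs
}

#' Detect clonal groups from an IBS matrix
#'
#' Samples whose pairwise IBS is strictly greater than `threshold` are
#' linked; clonal groups are the connected components with two or more
#' members. Within each group the representative is the member with the
#' most non-missing calls.
#'
#' @param ibs symmetric IBS matrix (as from [ibs_matrix()])
#' @param n_called named vector: non-missing call count per sample (e.g.
#'   `rowSums(!is.na(geno$calls))`)
#' @param threshold strict IBS threshold (default 0.98)
#' @return list of `clone_group` lists with elements `members` and
#'   `representative`.
#' @export
clone_groups <- function(ibs, n_called, threshold = 0.98) {
  stopifnot(is.matrix(ibs), nrow(ibs) == ncol(ibs))
  adj <- !is.na(ibs) & ibs > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    members <- rownames(ibs)[comp$membership == ci]
    if (length(members) < 2) next
    rep_id <- members[which.max(n_called[members])]
    out[[length(out) + 1]] <- structure(
      list(members = members, representative = rep_id),
      class = "clone_group")
  }
  out
}
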