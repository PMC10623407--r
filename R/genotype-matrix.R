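#' Construct a genotype matrix
#'
#' The package-wide container for biallelic SNP calls: a samples x markers
#' matrix of alt-allele dosages (0 = a1a1, 1 = a1a2, 2 = a2a2, `NA` =
#' missing) together with a marker map giving chromosome, 1-based physical
#' position and the two alleles of each marker.
#'
#' @param calls integer matrix, samples in rows, markers in columns; values
#'   in \{0, 1, 2, NA\}. Row names are sample ids, column names marker ids.
#' @param map data.frame with columns `marker`, `chrom`, `pos` (1-based bp),
#'   `a1` (reference allele), `a2` (alternate allele), one row per column of
#'   `calls`, in the same order.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `samples`, and `map`.
#' @export
genotype_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) stop("calls must have sample ids as rownames")
  if (is.null(colnames(calls))) colnames(calls) <- map$marker
  stopifnot(is.data.frame(map),
            all(c("marker", "chrom", "pos", "a1", "a2") %in% names(map)),
            ncol(calls) == nrow(map))
  if (!identical(colnames(calls), as.character(map$marker)))
    stop("marker ids in calls and map disagree")
  if (anyDuplicated(map$marker)) stop("duplicate marker id")
  if (anyDuplicated(rownames(calls))) stop("duplicate sample id")
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch,
           "; sort markers by (chrom, pos) first")
  }
  structure(list(calls = calls, samples = rownames(calls), map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or markers
#'
#' @param geno a `genotype_matrix`
#' @param samples character or logical/integer index of samples to keep
#' @param markers character or logical/integer index of markers to keep
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(geno, samples = NULL, markers = NULL) {
  calls <- geno$calls
  map <- geno$map
  if (!is.null(samples)) calls <- calls[samples, , drop = FALSE]
  if (!is.null(markers)) {
    calls <- calls[, markers, drop = FALSE]
    keep <- match(colnames(calls), map$marker)
    map <- map[keep, , drop = FALSE]
    rownames(map) <- NULL
  }
  genotype_matrix(calls, map)
}

#' Per-marker alt-allele frequency
#'
#' Computed on called genotypes only, as mean alt dosage / 2.
#'
#' @param geno a `genotype_matrix`
#' @return Numeric vector of alt-allele frequencies, one per marker.
#' @export
allele_freq <- function(geno) {
  colMeans(geno$calls, na.rm = TRUE) / 2
}

#' Minor allele frequency per marker
#'
#' Alt-allele frequency folded to be at most 0.5.
#'
#' @inheritParams allele_freq
#' @return Numeric vector of minor-allele frequencies.
#' @export
maf <- function(geno) {
  p <- allele_freq(geno)
  pmin(p, 1 - p)
}
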