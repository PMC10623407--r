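#' Read genotypes from VCF or a TSV dosage matrix
#'
#' VCF input (v4.x, GT field only; phased and unphased treated identically)
#' is parsed with \pkg{vcfR}. Multiallelic records are rejected. The TSV
#' dialect is the one written by [write_genotypes()]: columns `marker`,
#' `chrom`, `pos`, `a1`, `a2`, then one column per sample holding alt-allele
#' dosages (0/1/2, empty or NA for missing).
#'
#' @param path file to read
#' @param format `"vcf"` or `"tsv"`
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multiallelic sites are not supported; split or drop them first")
  gt <- vcfR::extract.gt(v, element = "GT")
  # gt: markers x samples character; count alt alleles in GT
  dos <- gt_to_dosage(gt)
  map <- data.frame(marker = if (all(is.na(fix[, "ID"])) ||
                                 any(fix[, "ID"] %in% c(".", NA)))
                      paste0(fix[, "CHROM"], "_", fix[, "POS"])
                    else fix[, "ID"],
                    chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    a1 = fix[, "REF"], a2 = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$marker)) stop("duplicate marker id in VCF")
  genotype_matrix(t(dos), map)
}

gt_to_dosage <- function(gt) {
  u <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[u %in% c("0/0")] <- 0L
  dos[u %in% c("0/1", "1/0")] <- 1L
  dos[u %in% c("1/1")] <- 2L
  known <- is.na(u) | u %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  if (!all(known)) stop("unparseable GT value: ", u[!known][1])
  dos
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("marker", "chrom", "pos", "a1", "a2")
  if (!all(fixed %in% names(tab)))
    stop("dosage TSV must have columns ", paste(fixed, collapse = ", "))
  map <- tab[fixed]
  calls <- t(as.matrix(tab[setdiff(names(tab), fixed)]))
  colnames(calls) <- map$marker
  genotype_matrix(calls, map)
}

#' Write genotypes to VCF or TSV
#'
#' The VCF writer emits a minimal deterministic VCFv4.2 file (GT field only,
#' unphased, missing as `./.`); the TSV writer emits the dosage-matrix
#' dialect read back by [read_genotypes()]. Writing then reading either
#' format round-trips calls, ids and map exactly.
#'
#' @param geno a [genotype_matrix()]
#' @param path output file
#' @param format `"vcf"` or `"tsv"`
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- cbind(geno$map, as.data.frame(t(geno$calls), check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    return(invisible(path))
  }
  gt <- matrix(c("0/0", "0/1", "1/1")[geno$calls + 1L],
               nrow(geno$calls), ncol(geno$calls))
  gt[is.na(gt)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste0(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$samples), collapse = "\t"))
  body <- paste(geno$map$chrom, geno$map$pos, geno$map$marker, geno$map$a1,
                geno$map$a2, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read gene records from a GFF3 annotation
#'
#' Only features of type `gene` are retained; coordinates stay 1-based
#' inclusive as in the file.
#'
#' @param path GFF3 file
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 9))
    stop("malformed GFF3 record at line ", which(nf != 9)[1])
  f <- do.call(rbind, f)
  keep <- f[, 3] == "gene"
  f <- f[keep, , drop = FALSE]
  start <- suppressWarnings(as.integer(f[, 4]))
  end <- suppressWarnings(as.integer(f[, 5]))
  if (anyNA(start) || anyNA(end))
    stop("malformed coordinate at line ", which(keep)[which(is.na(start) | is.na(end))][1])
  id <- sub("^.*ID=([^;]+).*$", "\\1", f[, 9])
  out <- data.frame(gene = id, chrom = f[, 1], start = start, end = end,
                    strand = f[, 7], stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("gene with start > end")
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Read a coexpression network from a two-column edge list
#'
#' Returns an undirected simple graph; self-loops and duplicate edges are
#' dropped (with a warning for self-loops).
#'
#' @param path TSV file with two columns of gene ids (no header required;
#'   a header line is detected if the first row repeats in no edge)
#' @param header logical, does the file have a header line
#' @return an \pkg{igraph} undirected graph
#' @export
read_network <- function(path, header = FALSE) {
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("edge list must have two columns")
  edges <- tab[, 1:2]
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Read a long-format phenotype table
#'
#' @param path CSV with columns `accession`, `trait`, `year`, `rep`, `value`
#' @param traits allowed trait names; any other trait name is a validation
#'   error reporting the offending row
#' @return data.frame of class `phenotype_table`
#' @export
read_phenotypes <- function(path, traits = c("NW", "KW", "CRO", "DK", "BLO")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "trait", "year", "rep", "value")
  if (!all(need %in% names(tab)))
    stop("phenotype CSV must have columns ", paste(need, collapse = ", "))
  bad <- !(tab$trait %in% traits)
  if (any(bad))
    stop("unknown trait '", tab$trait[bad][1], "' at row ", which(bad)[1])
  phenotype_table(tab)
}

#' @rdname read_phenotypes
#' @param tab data.frame with the phenotype columns
#' @export
phenotype_table <- function(tab) {
  key <- paste(tab$accession, tab$trait, tab$year, tab$rep)
  if (anyDuplicated(key))
    stop("duplicate (accession, trait, year, rep) observation")
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Write a GFF3 gene annotation
#'
#' @param genes data.frame as returned by [read_annotation()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             paste(genes$chrom, "panelgwas", "gene", genes$start, genes$end,
                   ".", genes$strand, ".", paste0("ID=", genes$gene),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
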