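#' Parameters for sliding-window ROH detection
#'
#' Two parameter sets are conventionally used to separate recent from
#' ancient inbreeding: long runs ("ROH 2", minimum length 2% of the genome
#' with a 1 Mb gap allowance) and short runs ("ROH 0.25", minimum length
#' 0.25% of the genome with a 100 kb gap allowance), both detected with a
#' 20-SNP sliding window.
#'
#' @param window_snps sliding-window size in SNPs (default 20)
#' @param min_length_bp minimum run span in bp
#' @param max_gap_bp maximum gap between consecutive SNPs inside one run
#' @param max_het_per_window heterozygous calls tolerated per window
#' @param max_miss_per_window missing calls tolerated per window
#' @param snp_in_run_proportion minimum proportion of overlapping
#'   homozygous windows for a SNP to be counted inside a run
#' @param min_snps_per_run minimum SNP count per run
#' @return A `roh_params` list.
#' @export
roh_params <- function(window_snps = 20, min_length_bp, max_gap_bp,
                       max_het_per_window = 0, max_miss_per_window = 1,
                       snp_in_run_proportion = 0.05, min_snps_per_run = 20) {
  stopifnot(window_snps >= 1, min_length_bp > 0, max_gap_bp > 0,
            max_het_per_window >= 0, max_miss_per_window >= 0,
            snp_in_run_proportion > 0, snp_in_run_proportion <= 1,
            min_snps_per_run >= 1)
  structure(list(window_snps = window_snps, min_length_bp = min_length_bp,
                 max_gap_bp = max_gap_bp,
                 max_het_per_window = max_het_per_window,
                 max_miss_per_window = max_miss_per_window,
                 snp_in_run_proportion = snp_in_run_proportion,
                 min_snps_per_run = min_snps_per_run),
            class = "roh_params")
}

#' Reference genome length used for ROH length classes
#'
#' The minimum ROH length for a class defined as a percentage of the genome,
#' e.g. `roh_length_threshold(0.02)` for the 2% class and
#' `roh_length_threshold(0.0025)` for the 0.25% class.
#'
#' @param fraction genome fraction defining the class
#' @param genome_bp genome length in bp (default: the 208,184,300 bp implied
#'   by the 2% class threshold of 4,163,686 bp)
#' @return Minimum run length in bp, rounded to the nearest integer.
#' @export
roh_length_threshold <- function(fraction, genome_bp = 208184300) {
  round(fraction * genome_bp)
}

#' Canonical long- and short-run ROH parameter sets
#'
#' @param class `"2"` (recent inbreeding, 2% of genome, 1 Mb gap) or
#'   `"0.25"` (ancient inbreeding, 0.25% of genome, 100 kb gap)
#' @param genome_bp genome length passed to [roh_length_threshold()]
#' @return A [roh_params()] object.
#' @export
roh_params_class <- function(class = c("2", "0.25"), genome_bp = 208184300) {
  class <- match.arg(class)
  if (class == "2")
    roh_params(min_length_bp = roh_length_threshold(0.02, genome_bp),
               max_gap_bp = 1e6)
  else
    roh_params(min_length_bp = roh_length_threshold(0.0025, genome_bp),
               max_gap_bp = 1e5)
}

#' Detect runs of homozygosity in one sample
#'
#' Sliding windows of `window_snps` consecutive SNPs are classified
#' homozygous when they contain at most `max_het_per_window` heterozygous
#' and `max_miss_per_window` missing calls. Each SNP is scored by the
#' proportion of overlapping windows that are homozygous; SNPs whose
#' proportion exceeds `snp_in_run_proportion` chain into candidate runs,
#' which are split at inter-SNP gaps above `max_gap_bp` and kept when they
#' span at least `min_length_bp` and contain at least `min_snps_per_run`
#' SNPs. Run coordinates are the first and last SNP positions.
#'
#' @param geno a [genotype_matrix()]
#' @param sample sample id
#' @param params a [roh_params()]
#' @return data.frame of class `roh_set` with columns `sample`, `chrom`,
#'   `start`, `end`, `n_snps`, `length_bp`.
#' @export
detect_roh <- function(geno, sample, params) {
  stopifnot(inherits(params, "roh_params"))
  g_all <- geno$calls[sample, ]
  out <- list()
  for (ch in unique(geno$map$chrom)) {
    idx <- which(geno$map$chrom == ch)
    g <- g_all[idx]
    pos <- geno$map$pos[idx]
    m <- length(g)
    w <- params$window_snps
    if (m < w) {
      warning("chromosome ", ch, " has fewer SNPs than the window; skipped")
      next
    }
    het <- as.integer(!is.na(g) & g == 1L)
    mis <- as.integer(is.na(g))
    ch_het <- cumsum(c(0L, het))
    ch_mis <- cumsum(c(0L, mis))
    nw <- m - w + 1L
    win_ok <- (ch_het[(w + 1):(m + 1)] - ch_het[1:nw]) <= params$max_het_per_window &
      (ch_mis[(w + 1):(m + 1)] - ch_mis[1:nw]) <= params$max_miss_per_window
    # proportion of homozygous windows overlapping each SNP
    ok_cum <- cumsum(c(0L, as.integer(win_ok)))
    first_w <- pmax(1L, seq_len(m) - w + 1L)
    last_w <- pmin(nw, seq_len(m))
    n_over <- last_w - first_w + 1L
    n_hom <- ok_cum[last_w + 1L] - ok_cum[first_w]
    in_run <- (n_hom / n_over) > params$snp_in_run_proportion
    # chain in-run SNPs, splitting at long gaps
    r <- rle(in_run)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (seg in which(r$values)) {
      snp_i <- starts[seg]:ends[seg]
      gaps <- diff(pos[snp_i])
      brk <- c(0L, which(gaps > params$max_gap_bp), length(snp_i))
      for (b in seq_len(length(brk) - 1L)) {
        sub <- snp_i[(brk[b] + 1L):brk[b + 1L]]
        span <- pos[sub[length(sub)]] - pos[sub[1]] + 1L
        if (span >= params$min_length_bp &&
            length(sub) >= params$min_snps_per_run)
          out[[length(out) + 1]] <- data.frame(
            sample = sample, chrom = ch, start = pos[sub[1]],
            end = pos[sub[length(sub)]], n_snps = length(sub),
            length_bp = span, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(), chrom = character(),
               start = integer(), end = integer(), n_snps = integer(),
               length_bp = integer(), stringsAsFactors = FALSE)
  class(res) <- c("roh_set", "data.frame")
  res
}

#' Detect ROH for every sample
#'
#' @inheritParams detect_roh
#' @return A single `roh_set` data.frame over all samples.
#' @export
detect_roh_all <- function(geno, params) {
  res <- do.call(rbind, lapply(geno$samples, function(s)
    detect_roh(geno, s, params)))
  class(res) <- c("roh_set", "data.frame")
  res
}

#' Per-sample inbreeding F and per-SNP ROH coverage frequency
#'
#' `F` for a sample is the summed length of its runs divided by the genome
#' length; `freq` for a SNP is the fraction of samples whose runs cover its
#' position.
#'
#' @param roh a `roh_set` (one ROH class)
#' @param samples all sample ids (samples without runs get F = 0)
#' @param map marker map of the genotype matrix (for per-SNP frequencies)
#' @param genome_length_bp genome length; defaults to the sum over
#'   chromosomes of (last - first SNP position + 1) in `map`
#' @return list with `F` (named per-sample vector) and `freq` (named
#'   per-SNP vector).
#' @export
summarize_inbreeding <- function(roh, samples, map,
                                 genome_length_bp = NULL) {
  if (is.null(genome_length_bp)) {
    genome_length_bp <- sum(vapply(unique(map$chrom), function(ch) {
      p <- map$pos[map$chrom == ch]
      max(p) - min(p) + 1
    }, numeric(1)))
  }
  stopifnot(genome_length_bp > 0)
  Fv <- stats::setNames(numeric(length(samples)), samples)
  if (nrow(roh)) {
    tot <- tapply(roh$length_bp, roh$sample, sum)
    Fv[names(tot)] <- tot / genome_length_bp
  }
  freq <- stats::setNames(numeric(nrow(map)), map$marker)
  if (nrow(roh)) {
    for (r in seq_len(nrow(roh)))
      freq <- freq + as.numeric(map$chrom == roh$chrom[r] &
                                  map$pos >= roh$start[r] &
                                  map$pos <= roh$end[r])
    freq <- freq / length(samples)
  }
  list(F = Fv, freq = freq, genome_length_bp = genome_length_bp)
}
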