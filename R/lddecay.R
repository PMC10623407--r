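#' Pairwise r-squared within a distance window on one chromosome
#'
#' For every pair of SNPs at most `window_bp` apart, the squared Pearson
#' correlation of their alt-dosage vectors over jointly called samples
#' (composite LD, appropriate for unphased array data). Pairs with fewer
#' than `min_joint` joint calls or a constant dosage vector are skipped.
#'
#' @param geno a [genotype_matrix()]
#' @param chromosome chromosome label
#' @param window_bp maximum pair distance (default 250,000)
#' @param min_joint minimum jointly called samples per pair (default 10)
#' @return data.frame with columns `marker1`, `marker2`, `dist_bp`, `r2`.
#' @export
pairwise_r2 <- function(geno, chromosome, window_bp = 250000,
                        min_joint = 10L) {
  idx <- which(geno$map$chrom == chromosome)
  if (length(idx) < 2) stop("need at least two SNPs on ", chromosome)
  pos <- geno$map$pos[idx]
  X <- geno$calls[, idx, drop = FALSE]
  out <- vector("list", length(idx))
  for (i in seq_len(length(idx) - 1L)) {
    jmax <- i
    while (jmax < length(idx) && pos[jmax + 1L] - pos[i] <= window_bp)
      jmax <- jmax + 1L
    if (jmax == i) next
    js <- (i + 1L):jmax
    r2 <- vapply(js, function(j) r2_pair(X[, i], X[, j], min_joint),
                 numeric(1))
    keep <- !is.na(r2)
    if (!any(keep)) next
    out[[i]] <- data.frame(marker1 = geno$map$marker[idx[i]],
                           marker2 = geno$map$marker[idx[js[keep]]],
                           dist_bp = pos[js[keep]] - pos[i],
                           r2 = r2[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(marker1 = character(), marker2 = character(),
                      dist_bp = integer(), r2 = numeric())
  rownames(res) <- NULL
  res
}

#' LD decay distance from pairwise r-squared values
#'
#' Smooths r-squared against distance with local (loess) regression and
#' returns the smallest distance at which the smoothed curve first drops
#' below `threshold`, scanning from zero distance. If the curve never
#' drops below the threshold the window bound is returned, flagged
#' censored.
#'
#' @param pairs data.frame from [pairwise_r2()] (needs `dist_bp`, `r2`);
#'   at least 50 pairs required
#' @param threshold r-squared level defining decay (default 0.2)
#' @param span loess span (default 0.1); widened automatically if the local
#'   fit is degenerate at the requested span
#' @param grid_n evaluation grid size (default 200)
#' @return list with `decay_bp`, `censored`, and the smoothed `curve`
#'   (data.frame `dist_bp`, `r2`).
#' @export
decay_distance <- function(pairs, threshold = 0.2, span = 0.1,
                           grid_n = 200) {
  if (nrow(pairs) < 50) stop("need at least 50 pairs to estimate decay")
  o <- order(pairs$dist_bp)
  d <- pairs$dist_bp[o]
  r2 <- pairs$r2[o]
  fit <- NULL
  sp <- span
  while (is.null(fit) && sp <= 1) {
    fit <- tryCatch(
      suppressWarnings(stats::loess(r2 ~ d, span = sp, degree = 1,
                                    family = "gaussian",
                                    control = stats::loess.control(surface = "direct"))),
      error = function(e) NULL)
    if (is.null(fit)) sp <- sp * 2
  }
  if (is.null(fit)) stop("loess smoothing failed")
  grid <- seq(min(d), max(d), length.out = grid_n)
  sm <- stats::predict(fit, newdata = data.frame(d = grid))
  below <- which(sm < threshold)
  if (length(below)) {
    list(decay_bp = grid[below[1]], censored = FALSE,
         curve = data.frame(dist_bp = grid, r2 = sm), span_used = sp)
  } else {
    list(decay_bp = max(d), censored = TRUE,
         curve = data.frame(dist_bp = grid, r2 = sm), span_used = sp)
  }
}

#' Per-chromosome LD decay for a whole genotype matrix
#'
#' @inheritParams pairwise_r2
#' @inheritParams decay_distance
#' @return data.frame with one row per chromosome: `chrom`, `decay_bp`,
#'   `censored`, `n_pairs`. Chromosomes with fewer than 50 usable pairs
#'   are reported with `NA` decay.
#' @export
ld_decay <- function(geno, window_bp = 250000, threshold = 0.2,
                     span = 0.1) {
  chroms <- unique(geno$map$chrom)
  rows <- lapply(chroms, function(ch) {
    pairs <- tryCatch(pairwise_r2(geno, ch, window_bp),
                      error = function(e) NULL)
    if (is.null(pairs) || nrow(pairs) < 50)
      return(data.frame(chrom = ch, decay_bp = NA_real_, censored = NA,
                        n_pairs = if (is.null(pairs)) 0L else nrow(pairs)))
    dec <- decay_distance(pairs, threshold, span)
    data.frame(chrom = ch, decay_bp = dec$decay_bp,
               censored = dec$censored, n_pairs = nrow(pairs))
  })
  do.call(rbind, rows)
}
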