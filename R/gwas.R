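#' Genotype effect modes
#'
#' @return The four genotype-phenotype interaction modes supported by the
#'   scan: `"additive"`, `"dominant"`, `"recessive"`, `"overdominant"`.
#' @export
gwas_modes <- function() c("additive", "dominant", "recessive", "overdominant")

#' Encode alt-allele dosages under an effect mode
#'
#' With a1 the reference and a2 the alternate allele, dosage 0 = a1a1,
#' 1 = a1a2, 2 = a2a2:
#' \itemize{
#'   \item additive: a1a1 -> 1, a1a2 -> 0, a2a2 -> -1
#'   \item dominant: a1a1, a1a2 -> 1, a2a2 -> -1
#'   \item recessive: a1a1 -> 1, a1a2, a2a2 -> -1
#'   \item overdominant: a1a1, a2a2 -> 1, a1a2 -> 0
#' }
#' The dominant and recessive codes together cover both orientations of a
#' dominant-recessive interaction. Missing stays missing.
#'
#' @param g integer vector of dosages (0/1/2/NA)
#' @param mode one of [gwas_modes()]
#' @return Numeric vector of codes in \{-1, 0, 1\}.
#' @export
encode_dosage <- function(g, mode) {
  codes <- switch(mode,
                  additive = c(1, 0, -1),
                  dominant = c(1, 1, -1),
                  recessive = c(1, -1, -1),
                  overdominant = c(1, 0, 1),
                  stop("unknown mode: ", mode))
  codes[g + 1L]
}

#' Encode a genotype matrix under an effect mode
#'
#' @param geno a [genotype_matrix()]
#' @param mode one of [gwas_modes()]
#' @return samples x markers numeric matrix with a `"mode"` attribute and a
#'   logical `"informative"` attribute (FALSE for markers whose encoded
#'   column is constant among called samples).
#' @export
encode_genotypes <- function(geno, mode) {
  mode <- match.arg(mode, gwas_modes())
  E <- matrix(encode_dosage(as.vector(geno$calls), mode),
              nrow(geno$calls), ncol(geno$calls),
              dimnames = dimnames(geno$calls))
  info <- apply(E, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && stats::var(x) > 0
  })
  attr(E, "mode") <- mode
  attr(E, "informative") <- info
  E
}

# EMMA-style REML of the null model y = W a + g + e with
# Var(y) = Vg * K2 + Ve * I, via the spectral decomposition of K2 (= 2K).
emma_reml_null <- function(y, W, K2) {
  e <- eigen(K2, symmetric = TRUE)
  dvals <- pmax(e$values, 0)
  U <- e$vectors
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, W)
  n <- length(y)
  q <- ncol(W)
  ldWW <- determinant(crossprod(W), logarithm = TRUE)$modulus
  negll <- function(logdelta) {
    w <- dvals + exp(logdelta)
    Ww <- Wt / w
    A <- crossprod(Wt, Ww)
    beta <- solve(A, crossprod(Ww, yt))
    r <- yt - Wt %*% beta
    rss <- sum(r^2 / w)
    s2 <- rss / (n - q)
    0.5 * ((n - q) * log(2 * pi * s2) + sum(log(w)) +
             determinant(A, logarithm = TRUE)$modulus - ldWW + (n - q))
  }
  grid <- seq(-10, 10, length.out = 41)
  vals <- vapply(grid, negll, numeric(1))
  i0 <- which.min(vals)
  lo <- grid[max(1, i0 - 1)]
  hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(negll, c(lo, hi))
  delta <- exp(opt$minimum)
  w <- dvals + delta
  Ww <- Wt / w
  A <- crossprod(Wt, Ww)
  beta <- solve(A, crossprod(Ww, yt))
  rss <- sum((yt - Wt %*% beta)^2 / w)
  Vg <- rss / (n - q)
  list(Vg = Vg, Ve = delta * Vg, delta = delta)
}

#' Mixed-model association scan for one encoding and one correction
#'
#' Tests every marker for association with the BLUP phenotype under the
#' model `y = mu + x beta + Q v + u + e`, where `x` is the encoded marker,
#' `Q`'s first K-1 membership columns are fixed covariates (corrections
#' `"Q"` and `"K+Q"`), and `u` is a polygenic random effect with covariance
#' `2 K Vg` (corrections `"K"` and `"K+Q"`; for `"Q"` the covariance is the
#' identity and the scan is ordinary regression). Variance components are
#' estimated once under the null model by REML via the eigendecomposition of
#' `2K` and reused for every marker (P3D). Markers are tested on their
#' called subset; markers with less than `min_coverage` coverage or a
#' constant encoding are skipped. Wald t p-values; the genomic inflation
#' factor lambda is median(chi-square) / 0.4549.
#'
#' @param blups named numeric vector: one phenotype value (BLUP) per sample
#' @param geno a [genotype_matrix()] covering the same samples
#' @param mode one of [gwas_modes()]
#' @param correction `"Q"`, `"K"` or `"K+Q"`
#' @param kinship [compute_kinship()] matrix (needed for `"K"`/`"K+Q"`)
#' @param Q ancestry matrix from [estimate_admixture()] (needed for
#'   `"Q"`/`"K+Q"`)
#' @param min_coverage minimum fraction of called samples per marker
#' @return An object of class `gwas_scan`: data.frame with per-marker
#'   `marker`, `chrom`, `pos`, `beta`, `se`, `minus_log10_p`, `n_used`, and
#'   attributes `mode`, `correction`, `lambda`, `bonferroni`, `n_markers`,
#'   `Vg`, `Ve`.
#' @export
scan_association <- function(blups, geno, mode, correction = c("Q", "K", "K+Q"),
                             kinship = NULL, Q = NULL, min_coverage = 0.8) {
  correction <- match.arg(correction)
  mode <- match.arg(mode, gwas_modes())
  ids <- geno$samples
  if (!all(ids %in% names(blups)))
    stop("every genotyped sample needs a phenotype value")
  y <- blups[ids]
  n <- length(y)
  W <- matrix(1, n, 1, dimnames = list(ids, "mu"))
  if (correction %in% c("Q", "K+Q")) {
    if (is.null(Q)) stop("correction ", correction, " needs the Q matrix")
    Qm <- as.matrix(Q)[ids, , drop = FALSE]
    if (ncol(Qm) > 1)
      W <- cbind(W, Qm[, -ncol(Qm), drop = FALSE])
  }
  use_K <- correction %in% c("K", "K+Q")
  V <- NULL
  Vg <- Ve <- NA_real_
  if (use_K) {
    if (is.null(kinship)) stop("correction ", correction, " needs kinship")
    K2 <- 2 * unclass(kinship)[ids, ids]
    ev_min <- min(eigen(K2, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-6)
      stop("kinship is not positive semidefinite; stabilize it first")
    vc <- emma_reml_null(y, W, K2)
    Vg <- vc$Vg; Ve <- vc$Ve
    V <- Vg * K2 + Ve * diag(n)
  }
  E <- encode_genotypes(geno, mode)
  m <- ncol(E)
  res <- data.frame(marker = geno$map$marker, chrom = geno$map$chrom,
                    pos = geno$map$pos, beta = NA_real_, se = NA_real_,
                    minus_log10_p = NA_real_, n_used = NA_integer_,
                    stringsAsFactors = FALSE)
  chol_full <- if (use_K) chol(V) else NULL
  for (j in seq_len(m)) {
    x <- E[, j]
    ok <- !is.na(x) & !is.na(y)
    nS <- sum(ok)
    if (nS < n * min_coverage) next
    if (stats::var(x[ok]) == 0) next
    X <- cbind(W[ok, , drop = FALSE], x = x[ok])
    yS <- y[ok]
    if (use_K) {
      R <- if (nS == n) chol_full else chol(V[ok, ok])
      X <- backsolve(R, X, transpose = TRUE)
      yS <- backsolve(R, yS, transpose = TRUE)
    }
    fit <- stats::lm.fit(X, yS)
    df <- nS - fit$rank
    if (df <= 0 || fit$rank < ncol(X)) next
    XtXi <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
    if (is.null(XtXi)) next
    s2 <- sum(fit$residuals^2) / df
    b <- fit$coefficients[ncol(X)]
    se <- sqrt(s2 * XtXi[ncol(X), ncol(X)])
    tval <- b / se
    p <- 2 * stats::pt(-abs(tval), df)
    res$beta[j] <- b
    res$se[j] <- se
    res$minus_log10_p[j] <- -log10(p)
    res$n_used[j] <- nS
  }
  pvals <- 10^(-res$minus_log10_p[!is.na(res$minus_log10_p)])
  lambda <- stats::median(stats::qchisq(1 - pvals, df = 1)) /
    stats::qchisq(0.5, df = 1)
  structure(res, class = c("gwas_scan", "data.frame"),
            mode = mode, correction = correction, lambda = lambda,
            bonferroni = 0.05 / m, n_markers = m, Vg = Vg, Ve = Ve)
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("gwas_scan [%s, %s]: %d markers, lambda = %.3f, -log10 threshold = %.2f\n",
              attr(x, "mode"), attr(x, "correction"), attr(x, "n_markers"),
              attr(x, "lambda"), -log10(attr(x, "bonferroni"))))
  top <- x[order(-x$minus_log10_p), ][1, ]
  if (!is.na(top$minus_log10_p))
    cat(sprintf("  top: %s (%s:%d) -log10 p = %.2f\n", top$marker, top$chrom,
                top$pos, top$minus_log10_p))
  invisible(x)
}

#' Run a scan under every requested correction
#'
#' @inheritParams scan_association
#' @param corrections subset of `c("Q", "K", "K+Q")`
#' @return Named list of `gwas_scan` objects in canonical order.
#' @export
scan_corrections <- function(blups, geno, mode,
                             corrections = c("Q", "K", "K+Q"),
                             kinship = NULL, Q = NULL, min_coverage = 0.8) {
  corrections <- intersect(c("Q", "K", "K+Q"), corrections)
  out <- lapply(corrections, function(cc)
    scan_association(blups, geno, mode, cc, kinship = kinship, Q = Q,
                     min_coverage = min_coverage))
  names(out) <- corrections
  out
}

#' Choose the correction whose p-values best match the null uniform
#'
#' Scores each scan by `|lambda - 1|`; ties are broken by the
#' Kolmogorov-Smirnov distance of the p-value distribution to Uniform(0,1),
#' then by the canonical order Q, K, K+Q.
#'
#' @param scans named list of `gwas_scan` objects (names from
#'   `c("Q", "K", "K+Q")`)
#' @return list with `correction` (chosen name), `scan`, and `scores`
#'   (data.frame of lambda and KS distance per candidate).
#' @export
select_correction <- function(scans) {
  if (length(scans) < 2) stop("need at least two candidate scans")
  canon <- intersect(c("Q", "K", "K+Q"), names(scans))
  scores <- do.call(rbind, lapply(canon, function(nm) {
    s <- scans[[nm]]
    p <- 10^(-s$minus_log10_p[!is.na(s$minus_log10_p)])
    ks <- suppressWarnings(stats::ks.test(p, "punif")$statistic)
    data.frame(correction = nm, lambda = attr(s, "lambda"),
               abs_dev = abs(attr(s, "lambda") - 1), ks = unname(ks))
  }))
  o <- order(round(scores$abs_dev, 12), round(scores$ks, 12),
             seq_len(nrow(scores)))
  chosen <- scores$correction[o[1]]
  list(correction = chosen, scan = scans[[chosen]], scores = scores)
}

r_squared <- function(y, X) {
  X <- as.matrix(X)
  ok <- stats::complete.cases(y, X)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  if (length(y) < 3) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Call QTLs from a scan with Bonferroni control and mode confirmation
#'
#' Markers above the Bonferroni threshold (0.05 / marker count) are grouped
#' into peaks: significant markers on the same chromosome within twice the
#' chromosome's LD-decay distance of each other share a peak, and the peak
#' maximum (ties broken toward the lower position) is the top SNP. Each
#' candidate is then checked for mode consistency, a quantitative
#' replacement for visual inspection of the phenotype-genotype boxplots:
#' among the four encodings, the one maximizing the R-squared of the BLUP
#' on the encoded top SNP must be the scanned mode, otherwise the record is
#' flagged a false positive. VE is the simple-regression R-squared of the
#' BLUP on the top SNP's encoding.
#'
#' @param scan a `gwas_scan`
#' @param blups named phenotype vector used for the scan
#' @param geno the scanned [genotype_matrix()]
#' @param decay per-chromosome LD decay: data.frame from [ld_decay()] or a
#'   named `decay_bp` vector; chromosomes missing a decay estimate fall
#'   back to 250,000 bp for peak grouping
#' @param trait trait name recorded on the records
#' @return data.frame of class `qtl_record` (possibly empty): `trait`,
#'   `mode`, `correction`, `marker`, `chrom`, `pos`, `minus_log10_p`,
#'   `ve`, `best_mode`, `true_positive`.
#' @export
call_qtls <- function(scan, blups, geno, decay, trait = "TRAIT") {
  thr <- -log10(attr(scan, "bonferroni"))
  if (is.data.frame(decay)) {
    dvec <- stats::setNames(decay$decay_bp, decay$chrom)
  } else dvec <- decay
  sig <- scan[!is.na(scan$minus_log10_p) & scan$minus_log10_p > thr, ,
              drop = FALSE]
  empty <- data.frame(trait = character(), mode = character(),
                      correction = character(), marker = character(),
                      chrom = character(), pos = integer(),
                      minus_log10_p = numeric(), ve = numeric(),
                      best_mode = character(), true_positive = logical(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("qtl_record", "data.frame")
  if (nrow(sig) == 0) return(empty)
  y <- blups[geno$samples]
  recs <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    gap <- 2 * (if (!is.na(dvec[ch] %||% NA)) dvec[ch] else 250000)
    peak_id <- cumsum(c(1, diff(s$pos) > gap))
    for (pk in unique(peak_id)) {
      p <- s[peak_id == pk, , drop = FALSE]
      top <- p[order(-p$minus_log10_p, p$pos), ][1, ]
      g_top <- geno$calls[, top$marker]
      r2_by_mode <- vapply(gwas_modes(), function(md)
        r_squared(y, encode_dosage(g_top, md)), numeric(1))
      best <- names(which.max(r2_by_mode))
      ve <- r_squared(y, encode_dosage(g_top, attr(scan, "mode")))
      recs[[length(recs) + 1]] <- data.frame(
        trait = trait, mode = attr(scan, "mode"),
        correction = attr(scan, "correction"), marker = top$marker,
        chrom = top$chrom, pos = top$pos,
        minus_log10_p = top$minus_log10_p, ve = ve, best_mode = best,
        true_positive = identical(best, attr(scan, "mode")),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  class(out) <- c("qtl_record", "data.frame")
  out
}

#' Name QTLs and compute combined variance explained per trait
#'
#' Assigns standard QTL names (`q<trait><chromosome>` with `.k` suffixes
#' when one trait has several QTLs on a chromosome) and, for every trait,
#' computes the combined variance explained (CVE): the R-squared of the
#' joint linear regression of the trait's BLUPs on the encodings of all its
#' confirmed top SNPs. With a single confirmed QTL the CVE equals its VE.
#'
#' @param records `qtl_record` rows (possibly from several scans/traits)
#' @param blups named list: per trait, the named BLUP vector
#' @param geno the scanned [genotype_matrix()]
#' @return The records with `name` and `cve` columns added (CVE repeated on
#'   every confirmed record of a trait; `NA` on false positives).
#' @export
qtl_summary <- function(records, blups, geno) {
  if (nrow(records) == 0) return(records)
  chromnum <- gsub("\\D", "", records$chrom)
  records$name <- paste0("q", records$trait, chromnum)
  for (key in unique(paste(records$trait, chromnum))) {
    i <- which(paste(records$trait, chromnum) == key)
    if (length(i) > 1)
      records$name[i] <- paste0(records$name[i], ".", seq_along(i))
  }
  records$cve <- NA_real_
  for (tr in unique(records$trait)) {
    conf <- which(records$trait == tr & records$true_positive)
    if (!length(conf)) next
    y <- blups[[tr]][geno$samples]
    X <- vapply(conf, function(i)
      encode_dosage(geno$calls[, records$marker[i]], records$mode[i]),
      numeric(nrow(geno$calls)))
    records$cve[conf] <- r_squared(y, X)
  }
  records
}
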