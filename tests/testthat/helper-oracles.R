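# Fixture builders and independent brute-force oracles used across tests.

# Genotype matrix from a raw calls matrix; markers evenly spaced on one or
# more chromosomes.
make_geno <- function(calls, n_chrom = 1, spacing = 1000L) {
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("S%02d", seq_len(n))
  per <- ceiling(m / n_chrom)
  chrom <- rep(sprintf("chr%d", seq_len(n_chrom)), each = per)[seq_len(m)]
  pos <- unlist(lapply(split(seq_len(m), chrom), seq_along), use.names = FALSE)
  pos <- ave(seq_len(m), chrom, FUN = seq_along) * spacing
  map <- data.frame(marker = sprintf("M%04d", seq_len(m)), chrom = chrom,
                    pos = as.integer(pos), a1 = "A", a2 = "G",
                    stringsAsFactors = FALSE)
  colnames(calls) <- map$marker
  genotype_matrix(calls, map)
}

random_geno <- function(n, m, miss = 0, seed = 1, n_chrom = 1) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss > 0) calls[runif(n * m) < miss] <- NA
  make_geno(calls, n_chrom = n_chrom)
}

# IBS by explicit double loop over pairs and markers.
oracle_ibs <- function(X) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    both <- !is.na(X[i, ]) & !is.na(X[j, ])
    if (sum(both) == 0) next
    out[i, j] <- mean(X[i, both] == X[j, both])
  }
  diag(out) <- 1
  out
}

# VanRaden kinship entry-by-entry for a complete (no missing) matrix.
oracle_kinship <- function(X) {
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  Z <- sweep(X, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  out <- matrix(NA_real_, nrow(X), nrow(X))
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(X)))
    out[i, j] <- sum(Z[i, ] * Z[j, ]) / denom
  out
}

# Straightforward agglomerative UPGMA: returns the cophenetic distance
# matrix implied by average-linkage merging.
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(labels)
  dd <- d
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  active <- seq_len(n)
  sizes <- rep(1, n)
  while (length(active) > 1) {
    best <- c(NA, NA); bv <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii >= jj) next
      v <- dd[active[ii], active[jj]]
      if (v < bv) { bv <- v; best <- c(active[ii], active[jj]) }
    }
    a <- best[1]; b <- best[2]
    for (x in clusters[[a]]) for (y in clusters[[b]]) {
      coph[x, y] <- bv; coph[y, x] <- bv
    }
    # average-linkage update into slot a
    for (k in setdiff(active, best)) {
      dd[a, k] <- (sizes[a] * dd[a, k] + sizes[b] * dd[b, k]) /
        (sizes[a] + sizes[b])
      dd[k, a] <- dd[a, k]
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  coph
}

# EM-REML for y = X beta + Z u + e with u ~ N(0, Vg I), e ~ N(0, Ve I).
oracle_em_reml <- function(y, X, Z, tol = 1e-10, max_iter = 5000) {
  n <- length(y); q <- ncol(Z)
  Vg <- Ve <- stats::var(y) / 2 + 1e-6
  for (it in seq_len(max_iter)) {
    V <- Vg * tcrossprod(Z) + Ve * diag(n)
    Vi <- solve(V)
    XtViX <- solve(t(X) %*% Vi %*% X)
    P <- Vi - Vi %*% X %*% XtViX %*% t(X) %*% Vi
    u <- Vg * t(Z) %*% P %*% y
    beta <- XtViX %*% t(X) %*% Vi %*% y
    e <- y - X %*% beta - Z %*% u
    Vg_new <- (sum(u^2) + Vg * (q - Vg * sum(diag(t(Z) %*% P %*% Z)))) / q
    Ve_new <- (sum(e^2) + Ve * (n - Ve * sum(diag(P)))) / n
    if (abs(Vg_new - Vg) + abs(Ve_new - Ve) < tol) break
    Vg <- Vg_new; Ve <- Ve_new
  }
  list(Vg = Vg, Ve = Ve)
}

# OLS p-value for the last column of a design, via summary.lm.
oracle_ols_p <- function(y, covars, x) {
  ok <- stats::complete.cases(y, x)
  d <- data.frame(y = y[ok], x = x[ok])
  X <- if (is.null(covars)) NULL else covars[ok, , drop = FALSE]
  fit <- if (is.null(X)) stats::lm(y ~ x, data = d)
         else stats::lm(d$y ~ X + d$x)
  co <- summary(fit)$coefficients
  co[nrow(co), 4]
}
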