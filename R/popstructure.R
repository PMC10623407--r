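#' Estimate ancestry coefficients by masked matrix factorization
#'
#' Factorizes the half-dosage matrix `X = calls / 2` as `Q %*% G`, where
#' `Q` (samples x K) holds ancestry membership coefficients on the
#' probability simplex and `G` (K x markers) holds ancestral allele
#' frequencies in `[0, 1]`. The fit is alternating least squares with
#' simplex projection for `Q` rows, clipping for `G`, an EM-style fill for
#' unobserved entries and a backtracking step that makes the observed-data
#' residual monotonically non-increasing.
#'
#' Model choice: for each repetition, 5% of the called entries are masked
#' out of the fit; the per-K score is the Bernoulli cross-entropy of the
#' fitted frequencies on the masked entries, and the best K minimizes the
#' mean masked cross-entropy over repetitions.
#'
#' A sample is assigned to its argmax ancestral group when that coefficient
#' exceeds 0.60, and is "admixed" otherwise.
#'
#' @param geno a [genotype_matrix()] (missing calls allowed)
#' @param K_range candidate numbers of ancestral groups
#' @param reps masking repetitions per K
#' @param seed integer seed
#' @param max_iter,tol ALS iteration cap and relative-residual tolerance
#' @param mask_frac fraction of called entries masked per repetition
#' @return An object of class `ancestry_fit`: list with `K`, `Q`, `G`,
#'   `assignments`, `cross_entropy` (K x rep matrix), `ce_by_K`,
#'   `K_range`.
#' @export
estimate_admixture <- function(geno, K_range = 1:6, reps = 5, seed = 1,
                               max_iter = 500, tol = 1e-6,
                               mask_frac = 0.05) {
  X <- geno$calls / 2
  n <- nrow(X)
  if (max(K_range) >= n)
    stop("largest K must be smaller than the sample count")
  obs_idx <- which(!is.na(X))
  ce <- matrix(NA_real_, length(K_range), reps,
               dimnames = list(paste0("K", K_range), NULL))
  fits <- vector("list", length(K_range))
  for (r in seq_len(reps)) {
    set.seed(stream_seed(seed, "mask") + r)
    masked <- sample(obs_idx, max(1, round(mask_frac * length(obs_idx))))
    Xtrain <- X
    Xtrain[masked] <- NA
    for (ki in seq_along(K_range)) {
      fit <- qg_factorize(Xtrain, K_range[ki], seed = stream_seed(seed, "admixture") + 1000L * r + ki,
                          max_iter = max_iter, tol = tol)
      P <- pmin(pmax(fit$Q %*% fit$G, 1e-6), 1 - 1e-6)
      d <- X[masked]
      p <- P[masked]
      ce[ki, r] <- -mean(d * log(p) + (1 - d) * log(1 - p))
      if (is.null(fits[[ki]]) || ce[ki, r] <= min(ce[ki, seq_len(r - 1)], Inf, na.rm = TRUE))
        fits[[ki]] <- fit
    }
  }
  ce_by_K <- rowMeans(ce)
  best <- which.min(ce_by_K)
  fit <- fits[[best]]
  K <- K_range[best]
  colnames(fit$Q) <- paste0("G", seq_len(K))
  rownames(fit$Q) <- rownames(X)
  amax <- max.col(fit$Q, ties.method = "first")
  assignments <- ifelse(fit$Q[cbind(seq_len(n), amax)] > 0.60,
                        colnames(fit$Q)[amax], "admixed")
  names(assignments) <- rownames(X)
  structure(list(K = K, Q = fit$Q, G = fit$G, assignments = assignments,
                 cross_entropy = ce, ce_by_K = ce_by_K, K_range = K_range,
                 residual_path = fit$residuals),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat("ancestry_fit: K =", x$K, "(candidates:",
      paste(range(x$K_range), collapse = "-"), ")\n")
  tab <- table(x$assignments)
  cat("  assignments:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# Euclidean projection of each row onto the probability simplex.
project_simplex_rows <- function(Q) {
  t(apply(Q, 1, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    pmax(v + (1 - css[rho]) / rho, 0)
  }))
}

# Alternating least squares for X ~ Q G with missing entries filled by the
# current prediction; a backtracking interpolation keeps the observed-entry
# residual non-increasing.
qg_factorize <- function(X, K, seed, max_iter = 500, tol = 1e-6) {
  n <- nrow(X); m <- ncol(X)
  obs <- !is.na(X)
  if (K == 1) {
    G <- matrix(colMeans(X, na.rm = TRUE), 1, m)
    G[is.na(G)] <- 0.5
    return(list(Q = matrix(1, n, 1), G = G, residuals = numeric(0)))
  }
  set.seed(seed)
  Q <- project_simplex_rows(matrix(stats::rexp(n * K), n, K))
  G <- matrix(stats::runif(K * m, 0.1, 0.9), K, m)
  Xf <- X
  Xf[!obs] <- (Q %*% G)[!obs]
  res_obs <- function(Q, G) sqrt(sum(((X - Q %*% G)[obs])^2))
  res <- res_obs(Q, G)
  path <- res
  for (it in seq_len(max_iter)) {
    Xf[!obs] <- (Q %*% G)[!obs]
    Gc <- pmin(pmax(solve(crossprod(Q) + diag(1e-8, K), crossprod(Q, Xf)), 0), 1)
    Xf[!obs] <- (Q %*% Gc)[!obs]
    Qc <- project_simplex_rows(Xf %*% t(Gc) %*%
                                 solve(tcrossprod(Gc) + diag(1e-8, K)))
    t_step <- 1
    repeat {
      Qn <- Q + t_step * (Qc - Q)
      Gn <- G + t_step * (Gc - G)
      res_new <- res_obs(Qn, Gn)
      if (res_new <= res || t_step < 1e-4) break
      t_step <- t_step / 2
    }
    if (res_new > res) { res_new <- res; Qn <- Q; Gn <- G }
    Q <- Qn; G <- Gn
    path <- c(path, res_new)
    if (abs(res - res_new) < tol * max(res, 1e-12)) { res <- res_new; break }
    res <- res_new
  }
  list(Q = Q, G = G, residuals = path)
}

#' Additive realized-relationship (kinship) matrix
#'
#' VanRaden-type estimator: dosages are centered by twice the allele
#' frequency and cross-multiplied; each pair's product sum is scaled by
#' `2 * sum p(1-p)` over the markers called in both samples, so missing
#' calls contribute zero to the numerator and drop out of the denominator.
#' The result is stabilized by flooring eigenvalues at 1e-8, making `2K` a
#' valid polygenic covariance.
#'
#' @param geno a [genotype_matrix()]
#' @return Symmetric positive semidefinite matrix of class
#'   `kinship_matrix`.
#' @export
compute_kinship <- function(geno) {
  X <- geno$calls
  p <- allele_freq(geno)
  poly <- p > 0 & p < 1 & !is.na(p)
  if (!any(poly)) stop("all markers monomorphic; kinship undefined")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  called <- !is.na(X)
  Z <- sweep(X, 2, 2 * p)
  Z[!called] <- 0
  num <- tcrossprod(Z)
  w <- 2 * p * (1 - p)
  Wc <- sweep(called * 1, 2, sqrt(w), `*`)
  denom <- tcrossprod(Wc)
  K <- num / denom
  K[denom == 0] <- 0
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  K <- e$vectors %*% (pmax(e$values, 1e-8) * t(e$vectors))
  K <- (K + t(K)) / 2
  dimnames(K) <- list(geno$samples, geno$samples)
  class(K) <- c("kinship_matrix", "matrix")
  K
}

#' Principal component analysis of genotypes
#'
#' SVD of the centered, unit-variance-scaled dosage matrix; missing calls
#' are mean-imputed (for the PCA only), and zero-variance markers dropped.
#'
#' @param geno a [genotype_matrix()]
#' @param n_pc number of components to return
#' @return list with `scores` (samples x n_pc) and `explained`
#'   (variance fractions, non-increasing, summing to at most 1).
#' @export
pca_genotypes <- function(geno, n_pc = 10) {
  X <- geno$calls
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  v <- apply(X, 2, stats::var)
  X <- X[, v > 0, drop = FALSE]
  X <- scale(X)
  sv <- svd(X)
  n_pc <- min(n_pc, length(sv$d))
  scores <- sv$u[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)
  rownames(scores) <- geno$samples
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  list(scores = scores,
       explained = (sv$d^2 / sum(sv$d^2))[seq_len(n_pc)])
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage (UPGMA) hierarchical clustering of a distance matrix
#' (typically `1 - IBS`), returned as an ultrametric \pkg{ape} `phylo`
#' tree whose branch lengths are half the merge heights.
#'
#' @param d symmetric distance matrix with zero diagonal and no undefined
#'   entries
#' @return An `ape::phylo` tree; write it with `ape::write.tree()`.
#' @export
upgma_tree <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("undefined distances; resolve NA entries first")
  if (any(abs(diag(d)) > 1e-12)) stop("distance diagonal must be zero")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}
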