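# Internal helpers shared across modules.

# One user-facing seed drives every stage; each component draws from its own
# derived stream so stages can be regenerated independently.
stream_seed <- function(seed, component) {
  offsets <- c(genotypes = 1L, phenotypes = 2L, fixtures = 3L,
               admixture = 4L, mask = 5L, scan = 6L)
  if (!component %in% names(offsets)) stop("unknown RNG stream: ", component)
  (as.integer(seed) %% 21474836L) * 100L + offsets[[component]]
}

# Squared Pearson correlation over jointly observed entries; NA if fewer
# than min_n joint calls or either vector is constant.
r2_pair <- function(x, y, min_n = 10L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_n) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
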