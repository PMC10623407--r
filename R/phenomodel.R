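#' Crack-out fraction from nut and kernel weight
#'
#' The shell fraction of total nut mass: `(nw - kw) / nw`. Stored as a
#' fraction; convert to percent only for display.
#'
#' @param nw nut weight (g), > 0
#' @param kw kernel weight (g), between 0 and `nw`
#' @return Crack-out fraction in `[0, 1]`.
#' @export
crack_out <- function(nw, kw) {
  if (any(nw <= 0)) stop("nut weight must be positive")
  if (any(kw < 0 | kw > nw)) stop("kernel weight must lie in [0, nut weight]")
  (nw - kw) / nw
}

#' Broad-sense heritability from variance components
#'
#' `h2 = var_g / (var_g + var_e / n)` with `var_g` the genotypic variance,
#' `var_e` the residual variance and `n` the mean number of observations
#' per genotype.
#'
#' @param var_g genotypic variance (>= 0)
#' @param var_e residual variance (>= 0)
#' @param n mean observations per genotype (> 0)
#' @return Heritability in `[0, 1]`; `NA` (with a warning) if both
#'   variances are zero.
#' @export
heritability <- function(var_g, var_e, n) {
  stopifnot(var_g >= 0, var_e >= 0, n > 0)
  if (var_g == 0 && var_e == 0) {
    warning("both variance components are zero; heritability undefined")
    return(NA_real_)
  }
  var_g / (var_g + var_e / n)
}

#' Fit the BLUP mixed model for one trait
#'
#' REML fit (via \pkg{lme4}) of a linear mixed model with genotype as an
#' i.i.d. random effect. With `model = "with_year"` the fixed part is the
#' year effect (optionally the year x repetition interaction via
#' `year_rep = TRUE`); with `model = "no_year"` only an intercept is
#' fitted, the form used for traits scored without a year structure.
#'
#' @param table a `phenotype_table` (columns `accession`, `trait`, `year`,
#'   `rep`, `value`)
#' @param trait trait name to fit
#' @param model `"with_year"` or `"no_year"`
#' @param year_rep use the year x repetition interaction as the fixed
#'   effect instead of year alone
#' @return An object of class `blup_fit`: list with `blup` (named vector,
#'   overall mean + genotype BLUP), `u` (genotype deviations), `var_g`,
#'   `var_e`, `n` (mean observations per genotype), `h2`, `mu`, `model`.
#' @export
fit_blup <- function(table, trait, model = c("with_year", "no_year"),
                     year_rep = FALSE) {
  model <- match.arg(model)
  dat <- table[table$trait == trait & !is.na(table$value), , drop = FALSE]
  if (nrow(dat) == 0) stop("no observations for trait ", trait)
  dat$accession <- factor(dat$accession)
  if (nlevels(dat$accession) < 2) stop("need at least two genotypes")
  dropped <- setdiff(unique(table$accession[table$trait == trait]),
                     levels(dat$accession))
  if (length(dropped))
    warning("genotype(s) without observations excluded: ",
            paste(dropped, collapse = ", "))
  if (model == "with_year") {
    dat$year <- factor(dat$year)
    fixed <- if (year_rep) {
      dat$yr <- interaction(dat$year, dat$rep, drop = TRUE)
      ~ yr
    } else ~ year
    mm <- stats::model.matrix(fixed, dat)
    qr_mm <- qr(mm)
    if (qr_mm$rank < ncol(mm)) {
      aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
      stop("singular fixed design; aliased level(s): ",
           paste(aliased, collapse = ", "))
    }
    form <- if (year_rep) value ~ yr + (1 | accession)
            else value ~ year + (1 | accession)
  } else {
    form <- value ~ 1 + (1 | accession)
  }
  fit <- suppressMessages(lme4::lmer(form, data = dat, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_g <- vc$vcov[vc$grp == "accession"]
  var_e <- vc$vcov[vc$grp == "Residual"]
  u <- lme4::ranef(fit)$accession[, 1]
  names(u) <- rownames(lme4::ranef(fit)$accession)
  mu <- mean(stats::model.matrix(fit) %*% lme4::fixef(fit))
  n_mean <- nrow(dat) / nlevels(dat$accession)
  structure(list(blup = mu + u, u = u, var_g = var_g, var_e = var_e,
                 n = n_mean, h2 = heritability(var_g, var_e, n_mean),
                 mu = mu, model = model, trait = trait,
                 n_obs = nrow(dat), fit = fit),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("blup_fit [%s, %s]: %d genotypes, %d observations\n",
              x$trait, x$model, length(x$blup), x$n_obs))
  cat(sprintf("  var_g = %.4g, var_e = %.4g, mean reps n = %.2f, h2 = %.3f\n",
              x$var_g, x$var_e, x$n, x$h2))
  invisible(x)
}

#' Variance-component summary across traits
#'
#' Fits [fit_blup()] per trait and tabulates genotypic variance, residual
#' variance, mean repetitions and broad-sense heritability (the layout of a
#' variance-partition table).
#'
#' @param table a `phenotype_table`
#' @param traits traits to fit (default: all present)
#' @param no_year_traits traits fitted without the year fixed effect
#' @return data.frame with one row per trait.
#' @export
variance_table <- function(table, traits = unique(table$trait),
                           no_year_traits = "DK") {
  rows <- lapply(traits, function(tr) {
    f <- fit_blup(table, tr,
                  model = if (tr %in% no_year_traits) "no_year" else "with_year")
    data.frame(trait = tr, var_g = f$var_g, var_e = f$var_e, n = f$n,
               h2 = f$h2)
  })
  do.call(rbind, rows)
}
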