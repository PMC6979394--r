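#' Multi-environment BLUP and variance components
#'
#' Fits the random-effects model y = mu + line + env + e by REML (via lme4)
#' with genotype (line) and environment as random effects, and returns the
#' shrunken line values mu + BLUP(line) together with the genetic and
#' residual variance components. With a single environment the line and
#' residual variances are not separable: line means are returned with a
#' warning and the components are NA.
#'
#' @param pheno a phenotype table (line, trait, env, value).
#' @param trait trait to fit (default: the only trait present).
#' @return list with `blup` (named vector), `vc` (list sigma2_g, sigma2_e,
#'   sigma2_env, n_env), and `fit` (the lmer fit, NULL for single-env data).
#' @export
fit_blup <- function(pheno, trait = NULL) {
  tab <- as.data.frame(pheno)
  if (is.null(trait)) {
    trait <- unique(tab$trait)
    if (length(trait) > 1) stop("several traits present; pick one")
  }
  tab <- tab[tab$trait == trait & !is.na(tab$value), ]
  n_env <- length(unique(tab$env))
  if (n_env < 2) {
    warning("single environment: returning line means, variance components NA")
    mu <- c(tapply(tab$value, tab$line, mean))
    return(list(blup = mu[order(names(mu))],
                vc = list(sigma2_g = NA_real_, sigma2_e = NA_real_,
                          sigma2_env = NA_real_, n_env = n_env),
                fit = NULL))
  }
  fit <- lme4::lmer(value ~ 1 + (1 | line) + (1 | env), data = tab,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vcs <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    v <- vcs$vcov[vcs$grp == grp]
    if (length(v)) v else 0
  }
  re <- lme4::ranef(fit)$line
  blup <- lme4::fixef(fit)[["(Intercept)"]] + re[["(Intercept)"]]
  names(blup) <- rownames(re)
  list(blup = blup[order(names(blup))],
       vc = list(sigma2_g = get_vc("line"), sigma2_e = get_vc("Residual"),
                 sigma2_env = get_vc("env"), n_env = n_env),
       fit = fit)
}

#' Line mean-based broad-sense heritability
#'
#' H2 = sigma2_g / (sigma2_g + sigma2_e / n) over line means across n
#' environments.
#'
#' @param vc variance components (list with sigma2_g, sigma2_e, n_env), e.g.
#'   from [fit_blup()].
#' @param n_env number of environments; defaults to `vc$n_env`.
#' @return heritability in \[0, 1\].
#' @export
heritability <- function(vc, n_env = vc$n_env) {
  if (is.null(n_env) || n_env <= 0) stop("n_env must be positive")
  if (vc$sigma2_g == 0 && vc$sigma2_e == 0) stop("both components zero")
  vc$sigma2_g / (vc$sigma2_g + vc$sigma2_e / n_env)
}

#' Variance explained by QTL peak predictors
#'
#' Per-QTL PVE is the R-squared of a single-predictor regression of the line
#' BLUPs on the QTL's peak predictor (numeric dosage for SNP peaks, factor of
#' founder/allele states for bin peaks); the joint PVE is the R-squared of
#' the multiple regression on all peak predictors together. Collinear
#' predictors are dropped by the least-squares fit with a warning.
#'
#' @param predictors data.frame (or list) of per-QTL peak predictors, rows
#'   aligned with `blup`; numeric columns are treated as dosages, everything
#'   else as categorical founder states.
#' @param blup numeric vector of line values.
#' @param h2 optional broad-sense heritability; when given, PVEs are also
#'   reported as fractions of h2.
#' @return list with `per_qtl` (named vector of R2), `joint` (R2 of the full
#'   model), and optionally `per_qtl_h2`, `joint_h2`.
#' @export
qtl_pve <- function(predictors, blup, h2 = NULL) {
  predictors <- as.data.frame(predictors, stringsAsFactors = FALSE)
  stopifnot(nrow(predictors) == length(blup))
  for (j in seq_along(predictors)) {
    if (!is.numeric(predictors[[j]])) {
      predictors[[j]] <- relevel_most_frequent(predictors[[j]])
    }
  }
  r2 <- function(df) {
    fit <- stats::lm(blup ~ ., data = df)
    if (anyNA(stats::coef(fit))) {
      warning("collinear predictor levels dropped in PVE regression")
    }
    summary(fit)$r.squared
  }
  per <- vapply(seq_along(predictors), function(j) {
    r2(predictors[j])
  }, numeric(1))
  names(per) <- names(predictors)
  joint <- r2(predictors)
  out <- list(per_qtl = per, joint = joint)
  if (!is.null(h2)) {
    out$per_qtl_h2 <- per / h2
    out$joint_h2 <- joint / h2
  }
  out
}

# one-hot-style factor with the most frequent state as reference level
relevel_most_frequent <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "UNKNOWN"
  tab <- sort(table(x), decreasing = TRUE)
  factor(x, levels = names(tab))
}
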