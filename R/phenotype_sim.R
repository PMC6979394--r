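#' Specify quantitative trait nucleotides for phenotype simulation
#'
#' Additive effect magnitudes follow a geometric series `a^rank` (default
#' a = 0.95), globally rescaled at simulation time so that the realized
#' genetic variance equals `h2 * Vp`. Optional pairwise epistatic terms
#' (products of centered dosages) contribute `epi_pve * Vp` of variance on
#' top of the additive part.
#'
#' @param markers character vector of causal marker IDs.
#' @param ranks integer ranks n giving effect magnitudes a^n (defaults to
#'   1..length(markers)).
#' @param signs effect signs (+1/-1), default all +1.
#' @param effects optional explicit per-QTN effects (overrides
#'   `signs * a^ranks`; still rescaled jointly to hit `h2`).
#' @param a geometric decay base in (0, 1).
#' @param h2 target narrow-sense heritability in (0, 1].
#' @param Vp total phenotypic variance.
#' @param epi_pairs optional 2-column matrix of interacting marker IDs.
#' @param epi_pve variance fraction contributed by the epistatic terms.
#' @return A `qtn_spec` list.
#' @export
qtn_spec <- function(markers, ranks = seq_along(markers),
                     signs = rep(1, length(markers)), effects = NULL,
                     a = 0.95, h2 = 0.8, Vp = 1,
                     epi_pairs = NULL, epi_pve = 0) {
  if (a <= 0 || a >= 1) stop("a must be in (0, 1)")
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  if (Vp <= 0) stop("Vp must be positive")
  stopifnot(length(ranks) == length(markers), length(signs) == length(markers))
  if (h2 + epi_pve > 1) stop("h2 + epi_pve exceeds 1")
  if (!is.null(effects)) stopifnot(length(effects) == length(markers))
  structure(list(markers = markers, ranks = ranks, signs = signs,
                 effects = effects, a = a, h2 = h2, Vp = Vp,
                 epi_pairs = epi_pairs, epi_pve = epi_pve),
            class = "qtn_spec")
}

#' Simulate phenotypes with additive (and optional epistatic) QTN effects
#'
#' Genetic values are the dosage-weighted sum of QTN effects `sign * a^rank`,
#' rescaled so that their variance across lines is exactly `h2 * Vp`;
#' residuals are drawn i.i.d. normal with variance `(1 - h2 - epi_pve) * Vp`
#' (0.2 under the default h2 = 0.8, Vp = 1). With `n_env > 1`, each
#' environment adds independent noise of variance `env_var` on top of the
#' line value.
#'
#' @param geno a [genotype_matrix()] containing the QTN markers.
#' @param qtn a [qtn_spec()].
#' @param n_env number of environments.
#' @param env_var per-environment noise variance.
#' @param trait trait name for the output table.
#' @param seed RNG seed.
#' @return A phenotype table (line, trait, env, value) with attributes
#'   `genetic_values` (named vector) and `effects` (scaled per-QTN effects).
#' @export
simulate_phenotype <- function(geno, qtn, n_env = 1, env_var = 0,
                               trait = "trait1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- match(qtn$markers, geno$markers$marker_id)
  if (anyNA(idx)) stop("QTN markers absent from genotypes")
  D <- geno$dosage[, idx, drop = FALSE]
  D[is.na(D)] <- matrix(colMeans(D, na.rm = TRUE),
                        nrow(D), ncol(D), byrow = TRUE)[is.na(D)]
  eff <- if (!is.null(qtn$effects)) qtn$effects else qtn$signs * qtn$a^qtn$ranks
  g_add <- drop(D %*% eff)
  v_add <- stats::var(g_add)
  if (v_add <= 0) stop("QTN set carries no additive variance in this population")
  scale_add <- sqrt(qtn$h2 * qtn$Vp / v_add)
  g <- g_add * scale_add

  if (!is.null(qtn$epi_pairs) && qtn$epi_pve > 0) {
    P <- qtn$epi_pairs
    ia <- match(P[, 1], geno$markers$marker_id)
    ib <- match(P[, 2], geno$markers$marker_id)
    if (anyNA(ia) || anyNA(ib)) stop("epistatic markers absent from genotypes")
    Z <- sapply(seq_len(nrow(P)), function(k) {
      za <- geno$dosage[, ia[k]]
      zb <- geno$dosage[, ib[k]]
      za[is.na(za)] <- mean(za, na.rm = TRUE)
      zb[is.na(zb)] <- mean(zb, na.rm = TRUE)
      (za - mean(za)) * (zb - mean(zb))
    })
    g_epi <- rowSums(Z)
    v_epi <- stats::var(g_epi)
    if (v_epi > 0) g <- g + g_epi * sqrt(qtn$epi_pve * qtn$Vp / v_epi)
  }

  sd_e <- sqrt(max(1 - qtn$h2 - qtn$epi_pve, 0) * qtn$Vp)
  n <- length(g)
  line_value <- g + stats::rnorm(n, 0, sd_e)
  envs <- paste0("env", seq_len(n_env))
  tab <- do.call(rbind, lapply(seq_len(n_env), function(e) {
    data.frame(line = geno$samples, trait = trait, env = envs[e],
               value = line_value +
                 if (n_env > 1 || env_var > 0)
                   stats::rnorm(n, 0, sqrt(env_var)) else 0)
  }))
  out <- phenotype_table(tab)
  gv <- g
  names(gv) <- geno$samples
  attr(out, "genetic_values") <- gv
  attr(out, "effects") <- eff * scale_add
  out
}
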