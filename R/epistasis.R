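#' MAF and LD pruning before the epistasis scan
#'
#' Markers below the MAF cutoff are removed first; then a sliding-window
#' greedy pruning removes, within each window of `window_bp`, the later
#' member of any pair with r2 at or above `r2_max`, advancing the window
#' start by `step_snps` retained markers.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min minor allele frequency cutoff (default 0.02).
#' @param r2_max r2 at or above which the later marker is dropped
#'   (default 0.5).
#' @param window_bp window width in bp (default 50 kb).
#' @param step_snps SNPs stepped between windows (default 5).
#' @return pruned [genotype_matrix()].
#' @export
prune_variants <- function(geno, maf_min = 0.02, r2_max = 0.5,
                           window_bp = 50000, step_snps = 5) {
  maf <- marker_maf(geno)
  geno <- subset_genotypes(geno, markers = which(!is.na(maf) & maf >= maf_min))
  m <- geno$markers
  keep <- rep(TRUE, nrow(m))
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    start <- 1L
    while (start <= length(idx)) {
      live <- idx[keep[idx]]
      if (length(live) == 0) break
      if (start > length(live)) break
      w0 <- live[start]
      win <- live[live >= w0 &
                  m$pos_bp[live] < m$pos_bp[w0] + window_bp]
      if (length(win) > 1) {
        for (a in seq_along(win)) {
          if (!keep[win[a]]) next
          for (b in seq_along(win)) {
            if (b <= a || !keep[win[b]]) next
            if (marker_r2(geno, win[a], win[b]) >= r2_max) {
              keep[win[b]] <- FALSE
            }
          }
        }
      }
      start <- start + step_snps
    }
  }
  subset_genotypes(geno, markers = which(keep))
}

# closed-form interaction t-test for y ~ 1 + ga + gb + ga*gb
interaction_test <- function(y, ga, gb) {
  X <- cbind(1, ga, gb, ga * gb)
  fit <- stats::.lm.fit(X, y)
  df <- length(y) - 4
  if (df <= 0 || fit$rank < 4) return(c(beta = NA_real_, p = NA_real_))
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / df * XtXinv[4, 4])
  tstat <- fit$coefficients[4] / se
  c(beta = fit$coefficients[4], p = 2 * stats::pt(-abs(tstat), df))
}

#' Genome-wide pairwise interaction scan
#'
#' Every marker pair is tested with the 1-df interaction term of the linear
#' model y ~ gA + gB + gA:gB on dosages. Pairs with P above `first_pass_p`
#' are discarded; among surviving pairs whose two endpoints both lie within
#' `dedup_bp` of an already-retained (more significant) pair, only the most
#' significant representative is kept.
#'
#' @param geno a (pruned) [genotype_matrix()].
#' @param y named line values.
#' @param first_pass_p first-stage P cutoff (default 6e-16, i.e. roughly
#'   0.01 / Ne^2).
#' @param dedup_bp locus-uniqueness radius (default 100 kb).
#' @return data.frame of raw pairs: marker_a, marker_b, chrom/pos for both,
#'   beta_int, raw_p.
#' @export
pairwise_scan <- function(geno, y, first_pass_p = 6e-16, dedup_bp = 1e5) {
  if (!is.null(names(y))) y <- y[geno$samples]
  D <- geno$dosage
  D[is.na(D)] <- matrix(colMeans(D, na.rm = TRUE),
                        nrow(D), ncol(D), byrow = TRUE)[is.na(D)]
  S <- ncol(D)
  poly <- apply(D, 2, stats::sd) > 0
  res <- list()
  k <- 1L
  for (a in seq_len(S - 1)) {
    if (!poly[a]) next
    for (b in (a + 1):S) {
      if (!poly[b]) next
      r <- interaction_test(y, D[, a], D[, b])
      if (!is.na(r[["p"]]) && r[["p"]] <= first_pass_p) {
        res[[k]] <- c(a = a, b = b, beta = r[["beta"]], p = r[["p"]])
        k <- k + 1L
      }
    }
  }
  if (length(res) == 0) {
    return(empty_pairs())
  }
  tab <- as.data.frame(do.call(rbind, res))
  m <- geno$markers
  out <- data.frame(marker_a = m$marker_id[tab$a], marker_b = m$marker_id[tab$b],
                    chrom_a = m$chrom[tab$a], pos_a = m$pos_bp[tab$a],
                    chrom_b = m$chrom[tab$b], pos_b = m$pos_bp[tab$b],
                    beta_int = tab$beta, raw_p = tab$p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$raw_p), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    prior <- which(keep[seq_len(i - 1)])
    near <- out$chrom_a[prior] == out$chrom_a[i] &
      abs(out$pos_a[prior] - out$pos_a[i]) <= dedup_bp &
      out$chrom_b[prior] == out$chrom_b[i] &
      abs(out$pos_b[prior] - out$pos_b[i]) <= dedup_bp
    if (any(near)) keep[i] <- FALSE
  }
  out <- out[keep, ]
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(marker_a = character(0), marker_b = character(0),
             chrom_a = character(0), pos_a = numeric(0),
             chrom_b = character(0), pos_b = numeric(0),
             beta_int = numeric(0), raw_p = numeric(0),
             stringsAsFactors = FALSE)
}

#' Adjust raw interaction pairs for population structure and additive effects
#'
#' Each surviving pair is refit as y ~ PCs + gA + gB + gA:gB; the adjusted P
#' is the interaction-term test and the pair PVE is the incremental R2 of
#' the interaction term over the additive + structure model. Pairs with
#' adjusted P below `final_p` are kept.
#'
#' @param pairs output of [pairwise_scan()].
#' @param geno the [genotype_matrix()] holding the markers.
#' @param y named line values.
#' @param pcs optional PC covariates.
#' @param final_p adjusted-P cutoff (default 1e-12).
#' @return data.frame: pairs columns plus adj_p and pve; only significant
#'   pairs (rank-deficient fits are dropped with a message).
#' @export
adjust_pairs <- function(pairs, geno, y, pcs = NULL, final_p = 1e-12) {
  if (!is.null(names(y))) y <- y[geno$samples]
  if (nrow(pairs) == 0) {
    out <- cbind(pairs, adj_p = numeric(0), pve = numeric(0))
    return(out)
  }
  D <- geno$dosage
  D[is.na(D)] <- matrix(colMeans(D, na.rm = TRUE),
                        nrow(D), ncol(D), byrow = TRUE)[is.na(D)]
  adj_p <- pve <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- D[, match(pairs$marker_a[i], geno$markers$marker_id)]
    gb <- D[, match(pairs$marker_b[i], geno$markers$marker_id)]
    X0 <- cbind(1, pcs, ga, gb)
    X1 <- cbind(X0, ga * gb)
    f0 <- stats::.lm.fit(X0, y)
    f1 <- stats::.lm.fit(X1, y)
    if (f1$rank < ncol(X1)) {
      message("adjust_pairs: rank-deficient fit, dropping pair ", i)
      next
    }
    df <- length(y) - ncol(X1)
    rss0 <- sum(f0$residuals^2)
    rss1 <- sum(f1$residuals^2)
    fstat <- (rss0 - rss1) / (rss1 / df)
    adj_p[i] <- stats::pf(fstat, 1, df, lower.tail = FALSE)
    pve[i] <- (rss0 - rss1) / sum((y - mean(y))^2)
  }
  out <- cbind(pairs, adj_p = adj_p, pve = pve)
  out <- out[!is.na(out$adj_p) & out$adj_p < final_p, ]
  rownames(out) <- NULL
  out
}

#' Trait variance jointly explained by all epistatic interactions
#'
#' Population structure and the additive effects of all involved markers are
#' regressed out of the phenotype first; the joint epistatic variance is the
#' R2 of the residuals on all interaction product terms together. When more
#' interaction terms than n/2 survive, only the most significant (by
#' adjusted P) are retained with a warning.
#'
#' @param pairs adjusted pairs from [adjust_pairs()].
#' @param geno the [genotype_matrix()].
#' @param y named line values.
#' @param pcs optional PC covariates.
#' @param h2 optional heritability; when given, the fraction of h2 is also
#'   reported.
#' @return list with `r2` (joint epistatic variance fraction), `n_terms`,
#'   and optionally `frac_h2`.
#' @export
joint_epistatic_variance <- function(pairs, geno, y, pcs = NULL, h2 = NULL) {
  if (!is.null(names(y))) y <- y[geno$samples]
  if (nrow(pairs) == 0) {
    out <- list(r2 = 0, n_terms = 0L)
    if (!is.null(h2)) out$frac_h2 <- 0
    return(out)
  }
  if (!is.null(pairs$adj_p) && nrow(pairs) > length(y) / 2) {
    warning("more interaction terms than n/2: keeping the most significant")
    pairs <- pairs[order(pairs$adj_p), ][seq_len(floor(length(y) / 2)), ]
  }
  D <- geno$dosage
  D[is.na(D)] <- matrix(colMeans(D, na.rm = TRUE),
                        nrow(D), ncol(D), byrow = TRUE)[is.na(D)]
  mid <- geno$markers$marker_id
  mk <- unique(c(pairs$marker_a, pairs$marker_b))
  A <- D[, match(mk, mid), drop = FALSE]
  X0 <- cbind(1, pcs, A)
  resid <- stats::.lm.fit(X0, y)$residuals
  Zint <- sapply(seq_len(nrow(pairs)), function(i) {
    ga <- D[, match(pairs$marker_a[i], mid)]
    gb <- D[, match(pairs$marker_b[i], mid)]
    (ga - mean(ga)) * (gb - mean(gb))
  })
  Zint <- as.matrix(Zint)
  fit <- stats::lm(resid ~ Zint)
  # variance captured by the interaction terms as a fraction of the total
  # phenotypic variance (not of the residualized variance)
  ve <- (sum(resid^2) - sum(stats::residuals(fit)^2)) /
    sum((y - mean(y))^2)
  out <- list(r2 = ve, n_terms = ncol(Zint))
  if (!is.null(h2)) out$frac_h2 <- out$r2 / h2
  out
}

#' Categorise interaction pairs by linkage with the sQTL catalog
#'
#' A side of a pair is "linked" when it falls within `link_bp` of an sQTL
#' interval. Categories: SS-1 (both sides linked to sQTL of the same trait),
#' SS-2 (both linked, different traits only), SN (one side linked), NN
#' (neither).
#'
#' @param pairs adjusted pairs.
#' @param sqtl an sQTL catalog (possibly several traits concatenated) with
#'   columns trait, chrom, start_bp, end_bp.
#' @param link_bp linkage radius (default 50 kb).
#' @return list with `pairs` (input plus `category`) and `fractions` (named
#'   vector over SS-1, SS-2, SN, NN).
#' @export
categorize_pairs <- function(pairs, sqtl, link_bp = 50000) {
  linked_traits <- function(ch, pos) {
    hit <- sqtl$chrom == ch & pos >= sqtl$start_bp - link_bp &
      pos <= sqtl$end_bp + link_bp
    unique(sqtl$trait[hit])
  }
  cat <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ta <- linked_traits(pairs$chrom_a[i], pairs$pos_a[i])
    tb <- linked_traits(pairs$chrom_b[i], pairs$pos_b[i])
    cat[i] <- if (length(ta) && length(tb)) {
      if (length(intersect(ta, tb))) "SS-1" else "SS-2"
    } else if (length(ta) || length(tb)) "SN" else "NN"
  }
  pairs$category <- cat
  frac <- table(factor(cat, levels = c("SS-1", "SS-2", "SN", "NN")))
  frac <- as.numeric(frac) / max(nrow(pairs), 1)
  names(frac) <- c("SS-1", "SS-2", "SN", "NN")
  list(pairs = pairs, fractions = frac)
}

#' Recombinant fraction across a pair of loci
#'
#' Fraction of lines whose founder origins at the two loci differ (i.e.
#' descend from different founders), a diagnostic comparing interacting pairs
#' against matched random distal pairs.
#'
#' @param bins a [build_bins()] result.
#' @param bin_a,bin_b bin IDs.
#' @return fraction in \[0, 1\] over lines non-UNKNOWN at both bins.
#' @export
recombinant_fraction <- function(bins, bin_a, bin_b) {
  ia <- match(bin_a, bins$bins$bin_id)
  ib <- match(bin_b, bins$bins$bin_id)
  a <- bins$states[, ia]
  b <- bins$states[, ib]
  ok <- !is.na(a) & !is.na(b)
  mean(a[ok] != b[ok])
}
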