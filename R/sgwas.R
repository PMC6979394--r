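#' Bonferroni-style significance threshold from an effective test number
#'
#' @param alpha genome-wide type-I error rate in (0, 1).
#' @param n_eff effective number of independent tests (>= 1).
#' @return per-test threshold alpha / n_eff.
#' @export
significance_threshold <- function(alpha = 0.05, n_eff) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_eff < 1) stop("n_eff must be >= 1")
  alpha / n_eff
}

#' Single-variant mixed-model association scan
#'
#' Mixed linear model y = X beta + g b + u + e with u ~ N(0, sg2 K),
#' relatedness-corrected and with optional PC covariates. Variance components
#' are estimated once under the null model (no marker) by REML on the
#' eigenbasis of K, then held fixed for per-marker generalized least squares
#' (the P3D/EMMAX approximation); Wald t-tests give per-marker P-values.
#' Markers below the MAF cutoff are skipped; missing dosages are mean-imputed.
#'
#' @param geno a [genotype_matrix()].
#' @param y named numeric vector of line values (e.g. BLUPs), aligned to
#'   `geno$samples` by name when named.
#' @param K kinship matrix (default [snp_kinship()] of `geno`).
#' @param pcs optional PC score matrix used as fixed covariates.
#' @param maf_min minor allele frequency cutoff (default 0.02).
#' @param exact refit variance components for every marker (slow exact LMM)
#'   instead of the P3D approximation.
#' @return data.frame of class `assoc_result`: marker_id, chrom, pos_bp, maf,
#'   beta, se, p (NA for skipped markers), beta_sd (effect in trait SD
#'   units); the null fit is attached as attribute `null_fit`.
#' @export
lmm_scan <- function(geno, y, K = NULL, pcs = NULL, maf_min = 0.02,
                     exact = FALSE) {
  if (!is.null(names(y))) y <- y[geno$samples]
  if (anyNA(y)) stop("phenotype missing for some tested lines")
  n <- length(y)
  if (is.null(K)) K <- snp_kinship(geno)
  X <- cbind(`(Intercept)` = rep(1, n), pcs)
  p <- ncol(X)
  null <- lmm_null_fit(y, X, K)

  maf <- marker_maf(geno)
  test <- which(!is.na(maf) & maf >= maf_min)
  D <- geno$dosage[, test, drop = FALSE]
  D[is.na(D)] <- matrix(colMeans(D, na.rm = TRUE),
                        nrow(D), ncol(D), byrow = TRUE)[is.na(D)]

  S <- length(test)
  beta <- se <- pv <- rep(NA_real_, nrow(geno$markers))
  if (S > 0 && !exact) {
    sw <- 1 / sqrt(null$lambda + null$delta)
    yw <- drop(crossprod(null$U, y)) * sw
    Xw <- crossprod(null$U, X) * sw
    Gw <- crossprod(null$U, D) * sw
    qr_x <- qr(Xw)
    ry <- qr.resid(qr_x, yw)
    RG <- qr.resid(qr_x, Gw)
    gg <- colSums(RG^2)
    gy <- drop(crossprod(RG, ry))
    ok <- gg > 1e-12
    b <- gy[ok] / gg[ok]
    df <- n - p - 1
    s2 <- (sum(ry^2) - b^2 * gg[ok]) / df
    sehat <- sqrt(pmax(s2, 0) / gg[ok])
    tstat <- b / sehat
    beta[test[ok]] <- b
    se[test[ok]] <- sehat
    pv[test[ok]] <- 2 * stats::pt(-abs(tstat), df)
  } else if (S > 0) {
    for (j in seq_len(S)) {
      fit <- lmm_null_fit(y, cbind(X, g = D[, j]), K)
      bj <- fit$beta[p + 1]
      sw <- 1 / sqrt(fit$lambda + fit$delta)
      Xw <- crossprod(fit$U, cbind(X, g = D[, j])) * sw
      covb <- solve(crossprod(Xw)) * fit$sigma_g2
      sj <- sqrt(covb[p + 1, p + 1])
      beta[test[j]] <- bj
      se[test[j]] <- sj
      pv[test[j]] <- 2 * stats::pt(-abs(bj / sj), n - p - 1)
    }
  }

  out <- data.frame(marker_id = geno$markers$marker_id,
                    chrom = geno$markers$chrom,
                    pos_bp = geno$markers$pos_bp,
                    maf = maf, beta = beta, se = se, p = pv,
                    beta_sd = beta / stats::sd(y),
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  attr(out, "null_fit") <- null
  attr(out, "n_pcs") <- if (is.null(pcs)) 0L else ncol(pcs)
  out
}

#' Squared dosage correlation between two markers
#' @param geno a [genotype_matrix()].
#' @param i,j marker indices or marker IDs.
#' @return r-squared over lines complete for both markers.
#' @export
marker_r2 <- function(geno, i, j) {
  if (is.character(i)) i <- match(i, geno$markers$marker_id)
  if (is.character(j)) j <- match(j, geno$markers$marker_id)
  a <- geno$dosage[, i]
  b <- geno$dosage[, j]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(0)
  stats::cor(a[ok], b[ok])^2
}

#' Group significant SNPs into QTL
#'
#' Implements the locus rules of a dense single-variant scan: (1) significant
#' SNPs on a chromosome are chained whenever consecutive SNPs are closer than
#' `gap_bp`; (2) chains with fewer than `min_snps` members are dropped; (3)
#' adjacent loci are merged when any pair of their significant SNPs is in LD
#' (r2 >= `ld_merge_r2`); (4) loci narrower than `small_span` whose peak P is
#' below `threshold / strong_factor` are extended by `extend_bp` on both
#' sides.
#'
#' @param assoc an `assoc_result` from [lmm_scan()].
#' @param geno the [genotype_matrix()] used for the scan (for r2).
#' @param threshold genome-wide significance threshold on P.
#' @param gap_bp chaining gap (default 20 kb).
#' @param min_snps minimum significant SNPs per locus (default 2).
#' @param ld_merge_r2 r2 cutoff for merging adjacent loci (default 0.2).
#' @param extend_bp extension applied to narrow strong loci (default 25 kb).
#' @param small_span span below which the extension applies (default 50 kb).
#' @param strong_factor peak-P multiplier gating the extension (default 100).
#' @param trait optional trait label carried into the output.
#' @return data.frame of sQTL records: trait, chrom, start_bp, end_bp,
#'   peak_marker, peak_pos, peak_p, n_snps; member markers as attribute
#'   `members` (list).
#' @export
group_sqtl <- function(assoc, geno, threshold = 1.23e-8, gap_bp = 20000,
                       min_snps = 2, ld_merge_r2 = 0.2, extend_bp = 25000,
                       small_span = 50000, strong_factor = 100,
                       trait = "trait1") {
  sig <- assoc[!is.na(assoc$p) & assoc$p <= threshold, ]
  loci <- list()
  members <- list()
  if (nrow(sig) > 0) {
    for (ch in unique(sig$chrom)) {
      s <- sig[sig$chrom == ch, ]
      s <- s[order(s$pos_bp), ]
      grp <- cumsum(c(1, diff(s$pos_bp) >= gap_bp))
      for (g in unique(grp)) {
        m <- s[grp == g, ]
        if (nrow(m) < min_snps) next
        loci[[length(loci) + 1]] <-
          data.frame(chrom = ch, start_bp = min(m$pos_bp),
                     end_bp = max(m$pos_bp),
                     peak_marker = m$marker_id[which.min(m$p)],
                     peak_pos = m$pos_bp[which.min(m$p)],
                     peak_p = min(m$p), n_snps = nrow(m))
        members[[length(members) + 1]] <- m$marker_id
      }
    }
  }
  if (length(loci) == 0) {
    out <- data.frame(trait = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      peak_marker = character(0), peak_pos = numeric(0),
                      peak_p = numeric(0), n_snps = integer(0))
    attr(out, "members") <- list()
    class(out) <- c("sqtl_set", "data.frame")
    return(out)
  }
  tab <- do.call(rbind, loci)
  ord <- order(tab$chrom, tab$start_bp)
  tab <- tab[ord, ]
  members <- members[ord]

  # merge adjacent loci in LD until stable
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(tab)) {
      if (tab$chrom[i] == tab$chrom[i + 1]) {
        pairs_r2 <- outer(members[[i]], members[[i + 1]],
                          Vectorize(function(a, b) marker_r2(geno, a, b)))
        if (max(pairs_r2) >= ld_merge_r2) {
          tab$start_bp[i] <- min(tab$start_bp[i], tab$start_bp[i + 1])
          tab$end_bp[i] <- max(tab$end_bp[i], tab$end_bp[i + 1])
          if (tab$peak_p[i + 1] < tab$peak_p[i]) {
            tab$peak_p[i] <- tab$peak_p[i + 1]
            tab$peak_marker[i] <- tab$peak_marker[i + 1]
            tab$peak_pos[i] <- tab$peak_pos[i + 1]
          }
          tab$n_snps[i] <- tab$n_snps[i] + tab$n_snps[i + 1]
          members[[i]] <- c(members[[i]], members[[i + 1]])
          tab <- tab[-(i + 1), ]
          members <- members[-(i + 1)]
          merged <- TRUE
          next
        }
      }
      i <- i + 1
    }
    if (!merged) break
  }

  narrow <- (tab$end_bp - tab$start_bp) < small_span &
    tab$peak_p < threshold / strong_factor
  tab$start_bp[narrow] <- pmax(tab$start_bp[narrow] - extend_bp, 1)
  tab$end_bp[narrow] <- tab$end_bp[narrow] + extend_bp

  tab <- cbind(trait = trait, tab)
  rownames(tab) <- NULL
  attr(tab, "members") <- members
  class(tab) <- c("sqtl_set", "data.frame")
  tab
}
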