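#' Partition trait heritability across the two QTL catalogs
#'
#' The sQTL component is the joint R2 of a multiple regression of the line
#' values on all sQTL peak dosages; the hQTL increment is the gain in joint
#' R2 when the hQTL peak-bin state factors are added. Both are expressed as
#' fractions of the broad-sense heritability; the remainder is what neither
#' catalog explains.
#'
#' @param sqtl_peaks data.frame of numeric peak dosage columns (may have 0
#'   columns).
#' @param hqtl_peaks data.frame of peak-bin state columns (factors/characters;
#'   may have 0 columns).
#' @param blup named line values.
#' @param h2 broad-sense heritability of the trait (> 0).
#' @return list: `sqtl_frac`, `hqtl_frac` (increment), `remainder`,
#'   `joint_r2`, plus raw R2 components.
#' @export
partition_heritability <- function(sqtl_peaks, hqtl_peaks, blup, h2) {
  if (h2 <= 0) stop("h2 must be positive")
  sqtl_peaks <- as.data.frame(sqtl_peaks)
  hqtl_peaks <- as.data.frame(hqtl_peaks)
  # bin states are categorical whatever their storage type
  for (j in seq_along(hqtl_peaks)) {
    hqtl_peaks[[j]] <- relevel_most_frequent(hqtl_peaks[[j]])
  }
  r2_of <- function(df) {
    if (ncol(df) == 0) return(0)
    for (j in seq_along(df)) {
      if (!is.numeric(df[[j]])) df[[j]] <- relevel_most_frequent(df[[j]])
    }
    summary(stats::lm(blup ~ ., data = df))$r.squared
  }
  r2_s <- r2_of(sqtl_peaks)
  r2_sh <- r2_of(cbind(sqtl_peaks, hqtl_peaks))
  sfrac <- min(r2_s / h2, 1)
  hfrac <- max(min((r2_sh - r2_s) / h2, 1 - sfrac), 0)
  list(sqtl_frac = sfrac, hqtl_frac = hfrac,
       remainder = max(1 - sfrac - hfrac, 0),
       r2_sqtl = r2_s, joint_r2 = r2_sh)
}

#' Co-localisation counts between the two QTL catalogs
#'
#' Physical-interval overlap per trait (at least `min_overlap_bp` shared
#' base pairs), summed over traits.
#'
#' @param sqtl,hqtl catalogs with columns trait, chrom, start_bp, end_bp.
#' @param min_overlap_bp minimum shared span to call an overlap (default 1).
#' @return named vector: s_only, shared (overlapping pairs), h_only.
#' @export
colocalize <- function(sqtl, hqtl, min_overlap_bp = 1) {
  s_hit <- rep(FALSE, nrow(sqtl))
  h_hit <- rep(FALSE, nrow(hqtl))
  shared <- 0L
  for (i in seq_len(nrow(sqtl))) {
    for (j in seq_len(nrow(hqtl))) {
      if (sqtl$trait[i] != hqtl$trait[j]) next
      if (sqtl$chrom[i] != hqtl$chrom[j]) next
      ov <- min(sqtl$end_bp[i], hqtl$end_bp[j]) -
        max(sqtl$start_bp[i], hqtl$start_bp[j]) + 1
      if (ov >= min_overlap_bp) {
        shared <- shared + 1L
        s_hit[i] <- TRUE
        h_hit[j] <- TRUE
      }
    }
  }
  c(s_only = sum(!s_hit), shared = shared, h_only = sum(!h_hit))
}

#' Assemble a per-trait summary record
#'
#' @param trait trait name.
#' @param h2 broad-sense heritability.
#' @param sqtl,hqtl catalogs for the trait.
#' @param partition output of [partition_heritability()].
#' @param epi_r2 joint epistatic variance fraction (of phenotypic variance).
#' @return one-row data.frame of class `trait_summary`.
#' @export
trait_summary <- function(trait, h2, sqtl, hqtl, partition, epi_r2 = 0) {
  out <- data.frame(trait = trait, h2 = h2,
                    n_sqtl = nrow(sqtl), n_hqtl = nrow(hqtl),
                    sqtl_frac_h2 = partition$sqtl_frac,
                    hqtl_frac_h2 = partition$hqtl_frac,
                    unexplained_frac_h2 = partition$remainder,
                    epi_frac_h2 = if (h2 > 0) epi_r2 / h2 else NA_real_)
  class(out) <- c("trait_summary", "data.frame")
  out
}
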