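#' Construct a founder panel
#'
#' Haploid representation of fully homozygous founder lines: an F x S matrix
#' of alleles in \{0, 1\} over the markers of a genetic map.
#'
#' @param alleles integer matrix founders x markers with values 0/1.
#' @param map the [genetic_map()] the marker columns refer to.
#' @param founder_ids character vector of founder names.
#' @return A `founder_panel` object: list(alleles, map, founder_ids).
#' @export
founder_panel <- function(alleles, map, founder_ids = rownames(alleles)) {
  alleles <- as.matrix(alleles)
  stopifnot(ncol(alleles) == nrow(map), nrow(alleles) >= 2,
            all(alleles %in% c(0L, 1L)))
  if (is.null(founder_ids)) founder_ids <- paste0("F", seq_len(nrow(alleles)))
  dimnames(alleles) <- list(founder_ids, map$marker_id)
  structure(list(alleles = alleles, map = map, founder_ids = founder_ids),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("founder_panel: %d founders x %d markers\n",
              nrow(x$alleles), ncol(x$alleles)))
  invisible(x)
}

#' Simulate a homozygous founder panel
#'
#' Alleles are drawn per site so that the expected pairwise founder difference
#' rate equals `divergence`: with F founders, a site where k founders carry
#' the minor allele contributes 2k(F-k)/(F(F-1)) to the pairwise difference
#' rate, so k is solved from the target and rounded stochastically (the
#' default `"balanced"` law). A user function `maf_law(n_sites, n_founders)`
#' returning per-site minor-founder counts may be supplied instead, in which
#' case `divergence` is ignored.
#'
#' The attainable divergence is bounded by k = F/2: 1 for two founders and
#' about 0.52 for 24 founders.
#'
#' With `ld_block_bp` set, carrier sets persist along the chromosome in
#' haplotype blocks: each site either redraws a fresh carrier set (with
#' probability 1 - exp(-d/ld_block_bp) over the distance d to the previous
#' marker) or inherits the previous set, swapping one member with
#' probability `swap_prob`. This emulates the local LD of real inbred
#' founder panels (per-site allele frequencies are unchanged); by default
#' sites are independent.
#'
#' @param n_founders number of founders (>= 2).
#' @param map a [genetic_map()] providing the marker scaffold.
#' @param divergence target expected pairwise difference rate in \[0, 1\].
#' @param maf_law `"balanced"` or a function (see Details).
#' @param ld_block_bp founder haplotype-block length scale in bp (NULL =
#'   independent sites).
#' @param swap_prob per-site carrier-swap probability within a persisting
#'   block.
#' @param seed RNG seed.
#' @return A [founder_panel()].
#' @export
simulate_founders <- function(n_founders = 24, map, divergence = 0.35,
                              maf_law = "balanced", ld_block_bp = NULL,
                              swap_prob = 0.5, seed = NULL) {
  stopifnot(n_founders >= 2, nrow(map) > 0)
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  F <- n_founders
  S <- nrow(map)
  if (is.function(maf_law)) {
    k <- maf_law(S, F)
    stopifnot(length(k) == S, all(k >= 0), all(k <= F))
  } else {
    dmax <- 2 * floor(F / 2) * ceiling(F / 2) / (F * (F - 1))
    if (divergence > dmax + 1e-12) {
      stop(sprintf("divergence %.3f unattainable with %d founders (max %.3f)",
                   divergence, F, dmax))
    }
    # solve 2k(F-k)/(F(F-1)) = divergence for the minor-side root
    disc <- F^2 - 2 * divergence * F * (F - 1)
    kreal <- (F - sqrt(max(disc, 0))) / 2
    kf <- floor(kreal)
    k <- kf + (stats::runif(S) < (kreal - kf))
  }
  alleles <- matrix(0L, F, S)
  if (is.null(ld_block_bp)) {
    carriers <- lapply(k, function(ki)
      if (ki > 0) sample.int(F, ki) else integer(0))
  } else {
    carriers <- vector("list", S)
    prev_chrom <- ""
    for (s in seq_len(S)) {
      d <- if (map$chrom[s] == prev_chrom) {
        map$pos_bp[s] - map$pos_bp[s - 1]
      } else {
        Inf
      }
      fresh <- is.infinite(d) || stats::runif(1) > exp(-d / ld_block_bp)
      if (fresh || length(carriers[[s - 1]]) == 0) {
        carriers[[s]] <- if (k[s] > 0) sample.int(F, k[s]) else integer(0)
      } else {
        cs <- carriers[[s - 1]]
        if (stats::runif(1) < swap_prob && length(cs) < F) {
          out <- sample(seq_along(cs), 1)
          cs[out] <- sample(setdiff(seq_len(F), cs), 1)
        }
        carriers[[s]] <- cs
      }
      prev_chrom <- map$chrom[s]
    }
  }
  for (s in seq_len(S)) alleles[carriers[[s]], s] <- 1L
  founder_panel(alleles, map)
}

#' Observed pairwise founder difference rate
#' @param founders a [founder_panel()].
#' @return mean fraction of sites at which a random founder pair differs.
#' @export
founder_divergence <- function(founders) {
  A <- founders$alleles
  F <- nrow(A)
  k <- colSums(A)
  mean(2 * k * (F - k) / (F * (F - 1)))
}
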