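#' Simulate a study population for the mapping power comparison
#'
#' Convenience wrapper bundling the pieces the mapping power study needs: a
#' 24-founder panel on a two-chromosome genome (80 cM / 8 Mb / 3000 markers
#' per chromosome), an inter-cross pedigree population, its truth-derived
#' recombination bins and both kinships.
#'
#' @param n_lines progeny lines (default 500).
#' @param n_founders founders (default 24).
#' @param divergence founder panel divergence (default 0.35).
#' @param ld_block_bp founder haplotype-block scale passed to
#'   [simulate_founders()] (default 30 kb, so nearby markers show the local
#'   LD that incompletely linked QTNs require).
#' @param seed RNG seed.
#' @return list with `map`, `founders`, `geno`, `truth`, `bins`, `K_snp`,
#'   `K_bin`.
#' @export
mapping_study_population <- function(n_lines = 500, n_founders = 24,
                                     divergence = 0.35, ld_block_bp = 30000,
                                     seed = NULL) {
  m1 <- synthetic_map(1, 200, 2e7, 4000)
  m2 <- synthetic_map(1, 50, 5e6, 1000)
  m2$chrom <- "chr2"
  map <- genetic_map(rbind(as.data.frame(m1)[, c("chrom", "pos_bp", "pos_cM")],
                           as.data.frame(m2)[, c("chrom", "pos_bp", "pos_cM")]),
                     chrom_len = c(chr1 = 2e7, chr2 = 5e6))
  founders <- simulate_founders(n_founders, map, divergence = divergence,
                                ld_block_bp = ld_block_bp, seed = seed)
  pop <- simulate_pedigree_population(founders, n_lines = n_lines,
                                      seed = if (is.null(seed)) NULL
                                             else seed + 1)
  bins <- build_bins(pop$truth)
  list(map = map, founders = founders, geno = pop$genotypes,
       truth = pop$truth, bins = bins,
       K_snp = snp_kinship(pop$genotypes), K_bin = bin_kinship(bins))
}

#' Founder-tracing power study on pseudoprogeny
#'
#' Full loop of the HMM power evaluation: simulate pseudoprogeny lines by
#' reshuffling founder genomes (fixed segment count per line, breakpoints
#' placed by local recombination density), project their SNP genotypes, run
#' the founder-tracing HMM, and score the fraction of SNPs whose inferred
#' founder origin matches the simulated truth.
#'
#' @param founders a [founder_panel()] (e.g. from [simulate_founders()]).
#' @param map the [genetic_map()] (defaults to the panel's map).
#' @param n_lines pseudoprogeny lines (default 100).
#' @param n_segments recombinant segments per line (default 180).
#' @param params [hmm_params()] (default G = 9).
#' @param seed RNG seed.
#' @return list with `overall` and `per_chrom` power, `per_line` fractions,
#'   and `breakpoints` (truth vs inferred segment counts per line).
#' @export
run_hmm_power_study <- function(founders, map = founders$map, n_lines = 100,
                                n_segments = 180, params = hmm_params(),
                                seed = NULL) {
  sim <- simulate_pseudoprogeny(founders, map, n_lines = n_lines,
                                n_segments = n_segments, seed = seed)
  fit <- fit_mosaic(sim$genotypes, founders, map, params)
  pw <- tracing_power(sim$truth, fit$mosaic, map)
  bk <- data.frame(line = names(segments_per_line(sim$truth)),
                   truth = as.integer(segments_per_line(sim$truth)),
                   inferred = as.integer(
                     segments_per_line(fit$mosaic)[names(segments_per_line(sim$truth))]))
  c(pw, list(breakpoints = bk, mosaic = fit$mosaic, truth = sim$truth))
}

# pick k markers at one QTL (the bin, extended by extend_bp for linked QTNs)
# whose pairwise dosage r2 falls in the band; exhaustive pair/greedy triple
# search over the local candidates
pick_qtn_markers <- function(geno, bins, bin_idx, k, r2_band = c(0.3, 0.9),
                             extend_bp = 15000, max_cand = 30) {
  b <- bins$bins[bin_idx, ]
  ext <- if (k == 1) 0 else extend_bp
  cand <- which(geno$markers$chrom == b$chrom &
                geno$markers$pos_bp >= b$start_bp - ext &
                geno$markers$pos_bp <= b$end_bp + ext)
  maf <- marker_maf(geno)
  cand <- cand[!is.na(maf[cand]) & maf[cand] >= 0.05]
  if (length(cand) < k) return(NULL)
  if (k == 1) return(cand[sample.int(length(cand), 1)])
  if (length(cand) > max_cand) cand <- sort(sample(cand, max_cand))
  D <- geno$dosage[, cand, drop = FALSE]
  D[is.na(D)] <- matrix(colMeans(D, na.rm = TRUE),
                        nrow(D), ncol(D), byrow = TRUE)[is.na(D)]
  R2 <- suppressWarnings(stats::cor(D))^2
  R2[is.na(R2)] <- 0
  in_band <- R2 >= r2_band[1] & R2 <= r2_band[2]
  diag(in_band) <- FALSE
  pairs <- which(in_band & upper.tri(in_band), arr.ind = TRUE)
  if (nrow(pairs) == 0) return(NULL)
  pairs <- pairs[sample(nrow(pairs)), , drop = FALSE]
  if (k == 2) return(cand[as.integer(pairs[1, ])])
  # triples form a linkage chain (adjacent pairs in the band, outer pair
  # weaker) so the series carries two semi-independent repulsion contrasts
  weak <- R2 < r2_band[1]
  for (pi in seq_len(nrow(pairs))) {
    i <- pairs[pi, 1]
    j <- pairs[pi, 2]
    third <- setdiff(which((in_band[, i] & weak[, j]) |
                           (in_band[, j] & weak[, i])), c(i, j))
    if (length(third)) {
      return(cand[sort(c(i, j, third[sample.int(length(third), 1)]))])
    }
  }
  for (pi in seq_len(nrow(pairs))) {
    i <- pairs[pi, 1]
    j <- pairs[pi, 2]
    third <- setdiff(which(in_band[, i] & in_band[, j]), c(i, j))
    if (length(third)) {
      return(cand[sort(c(i, j, third[sample.int(length(third), 1)]))])
    }
  }
  NULL
}

# repulsion-phase effect direction for a set of linked QTNs: the minor
# eigenvector of their dosage correlation matrix. For two equally
# correlated QTNs this is (1, -1)/sqrt(2) (classic repulsion linkage); in
# general it is the allele combination least visible to any single-marker
# regression, while the founder-state (bin) term retains the full variance.
qtn_repulsion_weights <- function(geno, markers, n_try = 15) {
  k <- length(markers)
  if (k == 1) return(1)
  D <- geno$dosage[, markers, drop = FALSE]
  D[is.na(D)] <- matrix(colMeans(D, na.rm = TRUE),
                        nrow(D), ncol(D), byrow = TRUE)[is.na(D)]
  R <- stats::cor(D)
  eg <- eigen(R, symmetric = TRUE)
  w <- eg$vectors[, k]
  if (k >= 3) {
    # search the span of the two smallest eigenvectors for the masked
    # direction whose allele classes participate most evenly, so the
    # series spreads over several functional alleles instead of isolating
    # one haplotype
    E <- eg$vectors[, c(k, k - 1)]
    Dc <- scale(D, scale = FALSE)
    grp <- do.call(paste, as.data.frame(D))
    best <- -Inf
    for (t in seq_len(n_try)) {
      cc <- stats::rnorm(2)
      cc <- cc / sqrt(sum(cc^2))
      cand_w <- drop(E %*% cc)
      marg <- max(abs(R %*% cand_w))
      if (marg > max(0.45, eg$values[k] + 0.15)) next
      v <- drop(Dc %*% cand_w)
      m <- tapply(v, grp, mean)
      n_g <- table(grp)
      contrib <- as.numeric(n_g) * (m - stats::weighted.mean(m, n_g))^2
      p <- contrib / sum(contrib)
      p <- p[p > 1e-12]
      score <- exp(-sum(p * log(p)))
      if (score > best) {
        best <- score
        w <- cand_w
      }
    }
  }
  if (w[1] < 0) w <- -w
  w
}

#' Mapping power and FDR of the two scan types under allelic-series QTL
#'
#' Reproduces the in-silico comparison of single-variant and bin-haplotype
#' mapping: each replicate plants 30 causal bins on chromosome 1 — 10
#' biallelic (1 QTN), 10 four-allelic (2 incompletely linked QTNs) and 10
#' nine-allelic (3 QTNs) — with additive effect magnitudes following the
#' geometric series a^n (a = 0.95, ranks 1..30 assigned to bins round-robin
#' across the three scenarios; every QTN in a bin carries the bin's
#' magnitude, with signs alternating within a bin). Phenotypes are simulated
#' at h2 = 0.8, Vp = 1; both scans are run and detections are scored within
#' `window_bp` of the causal bin. Power is the per-scenario fraction of
#' causal QTL detected; FDR the fraction of declared loci not near any
#' causal bin.
#'
#' @param geno population [genotype_matrix()].
#' @param bins [build_bins()] result for the same lines.
#' @param K_snp,K_bin kinships (computed when NULL).
#' @param pcs PC covariates used in both scans.
#' @param n_replicates number of simulation replicates (default 200).
#' @param s_threshold single-variant significance threshold (default
#'   0.05 / number of tested markers).
#' @param h_cutoff bin-scan LRT cutoff (default: permutation threshold with
#'   `n_perm` shuffles, computed once).
#' @param n_perm permutations for the default cutoff.
#' @param window_bp detection window around the causal bin (default 1 Mb).
#' @param h2,Vp,a trait architecture parameters.
#' @param r2_band target dosage r2 band for linked QTNs within a bin.
#' @param allele_premium per-scenario multiplier on the a^(2n) variance
#'   series (default 1 / 2 / 3, i.e. proportional to the QTN count, since
#'   every functional variant at a locus carries an effect from the same
#'   series).
#' @param min_sep_bp minimum spacing between causal bins (default 500 kb =
#'   5 cM on the study genome), so neighbouring causal signals stay
#'   separable.
#' @param seed RNG seed.
#' @return data.frame of class `power_report`: scenario, method, power, fdr,
#'   n_causal, n_replicates, plus binomial 99% CI bounds for power.
#' @export
run_mapping_power_study <- function(geno, bins, K_snp = NULL, K_bin = NULL,
                                    pcs = NULL, n_replicates = 200,
                                    s_threshold = NULL, h_cutoff = NULL,
                                    n_perm = 300, window_bp = 1e6,
                                    h2 = 0.8, Vp = 1, a = 0.95,
                                    r2_band = c(0.3, 0.9),
                                    allele_premium = c(1, 2, 3),
                                    min_sep_bp = 5e5, seed = NULL) {
  if (n_replicates < 50) warning("fewer than 50 replicates: noisy estimates")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(K_snp)) K_snp <- snp_kinship(geno)
  if (is.null(K_bin)) K_bin <- bin_kinship(bins)
  maf <- marker_maf(geno)
  n_tested <- sum(!is.na(maf) & maf >= 0.02)
  if (is.null(s_threshold)) s_threshold <- 0.05 / n_tested
  chr1 <- unique(bins$bins$chrom)[1]
  if (is.null(h_cutoff)) {
    ynull <- stats::rnorm(length(geno$samples))
    names(ynull) <- geno$samples
    h_cutoff <- as.numeric(permutation_threshold(bins, ynull, K = K_bin,
                                                 pcs = pcs, n_perm = n_perm,
                                                 alpha = 0.05))
  }
  engine <- hgwas_engine(bins, stats::rnorm(length(geno$samples)),
                         K = K_bin, pcs = pcs)
  scen_k <- c(biallelic = 1L, four_allelic = 2L, nine_allelic = 3L)
  counts <- matrix(0, 3, 2, dimnames = list(names(scen_k), c("sgwas", "hgwas")))
  totals <- matrix(0, 3, 2, dimnames = dimnames(counts))
  false_cnt <- c(sgwas = 0, hgwas = 0)
  declared <- c(sgwas = 0, hgwas = 0)
  eligible <- which(bins$bins$chrom == chr1)

  for (rep_i in seq_len(n_replicates)) {
    # draw 30 causal bins on chromosome 1, one per equal-width slot so
    # causal loci stay separated; scenarios rotate across rank triplets so
    # mean effect ranks are equal
    scen_seq <- as.vector(vapply(seq_len(10), function(t)
      as.integer(((0:2) + t - 1) %% 3 + 1), integer(3)))
    span <- range(bins$bins$start_bp[eligible])
    slot_edges <- seq(span[1], span[2] + 1, length.out = 31)
    sel <- list()
    scen_of_bin <- integer(0)
    qtn <- list()
    ok_all <- TRUE
    for (si in seq_len(30L)) {
      k <- scen_k[scen_seq[si]]
      in_slot <- eligible[bins$bins$start_bp[eligible] >= slot_edges[si] &
                          bins$bins$start_bp[eligible] < slot_edges[si + 1]]
      mk <- NULL
      for (bidx in in_slot[sample.int(length(in_slot),
                                         min(length(in_slot), 25))]) {
        mk <- pick_qtn_markers(geno, bins, bidx, k, r2_band)
        if (!is.null(mk)) break
      }
      if (is.null(mk)) {
        ok_all <- FALSE
        break
      }
      sel[[si]] <- bidx
      scen_of_bin[si] <- scen_seq[si]
      qtn[[si]] <- mk
    }
    if (!ok_all) stop("could not place 30 causal bins; genome too small")
    causal_bins <- unlist(sel)
    markers <- unlist(qtn)
    # per-QTL variance follows the geometric series a^(2n) with a tempered
    # allelic-series premium q_k; each bin realises its variance through its
    # k repulsion-phase QTNs (signs alternate along the linkage chain)
    q_k <- allele_premium
    effects <- numeric(0)
    for (b in seq_len(30)) {
      mk <- qtn[[b]]
      sg <- qtn_repulsion_weights(geno, mk)
      Db <- geno$dosage[, mk, drop = FALSE]
      Db[is.na(Db)] <- matrix(colMeans(Db, na.rm = TRUE), nrow(Db),
                              ncol(Db), byrow = TRUE)[is.na(Db)]
      v <- stats::var(drop(Db %*% sg))
      target <- q_k[scen_of_bin[b]] * a^(2 * b)
      effects <- c(effects, sg * sqrt(target / max(v, 1e-8)))
    }
    spec <- qtn_spec(geno$markers$marker_id[markers],
                     ranks = rep(seq_len(30), lengths(qtn)),
                     effects = effects, a = a, h2 = h2, Vp = Vp)
    ph <- simulate_phenotype(geno, spec, n_env = 1)
    y <- stats::setNames(ph$value, ph$line)[geno$samples]

    assoc <- lmm_scan(geno, y, K = K_snp, pcs = pcs, maf_min = 0.02)
    hscan <- hgwas_scan(bins, y, engine = engine)

    sig_pos <- assoc$pos_bp[!is.na(assoc$p) & assoc$p <= s_threshold &
                            assoc$chrom == chr1]
    sig_any_chrom <- assoc[!is.na(assoc$p) & assoc$p <= s_threshold, ]
    hsig <- which(hscan$lrt >= h_cutoff)

    cb <- bins$bins[causal_bins, ]
    for (q in seq_len(30)) {
      scn <- scen_of_bin[q]
      totals[scn, ] <- totals[scn, ] + 1
      lo <- cb$start_bp[q] - window_bp
      hi <- cb$end_bp[q] + window_bp
      if (any(sig_pos >= lo & sig_pos <= hi)) {
        counts[scn, "sgwas"] <- counts[scn, "sgwas"] + 1
      }
      hit_bins <- hscan$chrom[hsig] == cb$chrom[q] &
        hscan$end_bp[hsig] >= lo & hscan$start_bp[hsig] <= hi
      if (any(hit_bins)) counts[scn, "hgwas"] <- counts[scn, "hgwas"] + 1
    }

    # FDR bookkeeping on declared loci
    sq <- group_sqtl(structure(sig_any_chrom,
                               class = c("assoc_result", "data.frame")),
                     geno, threshold = s_threshold, min_snps = 1)
    if (nrow(sq)) {
      declared["sgwas"] <- declared["sgwas"] + nrow(sq)
      near <- vapply(seq_len(nrow(sq)), function(i) {
        any(cb$chrom == sq$chrom[i] &
            cb$end_bp + window_bp >= sq$start_bp[i] &
            cb$start_bp - window_bp <= sq$end_bp[i])
      }, logical(1))
      false_cnt["sgwas"] <- false_cnt["sgwas"] + sum(!near)
    }
    hq <- merge_hqtl(hscan, h_cutoff)
    if (nrow(hq)) {
      declared["hgwas"] <- declared["hgwas"] + nrow(hq)
      near <- vapply(seq_len(nrow(hq)), function(i) {
        any(cb$chrom == hq$chrom[i] &
            cb$end_bp + window_bp >= hq$start_bp[i] &
            cb$start_bp - window_bp <= hq$end_bp[i])
      }, logical(1))
      false_cnt["hgwas"] <- false_cnt["hgwas"] + sum(!near)
    }
  }

  rows <- list()
  for (scn in 1:3) {
    for (meth in c("sgwas", "hgwas")) {
      x <- counts[scn, meth]
      ntot <- totals[scn, meth]
      ci <- stats::binom.test(x, ntot, conf.level = 0.99)$conf.int
      rows[[length(rows) + 1]] <-
        data.frame(scenario = rownames(counts)[scn], method = meth,
                   power = x / ntot, ci_lo = ci[1], ci_hi = ci[2],
                   n_causal = ntot,
                   fdr = unname(false_cnt[meth] / max(declared[meth], 1)),
                   n_replicates = n_replicates)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "s_threshold") <- s_threshold
  attr(out, "h_cutoff") <- h_cutoff
  class(out) <- c("power_report", "data.frame")
  out
}
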