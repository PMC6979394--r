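#' Major QTL eligible for linkage-like refinement
#'
#' A major QTL is a locus detected by both scan types for the same trait,
#' with both PVEs at or above `pve_min`; its region is the union of the sQTL
#' and hQTL intervals.
#'
#' @param sqtl sQTL catalog (trait, chrom, start_bp, end_bp, ... , pve).
#' @param hqtl hQTL catalog (same interval columns, plus peak_bin, pve).
#' @param pve_min PVE eligibility cutoff (default 0.10).
#' @return data.frame of regions: trait, chrom, start_bp, end_bp, peak_bin,
#'   sqtl_pve, hqtl_pve. Empty when nothing co-localises.
#' @export
define_major_qtl <- function(sqtl, hqtl, pve_min = 0.10) {
  out <- list()
  for (i in seq_len(nrow(sqtl))) {
    for (j in seq_len(nrow(hqtl))) {
      if (sqtl$trait[i] != hqtl$trait[j]) next
      if (sqtl$chrom[i] != hqtl$chrom[j]) next
      if (sqtl$end_bp[i] < hqtl$start_bp[j] ||
          hqtl$end_bp[j] < sqtl$start_bp[i]) next
      if (is.null(sqtl$pve) || is.null(hqtl$pve)) {
        stop("both catalogs need a pve column")
      }
      if (sqtl$pve[i] < pve_min || hqtl$pve[j] < pve_min) next
      out[[length(out) + 1]] <-
        data.frame(trait = sqtl$trait[i], chrom = sqtl$chrom[i],
                   start_bp = min(sqtl$start_bp[i], hqtl$start_bp[j]),
                   end_bp = max(sqtl$end_bp[i], hqtl$end_bp[j]),
                   peak_bin = hqtl$peak_bin[j],
                   sqtl_pve = sqtl$pve[i], hqtl_pve = hqtl$pve[j])
    }
  }
  if (length(out) == 0) {
    return(data.frame(trait = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      peak_bin = character(0), sqtl_pve = numeric(0),
                      hqtl_pve = numeric(0)))
  }
  do.call(rbind, out)
}

#' Collapse founder IBD groups into functional alleles
#'
#' Lines are grouped by founder state at the QTL peak bin and every pair of
#' founder groups is compared with a Welch t-test on the line phenotypes.
#' Groups are merged agglomeratively: the between-cluster p-value is the
#' largest group-pair p-value across the two clusters (single linkage, so
#' the comparisons always stay at the level of the original founder groups,
#' where the test is honest), and the pair of clusters with the largest such
#' p is joined until every between-cluster comparison is significant at
#' `p_collapse`. Equivalently, the functional alleles are the connected
#' components of the graph linking phenotypically indistinguishable founder
#' groups. Groups smaller than `min_n` lines are attached afterwards to the
#' cluster with the nearest phenotype mean.
#'
#' @param states founder state per line at the peak bin (integer, NA =
#'   UNKNOWN), named by line.
#' @param pheno named line values (BLUPs).
#' @param p_collapse significance level separating clusters (default 0.05).
#' @param min_n minimum group size entering the clustering (default 2).
#' @return list with `allele_of_founder` (named integer: founder state ->
#'   allele cluster), `allele_of_line` (named integer per line, NA for
#'   UNKNOWN), `n_alleles`, and `cluster_means`.
#' @export
collapse_functional_alleles <- function(states, pheno, p_collapse = 0.05,
                                        min_n = 2) {
  if (!is.null(names(pheno)) && !is.null(names(states))) {
    pheno <- pheno[names(states)]
  }
  ok <- !is.na(states) & !is.na(pheno)
  grp <- split(pheno[ok], states[ok])
  big <- names(grp)[vapply(grp, length, integer(1)) >= min_n]
  small <- setdiff(names(grp), big)
  if (length(big) < 1) stop("no founder group reaches min_n lines")

  ng <- length(big)
  gp <- matrix(0, ng, ng)   # group-pair p-values
  for (i in seq_len(ng - 1)) {
    for (j in (i + 1):ng) {
      a <- grp[[big[i]]]
      b <- grp[[big[j]]]
      gp[i, j] <- gp[j, i] <-
        if (length(a) < 2 || length(b) < 2) 1
        else stats::t.test(a, b)$p.value
    }
  }
  clusters <- lapply(seq_len(ng), function(i) i)
  while (length(clusters) > 1) {
    np <- length(clusters)
    pm <- matrix(0, np, np)
    for (i in seq_len(np - 1)) {
      for (j in (i + 1):np) {
        pm[i, j] <- max(gp[clusters[[i]], clusters[[j]]])
      }
    }
    mx <- which(pm == max(pm[upper.tri(pm)]), arr.ind = TRUE)[1, ]
    if (pm[mx[1], mx[2]] < p_collapse) break
    i <- mx[1]; j <- mx[2]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters <- clusters[-j]
  }
  clusters <- lapply(clusters, function(ix)
    list(founders = big[ix],
         values = unlist(grp[big[ix]], use.names = FALSE)))
  means <- vapply(clusters, function(cl) mean(cl$values), numeric(1))
  ord <- order(means)
  clusters <- clusters[ord]
  means <- means[ord]
  allele_of_founder <- integer(0)
  for (k in seq_along(clusters)) {
    f <- clusters[[k]]$founders
    allele_of_founder[f] <- k
  }
  for (g in small) {
    allele_of_founder[g] <- which.min(abs(means - mean(grp[[g]])))
  }
  al <- allele_of_founder[as.character(states)]
  names(al) <- names(states)
  list(allele_of_founder = allele_of_founder, allele_of_line = al,
       n_alleles = length(clusters), cluster_means = means)
}

#' Narrow a QTL interval using re-clustered major haplotypes
#'
#' The functional-allele labels (from the peak bin's collapse) are projected
#' onto every bin in the region; lines sharing an identical allele vector
#' across the region form haplotypes, and haplotypes carried by more than
#' `min_hap_n - 1` lines are the major haplotypes. For each pair of major
#' haplotypes a phenotype t-test classifies the pair as distinct
#' (P < `p_narrow`), equivalent (P >= `p_equiv`), or ambiguous (no
#' constraint). Each bin is scored by the number of pair constraints it
#' satisfies (distinct pairs should disagree in allele at the bin,
#' equivalent pairs should agree); the supporting bins are those attaining
#' the maximum score, so a single discordant t-test cannot veto the causal
#' bin.
#' The refined interval is the longest maximal run of supporting bins
#' (preferring a run containing the peak bin).
#'
#' @param bins a [build_bins()] result.
#' @param region data.frame row with chrom, start_bp, end_bp, peak_bin.
#' @param allele_of_founder founder -> allele mapping from
#'   [collapse_functional_alleles()].
#' @param pheno named line values.
#' @param p_narrow significance level declaring a haplotype pair distinct
#'   (default 0.01).
#' @param p_equiv p-value above which a pair is treated as phenotypically
#'   equivalent (default 0.05); pairs in between constrain nothing.
#' @param min_hap_n major haplotypes must exceed `min_hap_n - 1` lines
#'   (default: more than 8 lines).
#' @return list with `interval` (chrom, start_bp, end_bp), `narrowed`
#'   (logical), `decision` (per-bin table), `haplotypes` (haplotype table
#'   with group sizes), and `flag` (character, reason when not narrowed).
#' @export
narrow_interval <- function(bins, region, allele_of_founder, pheno,
                            p_narrow = 0.01, p_equiv = 0.05, min_hap_n = 9) {
  bidx <- which(bins$bins$chrom == region$chrom &
                bins$bins$end_bp >= region$start_bp &
                bins$bins$start_bp <= region$end_bp)
  if (length(bidx) == 0) stop("region covers no bins")
  st <- bins$states[, bidx, drop = FALSE]
  al <- matrix(allele_of_founder[as.character(st)], nrow(st), ncol(st),
               dimnames = dimnames(st))
  if (!is.null(names(pheno))) pheno <- pheno[bins$samples]

  key <- apply(al, 1, paste, collapse = ",")
  complete <- !apply(al, 1, anyNA)
  sizes <- table(key[complete])
  major <- names(sizes)[sizes >= min_hap_n]
  full <- list(interval = data.frame(chrom = region$chrom,
                                     start_bp = region$start_bp,
                                     end_bp = region$end_bp),
               narrowed = FALSE, decision = NULL, haplotypes = NULL)
  if (length(major) < 2) {
    full$flag <- "fewer than two major haplotypes"
    return(full)
  }
  hap_al <- do.call(rbind, lapply(strsplit(major, ","), as.integer))
  hap_val <- lapply(major, function(h) pheno[complete & key == h])
  H <- length(major)
  distinct <- equivalent <- matrix(FALSE, H, H)
  for (i in seq_len(H - 1)) {
    for (j in (i + 1):H) {
      p <- stats::t.test(hap_val[[i]], hap_val[[j]])$p.value
      distinct[i, j] <- distinct[j, i] <- p < p_narrow
      equivalent[i, j] <- equivalent[j, i] <- p >= p_equiv
    }
  }
  if (!any(distinct)) {
    full$flag <- "no phenotypically distinct haplotype pair"
    return(full)
  }
  score <- integer(ncol(al))
  for (b in seq_len(ncol(al))) {
    sc <- 0L
    for (i in seq_len(H - 1)) {
      for (j in (i + 1):H) {
        differs <- hap_al[i, b] != hap_al[j, b]
        if (distinct[i, j] && differs) sc <- sc + 1L
        if (equivalent[i, j] && !differs) sc <- sc + 1L
      }
    }
    score[b] <- sc
  }
  support <- score == max(score)
  decision <- cbind(bins$bins[bidx, ], score = score, support = support)
  hapdf <- data.frame(haplotype = major, n = as.integer(sizes[major]),
                      mean = vapply(hap_val, mean, numeric(1)))
  if (!any(support)) {
    full$flag <- "no supporting bin; region returned unchanged"
    full$decision <- decision
    full$haplotypes <- hapdf
    return(full)
  }
  runs <- rle(support)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- which(runs$values)
  peak_local <- match(region$peak_bin, bins$bins$bin_id[bidx])
  pick <- cand[which.max(runs$lengths[cand])]
  if (!is.na(peak_local)) {
    containing <- cand[starts[cand] <= peak_local & ends[cand] >= peak_local]
    if (length(containing)) pick <- containing[1]
  }
  sel <- bidx[starts[pick]:ends[pick]]
  list(interval = data.frame(chrom = region$chrom,
                             start_bp = max(min(bins$bins$start_bp[sel]),
                                            region$start_bp),
                             end_bp = min(max(bins$bins$end_bp[sel]),
                                          region$end_bp)),
       narrowed = TRUE, decision = decision, haplotypes = hapdf,
       flag = NA_character_)
}
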