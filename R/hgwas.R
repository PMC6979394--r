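# Bin-haplotype association: for each bin the full model adds a random
# founder-state effect a ~ N(0, sb2 I) over state dummies Z_b to the null
# polygenic model y = X beta + u + e, u ~ N(0, sg2 K). The polygenic and
# residual components are fixed at their genome-wide null REML estimates
# (P3D); sb2 is then profiled on the eigenbasis of K via Woodbury identities
# and the statistic is the REML likelihood ratio LRT = 2(logL_full -
# logL_null), floored at 0 (the profile includes sb2 = 0). Significance is
# calibrated by permutation, never against an asymptotic null.

hgwas_prep <- function(bins, y, K, pcs = NULL) {
  samples <- bins$samples
  if (!is.null(names(y))) y <- y[samples]
  if (anyNA(y)) stop("phenotype missing for some lines")
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n), pcs)
  null <- lmm_null_fit(y, X, K)
  D <- null$sigma_g2 * null$lambda + null$sigma_e2
  sw <- 1 / sqrt(D)
  Xw <- crossprod(null$U, X) * sw
  G0 <- crossprod(Xw)
  list(null = null, U = null$U, sw = sw, Xw = Xw, samples = samples,
       G0 = G0, ldG0 = as.numeric(determinant(G0, TRUE)$modulus),
       ld0 = sum(log(D)), X = X, n = n, p = ncol(X), var_y = stats::var(y))
}

# state dummies for one bin: UNKNOWN rows are zero, states observed in fewer
# than min_state_n lines are pooled into a single residual column; returns a
# group-index vector (NA = no group) or NULL when fewer than 2 columns
bin_groups <- function(sb, min_state_n = 3) {
  tab <- table(sb[!is.na(sb)])
  lev <- as.integer(names(tab))
  common <- lev[tab >= min_state_n]
  rare <- lev[tab < min_state_n]
  m <- length(common) + (length(rare) > 0)
  if (m < 2) return(NULL)
  grp <- match(sb, common)
  if (length(rare)) grp[!is.na(sb) & sb %in% rare] <- length(common) + 1L
  grp
}

# y-independent structures for one bin
bin_precompute <- function(prep, grp) {
  idx <- which(!is.na(grp))
  M <- rowsum(prep$U[idx, , drop = FALSE], grp[idx])  # m x n, rows = U' Z cols
  M <- t(M) * prep$sw                                 # n x m, whitened
  sv <- svd(M, nu = ncol(M), nv = 0)
  C <- crossprod(sv$u, prep$Xw)                       # m x p
  list(s2 = sv$d^2, Um = sv$u, C = C, m = ncol(M))
}

# profiled LRT for one bin given response pieces; grid excludes 0 (the null)
bin_profile <- function(prep, pc, yw, a_y, c_y, yPy0, grid, refine_min = 2) {
  b_y <- drop(crossprod(pc$Um, yw))
  m <- pc$m
  p <- prep$p
  G <- length(grid)
  Tmat <- outer(pc$s2, grid)                 # m x G
  W <- Tmat / (1 + Tmat)
  ldT <- colSums(log1p(Tmat))
  q_y <- drop(crossprod(b_y^2, W))           # sum w b^2 per grid point
  if (p == 1) {
    c2 <- pc$C[, 1]^2
    XVX <- drop(prep$G0) - drop(crossprod(c2, W))
    XVy <- drop(c_y) - drop(crossprod(pc$C[, 1] * b_y, W))
    yPy <- (a_y - q_y) - XVy^2 / XVX
    dl <- (prep$ldG0 - log(XVX)) - ldT + (yPy0 - yPy)
  } else {
    Cb <- pc$C * b_y
    dl <- numeric(G)
    O <- t(apply(pc$C, 1, function(cj) tcrossprod(cj)))  # m x p^2
    if (m == 1) O <- matrix(O, 1, p * p)
    XVXs <- crossprod(O, W)                  # p^2 x G
    XVys <- crossprod(Cb, W)                 # p x G
    for (g in seq_len(G)) {
      XVX <- prep$G0 - matrix(XVXs[, g], p, p)
      XVy <- c_y - XVys[, g]
      beta <- solve(XVX, XVy)
      yPy <- (a_y - q_y[g]) - sum(XVy * beta)
      dl[g] <- (prep$ldG0 -
                as.numeric(determinant(XVX, TRUE)$modulus)) -
        ldT[g] + (yPy0 - yPy)
    }
  }
  best <- which.max(dl)
  lrt <- max(dl[best], 0)
  sb2 <- if (dl[best] > 0) grid[best] else 0
  if (lrt >= refine_min && length(grid) > 2) {
    lo <- grid[max(best - 1, 1)]
    hi <- grid[min(best + 1, G)]
    f1 <- function(sb2v) {
      t_j <- sb2v * pc$s2
      w <- t_j / (1 + t_j)
      XVX <- prep$G0 - crossprod(pc$C, w * pc$C)
      XVy <- c_y - drop(crossprod(pc$C, w * b_y))
      yVy <- a_y - sum(w * b_y^2)
      beta <- solve(XVX, XVy)
      (prep$ldG0 - as.numeric(determinant(XVX, TRUE)$modulus)) -
        sum(log1p(t_j)) + (yPy0 - (yVy - sum(XVy * beta)))
    }
    opt <- stats::optimize(f1, c(lo, hi), maximum = TRUE)
    if (opt$objective > lrt) {
      lrt <- opt$objective
      sb2 <- opt$maximum
    }
  }
  c(lrt = lrt, sigma_b2 = sb2)
}

default_sb2_grid <- function(var_y, n_grid = 25) {
  var_y * exp(seq(log(1e-4), log(5), length.out = n_grid))
}

#' Precompute a bin-scan engine for repeated phenotypes
#'
#' Builds the eigen/SVD structures of every bin once (null variance
#' components calibrated on a reference phenotype) so that repeated scans on
#' new phenotypes of the same population — as in simulation studies — reuse
#' them.
#'
#' @param bins a [build_bins()] result.
#' @param y_ref reference phenotype used to calibrate the null covariance.
#' @param K bin kinship (default [bin_kinship()]).
#' @param pcs optional PC covariates.
#' @param min_state_n rare-state pooling cutoff (default 3).
#' @param grid sb2 profiling grid (defaults to 25 log-spaced points).
#' @return an `hgwas_engine` list.
#' @export
hgwas_engine <- function(bins, y_ref, K = NULL, pcs = NULL, min_state_n = 3,
                         grid = NULL) {
  if (is.null(K)) K <- bin_kinship(bins)
  prep <- hgwas_prep(bins, y_ref, K, pcs)
  if (is.null(grid)) grid <- default_sb2_grid(prep$var_y)
  B <- ncol(bins$states)
  pcs_list <- vector("list", B)
  for (b in seq_len(B)) {
    grp <- bin_groups(bins$states[, b], min_state_n)
    if (!is.null(grp)) pcs_list[[b]] <- bin_precompute(prep, grp)
  }
  structure(list(prep = prep, bins = bins, grid = grid,
                 precomp = pcs_list), class = "hgwas_engine")
}

engine_response <- function(prep, y) {
  if (!is.null(names(y))) y <- y[prep$samples]
  yw <- drop(crossprod(prep$U, y)) * prep$sw
  c_y <- drop(crossprod(prep$Xw, yw))
  a_y <- sum(yw^2)
  yPy0 <- a_y - sum(c_y * solve(prep$G0, c_y))
  list(yw = yw, a_y = a_y, c_y = c_y, yPy0 = yPy0)
}

#' Bin-haplotype mixed-model scan (REML likelihood-ratio tests)
#'
#' @param bins a [build_bins()] result.
#' @param y named line values (BLUPs).
#' @param K kinship; default [bin_kinship()] of `bins`.
#' @param pcs optional PC covariate matrix.
#' @param min_state_n founder states observed in fewer lines than this are
#'   pooled into one residual class before testing (default 3).
#' @param grid sb2 profiling grid (0 is always evaluated as the null).
#' @param engine optional [hgwas_engine()]; when given, its null covariance
#'   and bin structures are reused and `K`, `pcs`, `grid` are ignored.
#' @param refine_min coarse LRT above which the profile maximum is refined
#'   with a 1-D optimiser (default 2).
#' @return data.frame of class `hgwas_result`: bin_id, chrom, start_bp,
#'   end_bp, n_states, n_tested, lrt, sigma_b2; the null fit is attached as
#'   attribute `null_fit`.
#' @export
hgwas_scan <- function(bins, y, K = NULL, pcs = NULL, min_state_n = 3,
                       grid = NULL, engine = NULL, refine_min = 2) {
  if (is.null(engine)) {
    if (is.null(K)) K <- bin_kinship(bins)
    engine <- hgwas_engine(bins, y, K, pcs, min_state_n, grid)
  }
  prep <- engine$prep
  resp <- engine_response(prep, y)
  B <- ncol(bins$states)
  lrt <- sb2 <- numeric(B)
  ntested <- integer(B)
  for (b in seq_len(B)) {
    pc <- engine$precomp[[b]]
    if (is.null(pc)) {
      ntested[b] <- 1L
      next
    }
    ntested[b] <- pc$m
    r <- bin_profile(prep, pc, resp$yw, resp$a_y, resp$c_y, resp$yPy0,
                     engine$grid, refine_min)
    lrt[b] <- r[["lrt"]]
    sb2[b] <- r[["sigma_b2"]]
  }
  out <- cbind(bins$bins, n_tested = ntested, lrt = lrt, sigma_b2 = sb2)
  class(out) <- c("hgwas_result", "data.frame")
  attr(out, "null_fit") <- prep$null
  out
}

#' Permutation threshold for the bin-scan LRT
#'
#' Phenotype values are shuffled across lines; for each permutation the
#' genome-wide maximum LRT is recorded (holding the null covariance fixed at
#' the observed-data fit) and the cutoff is the empirical (1 - alpha)
#' quantile of that maximum.
#'
#' @inheritParams hgwas_scan
#' @param n_perm number of permutations (default 500; fewer than 20 warns).
#' @param alpha genome-wide error rate (default 0.05).
#' @param seed RNG seed.
#' @return the LRT cutoff, with the per-permutation maxima as attribute
#'   `max_lrt`.
#' @export
permutation_threshold <- function(bins, y, K = NULL, pcs = NULL,
                                  n_perm = 500, alpha = 0.05,
                                  min_state_n = 3, grid = NULL,
                                  engine = NULL, seed = NULL) {
  if (n_perm < 20) warning("fewer than 20 permutations: unstable quantile")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(engine)) {
    if (is.null(K)) K <- bin_kinship(bins)
    engine <- hgwas_engine(bins, y, K, pcs, min_state_n, grid)
  }
  prep <- engine$prep
  grid <- engine$grid
  if (!is.null(names(y))) y <- y[bins$samples]
  n <- prep$n
  p <- prep$p
  Yp <- vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
  Yw <- crossprod(prep$U, Yp) * prep$sw
  a_y <- colSums(Yw^2)
  Cy <- crossprod(prep$Xw, Yw)                    # p x P
  yPy0 <- a_y - colSums(Cy * solve(prep$G0, Cy))
  maxlrt <- rep(0, n_perm)
  for (b in seq_along(engine$precomp)) {
    pc <- engine$precomp[[b]]
    if (is.null(pc)) next
    B_y <- crossprod(pc$Um, Yw)                   # m x P
    best <- rep(0, n_perm)
    for (g in grid) {
      t_j <- g * pc$s2
      w <- t_j / (1 + t_j)
      XVX <- prep$G0 - crossprod(pc$C, w * pc$C)
      XVy <- Cy - crossprod(w * pc$C, B_y)        # p x P
      yVy <- a_y - colSums(w * B_y^2)
      yPy <- yVy - colSums(XVy * solve(XVX, XVy))
      dl <- (prep$ldG0 - as.numeric(determinant(XVX, TRUE)$modulus)) -
        sum(log1p(t_j)) + (yPy0 - yPy)
      best <- pmax(best, dl)
    }
    maxlrt <- pmax(maxlrt, best)
  }
  cutoff <- as.numeric(stats::quantile(maxlrt, 1 - alpha, type = 1))
  attr(cutoff, "max_lrt") <- maxlrt
  cutoff
}

#' Merge significant bins into hQTL
#'
#' Significant bins are chained into one locus when separated by at most
#' `max_gap_bp` or by at most `max_gap_bins` intervening bins; the peak is
#' the member with the highest LRT and the interval is the physical span of
#' the member bins.
#'
#' @param scan an `hgwas_result` from [hgwas_scan()].
#' @param cutoff LRT significance cutoff (e.g. from
#'   [permutation_threshold()]).
#' @param max_gap_bp maximum physical gap between chained bins (default 1 Mb).
#' @param max_gap_bins maximum intervening-bin count (default 5).
#' @param trait optional trait label.
#' @return data.frame of hQTL records: trait, chrom, start_bp, end_bp,
#'   peak_bin, peak_lrt, n_bins; member bin IDs as attribute `members`.
#' @export
merge_hqtl <- function(scan, cutoff, max_gap_bp = 1e6, max_gap_bins = 5,
                       trait = "trait1") {
  sig <- which(scan$lrt >= cutoff)
  loci <- list()
  members <- list()
  if (length(sig) > 0) {
    for (ch in unique(scan$chrom[sig])) {
      s <- sig[scan$chrom[sig] == ch]
      s <- s[order(scan$start_bp[s])]
      if (length(s) > 1) {
        gap_bp <- scan$start_bp[s[-1]] - scan$end_bp[s[-length(s)]] - 1
        gap_bins <- diff(s) - 1
        new_locus <- gap_bp > max_gap_bp & gap_bins > max_gap_bins
        grp <- cumsum(c(1, new_locus))
      } else {
        grp <- 1
      }
      for (g in unique(grp)) {
        m <- s[grp == g]
        pk <- m[which.max(scan$lrt[m])]
        loci[[length(loci) + 1]] <-
          data.frame(chrom = ch, start_bp = min(scan$start_bp[m]),
                     end_bp = max(scan$end_bp[m]),
                     peak_bin = scan$bin_id[pk], peak_lrt = scan$lrt[pk],
                     n_bins = length(m))
        members[[length(members) + 1]] <- scan$bin_id[m]
      }
    }
  }
  if (length(loci) == 0) {
    out <- data.frame(trait = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      peak_bin = character(0), peak_lrt = numeric(0),
                      n_bins = integer(0))
  } else {
    out <- cbind(trait = trait, do.call(rbind, loci))
  }
  rownames(out) <- NULL
  attr(out, "members") <- members
  class(out) <- c("hqtl_set", "data.frame")
  out
}
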