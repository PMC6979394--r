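# Independent brute-force oracles used to validate the fast implementations.

# Exhaustive path-sum posterior for the founder-tracing HMM: enumerates all
# F^S hidden paths with the same transition/emission law as fit_mosaic.
brute_force_posterior <- function(dosage, founder_alleles, d_morgans, G, eps,
                                  distinct_redraw = FALSE) {
  Fn <- nrow(founder_alleles)
  S <- ncol(founder_alleles)
  emis <- function(s, f) {
    g <- dosage[s]
    if (is.na(g) || g == 1) return(1)
    match <- (g == 0 && founder_alleles[f, s] == 0L) ||
      (g == 2 && founder_alleles[f, s] == 1L)
    if (match) 1 - eps else eps
  }
  trans <- function(s, f1, f2) {
    stay <- exp(-G * d_morgans[s])
    if (distinct_redraw) {
      sw <- (1 - stay) / (Fn - 1)
      if (f1 == f2) stay else sw
    } else {
      sw <- (1 - stay) / Fn
      if (f1 == f2) stay + sw else sw
    }
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(Fn)), S)))
  w <- apply(paths, 1, function(p) {
    pr <- (1 / Fn) * emis(1, p[1])
    for (s in seq_len(S - 1)) {
      pr <- pr * trans(s, p[s], p[s + 1]) * emis(s + 1, p[s + 1])
    }
    pr
  })
  post <- matrix(0, S, Fn)
  for (s in seq_len(S)) {
    for (f in seq_len(Fn)) {
      post[s, f] <- sum(w[paths[, s] == f])
    }
  }
  post / rowSums(post)
}

# boundary-sweep oracle for recombination bins: distinct segment starts
oracle_bin_count <- function(mosaic) {
  n <- 0L
  for (ch in names(attr(mosaic, "chrom_len"))) {
    seg <- mosaic[mosaic$chrom == ch, ]
    n <- n + length(unique(seg$start_bp))
  }
  n
}

# brute-force greedy LD pruning on one window of markers
oracle_prune_window <- function(geno, idx, r2_max) {
  keep <- rep(TRUE, length(idx))
  for (a in seq_along(idx)) {
    if (!keep[a]) next
    for (b in seq_along(idx)) {
      if (b <= a || !keep[b]) next
      if (marker_r2(geno, idx[a], idx[b]) >= r2_max) keep[b] <- FALSE
    }
  }
  idx[keep]
}

# shared-state fraction kinship computed entry by entry
oracle_bin_kinship <- function(states) {
  n <- nrow(states)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      same <- !is.na(states[i, ]) & !is.na(states[j, ]) &
        states[i, ] == states[j, ]
      K[i, j] <- mean(same)
    }
  }
  K
}
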