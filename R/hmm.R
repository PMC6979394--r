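#' HMM parameters for founder mosaic reconstruction
#'
#' @param G effective number of generations governing the recombination
#'   density: IBD segment lengths are assumed exponential with mean rho/G
#'   (rho = genetic length), so the switch probability between markers at map
#'   distance d Morgans is 1 - exp(-G d).
#' @param epsilon per-site emission error probability in \[0, 0.5).
#' @param call_factor posterior call multiplier: a founder is called at a SNP
#'   only when the maximum posterior exceeds `call_factor / n_founders`
#'   (twice the uniform chance level by default); otherwise the state is
#'   UNKNOWN.
#' @param distinct_redraw if TRUE, a switch event re-draws the founder
#'   uniformly among the other F-1 founders rather than all F.
#' @return An `hmm_params` list.
#' @export
hmm_params <- function(G = 9, epsilon = 0.02, call_factor = 2,
                       distinct_redraw = FALSE) {
  if (G <= 0) stop("G must be positive")
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  structure(list(G = G, epsilon = epsilon, call_factor = call_factor,
                 distinct_redraw = distinct_redraw), class = "hmm_params")
}

#' Filter SNPs for IBD reconstruction
#'
#' Removes markers with an across-line heterozygosity fraction above
#' `het_max` or a missing-call fraction above `miss_max`; progeny genomes are
#' assumed essentially homozygous, so highly heterozygous markers are
#' uninformative for founder tracing.
#'
#' @param progeny a [genotype_matrix()].
#' @param het_max maximum tolerated heterozygote fraction (default 0.10).
#' @param miss_max maximum tolerated missing fraction (default 0.25).
#' @return A filtered [genotype_matrix()] (marker order preserved), with the
#'   logical keep-vector as attribute `kept`.
#' @export
filter_snps_for_ibd <- function(progeny, het_max = 0.10, miss_max = 0.25) {
  d <- progeny$dosage
  het <- colMeans(d == 1, na.rm = TRUE)
  het[is.nan(het)] <- 0
  miss <- colMeans(is.na(d))
  keep <- het <= het_max & miss <= miss_max
  if (!any(keep)) warning("no markers survive the IBD filters")
  out <- subset_genotypes(progeny, markers = keep)
  attr(out, "kept") <- keep
  out
}

# Emission probabilities for one marker: lines x founders.
# Homozygous progeny call matching the founder allele scores 1 - eps,
# a mismatch scores eps; missing and heterozygous calls are uninformative.
.emission <- function(g, fa, eps) {
  n <- length(g)
  Fn <- length(fa)
  E <- matrix(1, n, Fn)
  obs <- !is.na(g) & g != 1
  if (any(obs)) {
    match <- outer(g[obs] == 0, fa == 0L) | outer(g[obs] == 2, fa == 1L)
    E[obs, ] <- ifelse(match, 1 - eps, eps)
  }
  E
}

#' Reconstruct founder mosaics by forward-backward HMM
#'
#' Hidden states are the F founders; the initial distribution is uniform;
#' between adjacent markers at map distance d Morgans a switch event occurs
#' with probability 1 - exp(-G d), the new state drawn uniformly over all
#' founders (or over the other F-1 founders with `distinct_redraw`).
#' Posteriors are computed by scaled forward-backward per chromosome. The
#' per-SNP call is the argmax founder when the maximum posterior exceeds
#' `call_factor / F` (ties broken toward the lowest founder index), UNKNOWN
#' otherwise; consecutive identical calls are merged into segments with
#' boundaries midway between flanking markers.
#'
#' @param progeny a [genotype_matrix()] (pass through [filter_snps_for_ibd()]
#'   first for real data).
#' @param founders a [founder_panel()] sharing the progeny marker set.
#' @param map a [genetic_map()] covering all markers (defaults to the
#'   panel's map).
#' @param params an [hmm_params()].
#' @param return_posterior also return the full posterior arrays (lines kept
#'   small; memory is S x F per line).
#' @param block_size number of lines processed per vectorised block.
#' @return list with `mosaic` (a [mosaic_set()]), `calls` (lines x markers
#'   integer matrix, NA = UNKNOWN), `posterior_max` (matching matrix of
#'   maximum posteriors), and optionally `posterior` (list of S x F matrices
#'   per line).
#' @export
fit_mosaic <- function(progeny, founders, map = founders$map,
                       params = hmm_params(), return_posterior = FALSE,
                       block_size = 32L) {
  fa <- founders$alleles
  if (ncol(fa) != nrow(progeny$markers) ||
      !all(colnames(fa) == progeny$markers$marker_id)) {
    # allow founder panel wider than the filtered progeny set
    idx <- match(progeny$markers$marker_id, colnames(fa))
    if (anyNA(idx)) stop("marker sets of founders and progeny do not match")
    fa <- fa[, idx, drop = FALSE]
  }
  midx <- match(progeny$markers$marker_id, map$marker_id)
  if (anyNA(midx)) stop("map does not cover all progeny markers")
  Fn <- nrow(fa)
  N <- length(progeny$samples)
  eps <- params$epsilon
  chrom_len <- chrom_lengths(map)
  chroms <- unique(progeny$markers$chrom)

  calls <- matrix(NA_integer_, N, nrow(progeny$markers),
                  dimnames = list(progeny$samples, progeny$markers$marker_id))
  pmax_out <- matrix(NA_real_, N, nrow(progeny$markers),
                     dimnames = dimnames(calls))
  post_list <- if (return_posterior) {
    stats::setNames(vector("list", N), progeny$samples)
  }
  if (return_posterior) {
    for (i in seq_len(N)) {
      post_list[[i]] <- matrix(NA_real_, nrow(progeny$markers), Fn,
                               dimnames = list(progeny$markers$marker_id,
                                               founders$founder_ids))
    }
  }

  # capped below 1 so perfectly informative data stay callable when F is
  # small enough that call_factor/F reaches 1 (e.g. two founders)
  call_thr <- min(params$call_factor / Fn, 0.99)
  for (ch in chroms) {
    cols <- which(progeny$markers$chrom == ch)
    S <- length(cols)
    cm <- interp_cM(map, ch, progeny$markers$pos_bp[cols])
    d_M <- diff(cm) / 100
    if (any(d_M < 0)) stop("negative map distance on chromosome ", ch)
    stay <- exp(-params$G * d_M)
    blocks <- split(seq_len(N), ceiling(seq_len(N) / block_size))
    for (bl in blocks) {
      nb <- length(bl)
      A <- array(0, c(S, nb, Fn))   # scaled forward
      E <- array(0, c(S, nb, Fn))   # emissions
      for (s in seq_len(S)) {
        E[s, , ] <- .emission(progeny$dosage[bl, cols[s]], fa[, cols[s]], eps)
      }
      a <- matrix(1 / Fn, nb, Fn) * E[1, , ]
      a <- a / rowSums(a)
      A[1, , ] <- a
      for (s in seq_len(S - 1)) {
        if (params$distinct_redraw) {
          sw <- (1 - stay[s]) / (Fn - 1)
          pred <- (stay[s] - sw) * a + sw
        } else {
          pred <- stay[s] * a + (1 - stay[s]) / Fn
        }
        a <- pred * E[s + 1, , ]
        a <- a / rowSums(a)
        A[s + 1, , ] <- a
      }
      b <- matrix(1, nb, Fn)
      post <- A[S, , , drop = FALSE][1, , , drop = TRUE]
      if (nb == 1) post <- matrix(post, 1, Fn)
      .store <- function(s, post) {
        pm <- post / rowSums(post)
        mx <- apply(pm, 1, max)
        arg <- max.col(pm, ties.method = "first")
        arg[mx <= call_thr] <- NA_integer_
        calls[bl, cols[s]] <<- arg
        pmax_out[bl, cols[s]] <<- mx
        if (return_posterior) {
          for (j in seq_len(nrow(pm))) post_list[[bl[j]]][cols[s], ] <<- pm[j, ]
        }
      }
      .store(S, post)
      if (S > 1) for (s in (S - 1):1) {
        v <- E[s + 1, , , drop = FALSE][1, , , drop = TRUE] * b
        if (nb == 1) v <- matrix(v, 1, Fn)
        if (params$distinct_redraw) {
          sw <- (1 - stay[s]) / (Fn - 1)
          b <- (stay[s] - sw) * v + sw * rowSums(v)
        } else {
          b <- stay[s] * v + (1 - stay[s]) / Fn * rowSums(v)
        }
        b <- b / rowSums(b)
        av <- A[s, , , drop = FALSE][1, , , drop = TRUE]
        if (nb == 1) av <- matrix(av, 1, Fn)
        .store(s, av * b)
      }
    }
  }

  mosaic <- calls_to_mosaic(calls, progeny$markers, chrom_len, Fn)
  out <- list(mosaic = mosaic, calls = calls, posterior_max = pmax_out)
  if (return_posterior) out$posterior <- post_list
  out
}

#' Collapse per-SNP founder calls into a segment mosaic
#'
#' Runs of identical calls (including UNKNOWN runs) become segments; the
#' boundary between two runs is placed midway between the flanking markers.
#'
#' @param calls lines x markers integer matrix (NA = UNKNOWN).
#' @param markers marker table (chrom, pos_bp) matching the columns.
#' @param chrom_len named chromosome lengths.
#' @param n_founders founder count for the resulting [mosaic_set()].
#' @return A [mosaic_set()].
#' @export
calls_to_mosaic <- function(calls, markers, chrom_len, n_founders) {
  rows <- list()
  k <- 1L
  for (ch in unique(markers$chrom)) {
    cols <- which(markers$chrom == ch)
    pos <- markers$pos_bp[cols]
    L <- chrom_len[[ch]]
    for (i in seq_len(nrow(calls))) {
      v <- calls[i, cols]
      key <- ifelse(is.na(v), 0L, v)
      change <- which(key[-1] != key[-length(key)])
      starts <- c(1, floor((pos[change] + pos[change + 1]) / 2) + 1)
      ends <- c(floor((pos[change] + pos[change + 1]) / 2), L)
      rows[[k]] <- data.frame(line = rownames(calls)[i], chrom = ch,
                              start_bp = starts, end_bp = ends,
                              founder = v[c(1, change + 1)])
      k <- k + 1L
    }
  }
  mosaic_set(do.call(rbind, rows), chrom_len = chrom_len,
             n_founders = n_founders, validate = FALSE)
}

#' Founder tracing power: fraction of markers with correct IBD origin
#'
#' Compares the inferred mosaic with the simulated truth at every map marker;
#' UNKNOWN inferred states count as incorrect.
#'
#' @param truth a [mosaic_set()] (simulated truth).
#' @param inferred a [mosaic_set()] (HMM output) over the same genome/lines.
#' @param map a [genetic_map()] giving the marker positions to score.
#' @return list with `overall` (genome-wide fraction), `per_chrom`, and
#'   `per_line` fractions.
#' @export
tracing_power <- function(truth, inferred, map) {
  lines <- unique(truth$line)
  st_t <- mosaic_states_at(truth, map, lines = lines)
  st_i <- mosaic_states_at(inferred, map, lines = lines)
  ok <- !is.na(st_i) & st_i == st_t
  per_chrom <- vapply(unique(map$chrom), function(ch) {
    mean(ok[, map$chrom == ch])
  }, numeric(1))
  list(overall = mean(ok), per_chrom = per_chrom,
       per_line = rowMeans(ok))
}
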