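# Haplotypes are stored per chromosome as run-length segment lists:
# list(pos = start bp of each segment (first is 1), fdr = founder index).

hap_whole <- function(f, chroms) {
  h <- lapply(chroms, function(ch) list(pos = 1, fdr = f))
  names(h) <- chroms
  h
}

hap_state_at <- function(h, pos) h$fdr[findInterval(pos, h$pos)]

merge_runs <- function(pos, fdr) {
  if (length(fdr) > 1) {
    keep <- c(TRUE, fdr[-1] != fdr[-length(fdr)])
    pos <- pos[keep]
    fdr <- fdr[keep]
  }
  list(pos = pos, fdr = fdr)
}

# One chromosome of a gamete: crossovers at bp positions xbp (segment [1, x]
# keeps the current source, [x+1, ...] switches).
recombine_chrom <- function(hA, hB, xbp, start_with_A = TRUE) {
  if (length(xbp) == 0L) return(if (start_with_A) hA else hB)
  xbp <- sort(unique(xbp))
  bounds <- c(1, xbp + 1)
  ends <- c(xbp, Inf)
  src_a <- rep(c(start_with_A, !start_with_A), length.out = length(bounds))
  pos <- numeric(0)
  fdr <- integer(0)
  for (i in seq_along(bounds)) {
    h <- if (src_a[i]) hA else hB
    j0 <- findInterval(bounds[i], h$pos)
    j1 <- findInterval(ends[i], h$pos)
    pos <- c(pos, bounds[i], if (j1 > j0) h$pos[(j0 + 1):j1])
    fdr <- c(fdr, h$fdr[j0:j1])
  }
  merge_runs(pos, fdr)
}

# Gamete from an individual (list of two haplotypes): Poisson crossover count
# with mean = chromosome genetic length in Morgans, positions placed by cM
# density (Haldane, no interference).
make_gamete <- function(ind, map, chroms, len_cM, chrom_len) {
  g <- vector("list", length(chroms))
  names(g) <- chroms
  for (ch in chroms) {
    nx <- stats::rpois(1, len_cM[[ch]] / 100)
    xbp <- numeric(0)
    if (nx > 0) {
      m <- map[map$chrom == ch, ]
      u <- stats::runif(nx, min(m$pos_cM), max(m$pos_cM))
      xbp <- round(interp_bp(map, ch, u))
      xbp <- unique(pmin(pmax(xbp, 1), chrom_len[[ch]] - 1))
    }
    g[[ch]] <- recombine_chrom(ind[[1]][[ch]], ind[[2]][[ch]], xbp,
                               start_with_A = stats::runif(1) < 0.5)
  }
  g
}

hap_states_matrix <- function(haps, map, chroms) {
  S <- nrow(map)
  out <- matrix(NA_integer_, length(haps), S)
  for (ch in chroms) {
    cols <- which(map$chrom == ch)
    pos <- map$pos_bp[cols]
    for (i in seq_along(haps)) {
      h <- haps[[i]][[ch]]
      out[i, cols] <- h$fdr[findInterval(pos, h$pos)]
    }
  }
  out
}

haps_to_mosaic <- function(haps, line_ids, chroms, chrom_len, n_founders) {
  rows <- vector("list", length(haps) * length(chroms))
  k <- 1L
  for (i in seq_along(haps)) {
    for (ch in chroms) {
      h <- haps[[i]][[ch]]
      n <- length(h$pos)
      rows[[k]] <- data.frame(line = line_ids[i], chrom = ch,
                              start_bp = h$pos,
                              end_bp = c(h$pos[-1] - 1, chrom_len[[ch]]),
                              founder = h$fdr)
      k <- k + 1L
    }
  }
  mosaic_set(do.call(rbind, rows), chrom_len = chrom_len,
             n_founders = n_founders, validate = FALSE)
}

#' Simulate a multiparent inter-cross pedigree population
#'
#' Emulates the breeding scheme of a diallel-seeded MAGIC-type population:
#' an initial round of crosses between random distinct founder pairs, followed
#' by `n_intercross_gens - 1` rounds of random inter-mating of the pool, then
#' `n_selfing_gens` generations of selfing by single seed descent. Gametes
#' recombine with Poisson crossover counts (mean = chromosome length in
#' Morgans) and crossover positions placed by local cM density, without
#' interference. Residual heterozygosity after selfing is retained.
#'
#' With `n_intercross_gens = 0` the function returns non-recombinant F1
#' lines of two random founders each (no meiosis, no selfing).
#'
#' @param founders a [founder_panel()].
#' @param map the [genetic_map()] (defaults to the panel's map).
#' @param n_lines number of progeny lines.
#' @param n_intercross_gens rounds of inter-crossing (first = founder crosses).
#' @param n_selfing_gens generations of selfing.
#' @param select_fn optional truncation-selection hook: function(pool) ->
#'   indices of individuals retained before the next mating round; off by
#'   default.
#' @param seed RNG seed.
#' @return list with `truth` (a [mosaic_set()] of the first transmitted
#'   haplotype per line), `genotypes` (a [genotype_matrix()], dosage = sum of
#'   the two haplotype alleles), and `heterozygosity` (per-line fraction of
#'   markers with differing haplotype states).
#' @export
simulate_pedigree_population <- function(founders, map = founders$map,
                                         n_lines = 200,
                                         n_intercross_gens = 8,
                                         n_selfing_gens = 6,
                                         select_fn = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(map$chrom)
  if (!all(unique(founders$map$chrom) %in% chroms)) {
    stop("chromosome absent from map")
  }
  F <- nrow(founders$alleles)
  chrom_len <- chrom_lengths(map)
  len_cM <- map_lengths_cM(map)
  line_ids <- sprintf("line%04d", seq_len(n_lines))

  new_ind <- function(h1, h2) list(h1, h2)
  if (n_intercross_gens == 0) {
    pool <- lapply(seq_len(n_lines), function(i) {
      p <- sample.int(F, 2)
      new_ind(hap_whole(p[1], chroms), hap_whole(p[2], chroms))
    })
  } else {
    pool <- lapply(seq_len(n_lines), function(i) {
      p <- sample.int(F, 2)
      new_ind(hap_whole(p[1], chroms), hap_whole(p[2], chroms))
    })
    gen <- 1
    while (gen < n_intercross_gens) {
      if (!is.null(select_fn)) pool <- pool[select_fn(pool)]
      pool <- lapply(seq_len(n_lines), function(i) {
        par <- sample.int(length(pool), 2)
        new_ind(make_gamete(pool[[par[1]]], map, chroms, len_cM, chrom_len),
                make_gamete(pool[[par[2]]], map, chroms, len_cM, chrom_len))
      })
      gen <- gen + 1
    }
    for (g in seq_len(n_selfing_gens)) {
      pool <- lapply(pool, function(ind) {
        new_ind(make_gamete(ind, map, chroms, len_cM, chrom_len),
                make_gamete(ind, map, chroms, len_cM, chrom_len))
      })
    }
  }

  hapsA <- lapply(pool, `[[`, 1)
  hapsB <- lapply(pool, `[[`, 2)
  stA <- hap_states_matrix(hapsA, map, chroms)
  stB <- hap_states_matrix(hapsB, map, chroms)
  S <- nrow(map)
  colidx <- rep(seq_len(S), each = n_lines)
  dos <- matrix(founders$alleles[cbind(as.vector(stA), colidx)] +
                founders$alleles[cbind(as.vector(stB), colidx)],
                n_lines, S)
  geno <- genotype_matrix(dos, map_to_markers(map), samples = line_ids)
  truth <- haps_to_mosaic(hapsA, line_ids, chroms, chrom_len, F)
  het <- rowMeans(stA != stB &
                  matrix(founders$alleles[cbind(as.vector(stA), colidx)] !=
                         founders$alleles[cbind(as.vector(stB), colidx)],
                         n_lines, S))
  names(het) <- line_ids
  list(truth = truth, genotypes = geno, heterozygosity = het)
}

#' Simulate pseudoprogeny by reshuffling founder genomes
#'
#' Each line's genome is cut into a fixed number of recombinant segments:
#' segments are allocated to chromosomes proportionally to genetic map length
#' (largest-remainder rounding, at least one per chromosome), breakpoints are
#' sampled with density proportional to the local recombination rate (uniform
#' in cM, mapped back to bp), and founders are assigned to segments uniformly
#' at random with adjacent segments forced to differ. Genotypes are projected
#' from the founder alleles.
#'
#' @param founders a [founder_panel()].
#' @param map the [genetic_map()] (defaults to the panel's map).
#' @param n_lines number of pseudoprogeny lines.
#' @param n_segments recombinant segments per line (>= number of chromosomes).
#' @param seed RNG seed.
#' @return list with `truth` (a [mosaic_set()]) and `genotypes`
#'   (a [genotype_matrix()]).
#' @export
simulate_pseudoprogeny <- function(founders, map = founders$map,
                                   n_lines = 100, n_segments = 180,
                                   seed = NULL) {
  if (n_lines <= 0) stop("n_lines must be positive")
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(map$chrom)
  C <- length(chroms)
  if (n_segments < C) stop("n_segments must be >= number of chromosomes")
  len_cM <- map_lengths_cM(map)
  chrom_len <- chrom_lengths(map)
  # largest-remainder allocation, minimum one segment per chromosome
  raw <- n_segments * len_cM / sum(len_cM)
  n_c <- pmax(floor(raw), 1)
  while (sum(n_c) < n_segments) {
    i <- which.max(raw - n_c)
    n_c[i] <- n_c[i] + 1
  }
  while (sum(n_c) > n_segments) {
    cand <- which(n_c > 1)
    i <- cand[which.min((raw - n_c)[cand])]
    n_c[i] <- n_c[i] - 1
  }
  F <- nrow(founders$alleles)
  line_ids <- sprintf("sim%04d", seq_len(n_lines))
  rows <- vector("list", n_lines * C)
  k <- 1L
  for (i in seq_len(n_lines)) {
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      m <- map[map$chrom == ch, ]
      nseg <- n_c[[ch]]
      bp <- numeric(0)
      if (nseg > 1) {
        repeat {
          u <- stats::runif(nseg - 1, min(m$pos_cM), max(m$pos_cM))
          bp <- sort(unique(pmin(pmax(round(interp_bp(map, ch, u)), 1),
                                 chrom_len[[ch]] - 1)))
          if (length(bp) == nseg - 1) break
        }
      }
      f <- integer(nseg)
      f[1] <- sample.int(F, 1)
      if (nseg > 1) {
        for (j in 2:nseg) {
          f[j] <- sample.int(F - 1, 1)
          if (f[j] >= f[j - 1]) f[j] <- f[j] + 1L
        }
      }
      rows[[k]] <- data.frame(line = line_ids[i], chrom = ch,
                              start_bp = c(1, bp + 1),
                              end_bp = c(bp, chrom_len[[ch]]),
                              founder = f)
      k <- k + 1L
    }
  }
  truth <- mosaic_set(do.call(rbind, rows), chrom_len = chrom_len,
                      n_founders = F, validate = FALSE)
  list(truth = truth, genotypes = project_genotypes(truth, founders))
}

#' Segments per line of a mosaic set
#' @param mosaic a [mosaic_set()].
#' @return named integer vector, number of segments per line.
#' @export
segments_per_line <- function(mosaic) {
  tab <- table(mosaic$line)
  v <- as.integer(tab)
  names(v) <- names(tab)
  v
}
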