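# Shared fixtures are built lazily and cached for the session so expensive
# simulated populations are constructed once.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small two-chromosome genome used by most unit tests
fx_map <- function() fixture("map", function() synthetic_map(2, 100, 1e7, 400))

fx_founders <- function() fixture("founders", function() {
  simulate_founders(8, fx_map(), divergence = 0.4, seed = 101)
})

# mid-size population for scan unit tests
fx_pop <- function() fixture("pop", function() {
  simulate_pedigree_population(fx_founders(), n_lines = 150, seed = 202)
})

fx_bins <- function() fixture("bins", function() build_bins(fx_pop()$truth))

fx_bin_kinship <- function() fixture("bin_kinship", function() {
  bin_kinship(fx_bins())
})

fx_snp_kinship <- function() fixture("snp_kinship", function() {
  snp_kinship(fx_pop()$genotypes)
})

# study population for the mapping power comparison
fx_study_pop <- function() fixture("study_pop", function() {
  mapping_study_population(n_lines = 500, seed = 4001)
})

# genome-wide bin-scan LRT cutoff for the study population (alpha = 0.05)
fx_study_cutoff <- function() fixture("study_cutoff", function() {
  pop <- fx_study_pop()
  set.seed(4002)
  y <- stats::rnorm(length(pop$geno$samples))
  names(y) <- pop$geno$samples
  permutation_threshold(pop$bins, y, K = pop$K_bin, n_perm = 300,
                        alpha = 0.05, seed = 4003)
})

# full-size population (24 founders) for parameter-recovery and refinement
fx_big_pop <- function() fixture("big_pop", function() {
  map <- synthetic_map(2, 100, 1e7, 400)
  founders <- simulate_founders(24, map, divergence = 0.4, seed = 707)
  pop <- simulate_pedigree_population(founders, n_lines = 1404, seed = 708)
  list(map = map, founders = founders, truth = pop$truth,
       genotypes = pop$genotypes)
})

# marker-resolution bin map over a chromosome window (bins = marker
# intervals, states from the truth mosaic); used by refinement tests
region_bin_map <- function(truth, map, chrom, from, to, every = 1) {
  m <- map[map$chrom == chrom & map$pos_bp >= from & map$pos_bp <= to, ]
  m <- m[seq(1, nrow(m), by = every), ]
  st <- mosaic_states_at(truth, genetic_map(m))
  mid <- floor((m$pos_bp[-1] + m$pos_bp[-nrow(m)]) / 2)
  bins <- data.frame(bin_id = sprintf("rb%04d", seq_len(nrow(m))),
                     chrom = chrom,
                     start_bp = c(from, mid + 1),
                     end_bp = c(mid, to),
                     n_states = apply(st, 2, function(v)
                       length(unique(v[!is.na(v)]))))
  colnames(st) <- bins$bin_id
  structure(list(bins = bins, states = st, samples = rownames(st)),
            class = "bin_map")
}
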