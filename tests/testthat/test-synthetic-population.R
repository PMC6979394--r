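test_that("founder panels hit the requested divergence", {
  map <- synthetic_map(1, 50, 1e6, 200)
  f2 <- simulate_founders(2, map, divergence = 1, seed = 1)
  expect_true(all(f2$alleles[1, ] != f2$alleles[2, ]))

  f0 <- simulate_founders(6, map, divergence = 0, seed = 1)
  expect_true(all(apply(f0$alleles, 2, function(x) length(unique(x))) == 1))

  map10k <- synthetic_map(1, 50, 1e6, 10000)
  f <- simulate_founders(10, map10k, divergence = 0.3, seed = 2)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(founder_divergence(f) - 0.3), 3 * se)

  expect_error(simulate_founders(4, map, divergence = 1.5), "divergence")
  # same seed, same panel
  fa <- simulate_founders(5, map, divergence = 0.4, seed = 9)
  fb <- simulate_founders(5, map, divergence = 0.4, seed = 9)
  expect_identical(fa$alleles, fb$alleles)
})

test_that("zero inter-cross generations give whole-chromosome F1 lines", {
  pop <- simulate_pedigree_population(fx_founders(), n_lines = 6,
                                      n_intercross_gens = 0, seed = 4)
  segs <- segments_per_line(pop$truth)
  expect_true(all(segs == 2))  # one segment per chromosome
  # F1s of two founders are heterozygous wherever the parents differ
  expect_gt(mean(pop$heterozygosity), 0.1)
})

test_that("pedigree simulation matches the breakpoint-rate prediction", {
  pop <- fx_big_pop()
  segs <- segments_per_line(pop$truth)
  L <- sum(map_lengths_cM(pop$map)) / 100
  G_eff <- 8  # 7 inter-cross meioses + ~1 effective from selfing
  expected <- G_eff * L + 2
  expect_lt(abs(mean(segs) - expected) / expected, 0.25)
})

test_that("pedigree simulation is deterministic under a fixed seed", {
  a <- simulate_pedigree_population(fx_founders(), n_lines = 10, seed = 11)
  b <- simulate_pedigree_population(fx_founders(), n_lines = 10, seed = 11)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$truth$start_bp, b$truth$start_bp)
})

test_that("segment lengths are approximately exponential with mean rho/G", {
  # long single chromosome so censoring at the ends is negligible
  map <- synthetic_map(1, 400, 4e7, 400)
  founders <- simulate_founders(24, map, divergence = 0.4, seed = 717)
  pop <- simulate_pedigree_population(founders, n_lines = 500, seed = 718)
  segs <- segments_per_line(pop$truth)
  # realized switch rate per Morgan = the pedigree's effective G
  G_eff <- (mean(segs) - 1) / 4
  seg <- pop$truth
  inner <- seg[seg$start_bp != 1 & seg$end_bp != 4e7, ]  # drop censored ends
  len_cM <- (inner$end_bp - inner$start_bp + 1) / 4e7 * 400
  qq <- stats::qexp(stats::ppoints(length(len_cM)), rate = G_eff / 100)
  slope <- stats::coef(stats::lm(sort(len_cM) ~ qq))[2]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("pseudoprogeny segment allocation and bookkeeping are exact", {
  f <- fx_founders()
  # minimal segmentation: one founder per chromosome
  sim <- simulate_pseudoprogeny(f, n_lines = 4, n_segments = 2, seed = 3)
  expect_true(all(segments_per_line(sim$truth) == 2))

  sim2 <- simulate_pseudoprogeny(f, n_lines = 100, n_segments = 180, seed = 3)
  expect_equal(sum(segments_per_line(sim2$truth)), 18000)
  expect_error(simulate_pseudoprogeny(f, n_lines = 0), "positive")
  expect_error(simulate_pseudoprogeny(f, n_segments = 1), ">=")
})

test_that("pseudoprogeny breakpoints are uniform under a uniform-rate map", {
  f <- fx_founders()
  pvals <- vapply(1:10, function(s) {
    sim <- simulate_pseudoprogeny(f, n_lines = 20, n_segments = 40, seed = s)
    bp <- sim$truth$start_bp[sim$truth$start_bp != 1]
    stats::ks.test(bp / 1e7, "punif")$p.value
  }, numeric(1))
  expect_gt(min(pvals), 0.01)
})

test_that("genotype projection is deterministic given truth and founders", {
  f <- fx_founders()
  sim <- simulate_pseudoprogeny(f, n_lines = 5, n_segments = 10, seed = 7)
  expect_identical(project_genotypes(sim$truth, f)$dosage,
                   sim$genotypes$dosage)
  # projected dosages are homozygous copies of founder alleles
  st <- mosaic_states_at(sim$truth, f$map)
  expect_true(all(sim$genotypes$dosage %in% c(0, 2)))
  expect_equal(sim$genotypes$dosage[1, 17] / 2,
               as.numeric(f$alleles[st[1, 17], 17]))
})

test_that("simulated phenotypes realise the requested architecture", {
  geno <- fx_pop()$genotypes
  mk <- geno$markers$marker_id[c(50, 300, 520)]
  # noise-free limit: exact linear function of dosages
  ph1 <- simulate_phenotype(geno, qtn_spec(mk, h2 = 1), seed = 1)
  gv <- attr(ph1, "genetic_values")
  expect_equal(stats::setNames(ph1$value, ph1$line), gv)
  fitlm <- stats::lm(ph1$value ~ geno$dosage[, mk])
  expect_lt(max(abs(stats::residuals(fitlm))), 1e-10)

  # residual variance 0.2 at h2 = 0.8, Vp = 1
  resid <- replicate(40, {
    ph <- simulate_phenotype(geno, qtn_spec(mk, h2 = 0.8, Vp = 1))
    ph$value - attr(ph, "genetic_values")
  })
  expect_lt(abs(stats::var(as.vector(resid)) - 0.2), 0.01)

  # single biallelic QTN: genotype-class mean difference ~ 2b
  m1 <- geno$markers$marker_id[120]
  ph <- simulate_phenotype(geno, qtn_spec(m1, h2 = 0.5), seed = 42)
  b <- attr(ph, "effects")
  cls <- split(ph$value, geno$dosage[, m1])
  diff_means <- mean(cls[["2"]]) - mean(cls[["0"]])
  se <- sqrt(stats::var(cls[["2"]]) / length(cls[["2"]]) +
             stats::var(cls[["0"]]) / length(cls[["0"]]))
  expect_lt(abs(diff_means - 2 * b), 3 * se)

  expect_error(qtn_spec(m1, h2 = 1.2), "h2")
})

test_that("multi-environment phenotypes add independent noise per environment", {
  geno <- fx_pop()$genotypes
  mk <- geno$markers$marker_id[200]
  ph <- simulate_phenotype(geno, qtn_spec(mk, h2 = 0.8), n_env = 4,
                           env_var = 0.5, seed = 3)
  expect_equal(nrow(ph), 4 * length(geno$samples))
  wide <- matrix(ph$value, ncol = 4)
  resid <- wide - rowMeans(wide)
  expect_lt(abs(stats::var(as.vector(resid)) / (3 / 4) - 0.5), 0.08)
})
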