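test_that("significance thresholds follow alpha over effective tests", {
  expect_equal(signif(significance_threshold(0.05, 4057944), 3), 1.23e-8)
  expect_equal(significance_threshold(0.05, 1), 0.05)
  expect_equal(significance_threshold(0.01, 100), 1e-4)
  expect_error(significance_threshold(1.5, 10), "alpha")
  expect_error(significance_threshold(0.05, 0), "n_eff")
})

test_that("genotype PCs are orthonormal and separate clusters", {
  # two clusters of identical lines
  dos <- rbind(matrix(rep(c(0, 2, 0, 2, 2, 0, 0, 2, 2, 0), 6), 6,
                      byrow = TRUE),
               matrix(rep(c(2, 0, 2, 0, 0, 2, 2, 0, 0, 2), 6), 6,
                      byrow = TRUE))
  g <- genotype_matrix(dos, data.frame(chrom = "c",
                                       pos_bp = seq(10, 100, by = 10)))
  pcs <- genotype_pca(g, k = 2)
  expect_equal(length(unique(round(pcs[1:6, 1], 9))), 1)
  expect_gt(abs(mean(pcs[1:6, 1]) - mean(pcs[7:12, 1])), 0.1)

  geno <- fx_pop()$genotypes
  pcs2 <- genotype_pca(geno, k = 5)
  expect_equal(crossprod(pcs2), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(genotype_pca(geno, k = length(geno$samples)), "smaller")
})

test_that("PC1 variance fraction matches the brute-force eigen ratio", {
  geno <- subset_genotypes(fx_pop()$genotypes, markers = 1:150)
  pcs <- genotype_pca(geno, k = 3)
  D <- geno$dosage
  D[is.na(D)] <- 0
  mu <- colMeans(D); sdv <- apply(D, 2, sd)
  Xs <- scale(D[, sdv > 0], center = mu[sdv > 0], scale = sdv[sdv > 0])
  ev <- eigen(tcrossprod(Xs) / ncol(Xs), symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(attr(pcs, "var_explained")[1], ev[1] / sum(pmax(ev, 0)),
               tolerance = 1e-8)
})

test_that("the mixed-model scan degenerates to OLS under identity kinship", {
  geno <- subset_genotypes(fx_pop()$genotypes, markers = seq(1, 800, by = 8))
  set.seed(3)
  y <- stats::rnorm(length(geno$samples)) + geno$dosage[, 30] * 0.4
  names(y) <- geno$samples
  K <- diag(length(y))
  dimnames(K) <- list(geno$samples, geno$samples)
  scan <- lmm_scan(geno, y, K = K, maf_min = 0)
  ols <- apply(geno$dosage, 2, function(g) {
    if (stats::sd(g) == 0) return(NA_real_)
    summary(stats::lm(y ~ g))$coefficients[2, 4]
  })
  ok <- !is.na(scan$p) & !is.na(ols)
  expect_gt(sum(ok), 50)
  expect_equal(scan$p[ok], unname(ols[ok]), tolerance = 1e-8)
})

test_that("exact and P3D scans agree for null markers", {
  geno <- subset_genotypes(fx_pop()$genotypes,
                           markers = seq(5, 800, by = 40), lines = 1:80)
  set.seed(8)
  y <- stats::rnorm(80)
  names(y) <- geno$samples
  K <- fx_snp_kinship()[1:80, 1:80]
  p3d <- lmm_scan(geno, y, K = K, maf_min = 0)
  exact <- lmm_scan(geno, y, K = K, maf_min = 0, exact = TRUE)
  ok <- !is.na(p3d$p)
  expect_true(all(abs(log10(p3d$p[ok]) - log10(exact$p[ok])) < 1))
})

test_that("the scan localises a strong QTN and respects the MAF filter", {
  pop <- fx_pop()
  geno <- pop$genotypes
  mk <- geno$markers$marker_id[310]
  ph <- simulate_phenotype(geno, qtn_spec(mk, h2 = 0.4), seed = 6)
  y <- stats::setNames(ph$value, ph$line)
  scan <- lmm_scan(geno, y, K = fx_snp_kinship(),
                   pcs = genotype_pca(geno, 3))
  expect_true(all(is.na(scan$p[!is.na(scan$maf) & scan$maf < 0.02])))
  top <- scan[which.min(scan$p), ]
  expect_equal(top$chrom, geno$markers$chrom[310])
  expect_lt(abs(top$pos_bp - geno$markers$pos_bp[310]), 5e5)
})

r2_of <- function(geno, a, b) marker_r2(geno, a, b)

test_that("sQTL grouping applies the chain, size, LD-merge and extension rules", {
  # synthetic association table over one chromosome
  mk_pos <- c(100, 15000, 40000, 2e6, 2.015e6, 6e6, 6.01e6)
  n <- 200
  set.seed(42)
  base <- sample(0:2, n, replace = TRUE)
  corr <- ifelse(stats::runif(n) < 0.75, base, sample(0:2, n, TRUE))
  dos <- cbind(base, base, sample(0:2, n, TRUE), base,
               sample(0:2, n, TRUE), corr, sample(0:2, n, TRUE))
  geno <- genotype_matrix(dos, data.frame(chrom = "chr1", pos_bp = mk_pos))
  assoc <- data.frame(marker_id = geno$markers$marker_id, chrom = "chr1",
                      pos_bp = mk_pos, maf = 0.5,
                      beta = 1, se = 0.1,
                      p = c(1e-10, 1e-12, 1e-9, 1e-10, 1e-9, 1e-10, 0.5),
                      beta_sd = 1)
  class(assoc) <- c("assoc_result", "data.frame")

  # chain: SNPs at 100 and 15 kb (gap < 20 kb); singleton at 40 kb dropped;
  # locus at 2 Mb; locus at 6 Mb has only one significant SNP -> dropped
  q <- group_sqtl(assoc, geno, threshold = 1e-8, ld_merge_r2 = 2)
  expect_equal(nrow(q), 2)
  expect_equal(q$n_snps, c(2, 2))
  # first locus is narrow with a strong peak -> extended 25 kb both sides
  expect_equal(q$start_bp, c(1, 2e6))
  expect_equal(q$end_bp, c(40000, 2.015e6))

  # LD merge: markers 100/15000 correlate perfectly with marker at 2 Mb
  q2 <- group_sqtl(assoc, geno, threshold = 1e-8, ld_merge_r2 = 0.2)
  expect_equal(nrow(q2), 1)
  expect_gte(r2_of(geno, 1, 4), 0.2)
  # merged span 100..2.015 Mb exceeds 50 kb, so no extension applies
  expect_equal(q2$start_bp, 100)
  expect_equal(q2$end_bp, 2.015e6)
})

test_that("narrow strong loci are extended by 25 kb on both sides", {
  n <- 100
  set.seed(1)
  dos <- cbind(a = sample(0:2, n, TRUE), b = sample(0:2, n, TRUE))
  geno <- genotype_matrix(dos, data.frame(chrom = "chr1",
                                          pos_bp = c(5e5, 5.1e5)))
  assoc <- data.frame(marker_id = geno$markers$marker_id, chrom = "chr1",
                      pos_bp = c(5e5, 5.1e5), maf = 0.5, beta = 1, se = 0.1,
                      p = c(1e-12, 1e-9), beta_sd = 1)
  class(assoc) <- c("assoc_result", "data.frame")
  q <- group_sqtl(assoc, geno, threshold = 1e-8, ld_merge_r2 = 2)
  # span 10 kb < 50 kb and peak P = 1e-12 < 1e-8/100
  expect_equal(q$start_bp, 5e5 - 25000)
  expect_equal(q$end_bp, 5.1e5 + 25000)

  weak <- assoc
  weak$p <- c(1e-9, 1e-9)  # strong-peak condition fails
  qw <- group_sqtl(weak, geno, threshold = 1e-8, ld_merge_r2 = 2)
  expect_equal(qw$start_bp, 5e5)
  expect_equal(qw$end_bp, 5.1e5)

  none <- assoc
  none$p <- c(0.5, 0.7)
  expect_equal(nrow(group_sqtl(none, geno, threshold = 1e-8)), 0)
})

test_that("null scans are calibrated at the nominal type-I level", {
  # pseudoprogeny population: realistic LD, kinship handled by the model
  map <- synthetic_map(2, 100, 1e7, 1250)
  f <- simulate_founders(12, map, divergence = 0.4, seed = 51)
  sim <- simulate_pseudoprogeny(f, n_lines = 250, n_segments = 60, seed = 52)
  K <- snp_kinship(sim$genotypes)
  pcs <- genotype_pca(sim$genotypes, 3)
  set.seed(53)
  rate <- vapply(1:4, function(i) {
    y <- stats::rnorm(250)
    names(y) <- sim$genotypes$samples
    scan <- lmm_scan(sim$genotypes, y, K = K, pcs = pcs, maf_min = 0)
    mean(scan$p <= 0.01, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(rate), 0.005)
  expect_lte(mean(rate), 0.02)
})
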