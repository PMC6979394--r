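random_geno <- function(n, pos, seed, chrom = "chr1") {
  set.seed(seed)
  dos <- sapply(seq_along(pos), function(j) {
    p <- stats::runif(1, 0.2, 0.8)
    stats::rbinom(n, 2, p)
  })
  genotype_matrix(dos, data.frame(chrom = chrom, pos_bp = pos))
}

test_that("LD pruning removes duplicated markers and keeps independent ones", {
  g <- random_geno(120, seq(1000, 30000, by = 1000), seed = 1)
  # insert an exact duplicate of marker 5 right next to it
  dos <- cbind(g$dosage[, 1:5], g$dosage[, 5], g$dosage[, 6:30])
  g2 <- genotype_matrix(dos, data.frame(chrom = "chr1",
                                        pos_bp = c(seq(1000, 5000, 1000),
                                                   5500,
                                                   seq(6000, 30000, 1000))))
  pruned <- prune_variants(g2, r2_max = 0.5)
  expect_false("chr1_5500" %in% pruned$markers$marker_id)
  expect_true("chr1_5000" %in% pruned$markers$marker_id)

  # near-independent markers all survive
  g3 <- random_geno(500, seq(1000, 20000, by = 1000), seed = 2)
  expect_equal(nrow(prune_variants(g3, r2_max = 0.5)$markers), 20)

  # MAF filter applies first
  dos4 <- g$dosage
  dos4[, 3] <- c(2, rep(0, 119))
  g4 <- genotype_matrix(dos4, g$markers)
  expect_false("chr1_3000" %in%
               prune_variants(g4, maf_min = 0.02)$markers$marker_id)
})

test_that("window pruning equals the brute-force greedy oracle", {
  set.seed(7)
  n <- 150
  base <- stats::rbinom(n, 2, 0.5)
  dos <- sapply(1:10, function(j) {
    ifelse(stats::runif(n) < 0.6, base, stats::rbinom(n, 2, 0.5))
  })
  g <- genotype_matrix(dos, data.frame(chrom = "chr1",
                                       pos_bp = seq(100, 1000, by = 100)))
  pruned <- prune_variants(g, maf_min = 0, r2_max = 0.3, window_bp = 50000,
                           step_snps = 5)
  oracle <- oracle_prune_window(g, 1:10, r2_max = 0.3)
  expect_equal(match(pruned$markers$marker_id, g$markers$marker_id), oracle)
})

test_that("pure interactions are detected; the scan is symmetric in the pair", {
  g <- random_geno(200, c(1e5, 5e6), seed = 3)
  y <- g$dosage[, 1] * g$dosage[, 2]
  names(y) <- g$samples
  pairs <- pairwise_scan(g, y, first_pass_p = 1e-10)
  expect_equal(nrow(pairs), 1)
  expect_lt(pairs$raw_p, 1e-50)

  # swapping marker order changes nothing
  g_swap <- subset_genotypes(g, markers = c(2, 1))
  pairs2 <- pairwise_scan(g_swap, y, first_pass_p = 1e-10)
  expect_equal(pairs2$raw_p, pairs$raw_p)
  expect_equal(sort(c(pairs2$pos_a, pairs2$pos_b)),
               sort(c(pairs$pos_a, pairs$pos_b)))
})

test_that("additive-only phenotypes give calibrated interaction type-I error", {
  g <- random_geno(400, seq(1e5, by = 2e6, length.out = 150), seed = 4)
  set.seed(5)
  beta <- stats::rnorm(150, 0, 0.05)
  y <- drop(g$dosage %*% beta) + stats::rnorm(400)
  names(y) <- g$samples
  D <- g$dosage
  n_pairs <- 0
  n_sig <- 0
  for (a in 1:149) {
    for (b in (a + 1):150) {
      r <- magicmap:::interaction_test(y, D[, a], D[, b])
      n_pairs <- n_pairs + 1
      if (r[["p"]] <= 0.01) n_sig <- n_sig + 1
    }
  }
  expect_gt(n_pairs, 10000)
  rate <- n_sig / n_pairs
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.02)
})

test_that("locus-uniqueness keeps only the most significant nearby pair", {
  # three pairs whose endpoints all lie within 100 kb of each other
  set.seed(6)
  n <- 300
  ga <- stats::rbinom(n, 2, 0.5)
  gb <- stats::rbinom(n, 2, 0.5)
  noise <- function() ifelse(stats::runif(n) < 0.05,
                             stats::rbinom(n, 2, 0.5), NA)
  jitter2 <- function(v) ifelse(is.na(w <- noise()), v, w)
  dos <- cbind(ga, jitter2(ga), jitter2(ga), gb, jitter2(gb), jitter2(gb))
  g <- genotype_matrix(dos, data.frame(chrom = "chr1",
                                       pos_bp = c(1e5, 1.2e5, 1.4e5,
                                                  8e6, 8.02e6, 8.04e6)))
  y <- ga * gb + stats::rnorm(n, 0, 0.3)
  names(y) <- g$samples
  pairs <- pairwise_scan(g, y, first_pass_p = 1e-8)
  left_in_a <- pairs$pos_a < 1e6
  expect_equal(sum(left_in_a), 1)
  # the retained representative is the most significant of its cluster
  all_p <- c()
  for (a in 1:3) for (b in 4:6) {
    all_p <- c(all_p, magicmap:::interaction_test(y, dos[, a],
                                                  dos[, b])[["p"]])
  }
  expect_equal(pairs$raw_p, min(all_p))
})

test_that("adjustment removes structure-confounded pairs, keeps real ones", {
  set.seed(8)
  n <- 400
  cluster <- rep(0:1, each = n / 2)
  # two markers strongly differentiated between subpopulations
  ga <- stats::rbinom(n, 2, 0.15 + 0.7 * cluster)
  gb <- stats::rbinom(n, 2, 0.15 + 0.7 * cluster)
  g <- genotype_matrix(cbind(ga, gb),
                       data.frame(chrom = "chr1", pos_bp = c(1e5, 9e6)))
  y <- 2 * cluster + stats::rnorm(n, 0, 0.1)   # structure-driven trait
  names(y) <- g$samples
  pcs <- cbind(PC1 = cluster - mean(cluster))
  raw <- pairwise_scan(g, y, first_pass_p = 1e-4)
  if (nrow(raw) > 0) {
    adj <- adjust_pairs(raw, g, y, pcs = pcs, final_p = 1e-4)
    expect_equal(nrow(adj), 0)
  }

  # a genuine noise-free interaction survives with PVE near its true share
  gi <- random_geno(500, c(1e5, 5e6), seed = 9)
  zi <- scale(gi$dosage[, 1], scale = FALSE) *
    scale(gi$dosage[, 2], scale = FALSE)
  y2 <- drop(zi)
  names(y2) <- gi$samples
  raw2 <- pairwise_scan(gi, y2, first_pass_p = 1e-10)
  adj2 <- adjust_pairs(raw2, gi, y2, final_p = 1e-10)
  expect_equal(nrow(adj2), 1)
  expect_gt(adj2$pve, 0.95)

  # determinism: duplicated pair rows give identical adjusted P
  adj3 <- adjust_pairs(rbind(raw2, raw2), gi, y2, final_p = 1e-10)
  expect_equal(adj3$adj_p[1], adj3$adj_p[2])
})

test_that("joint epistatic variance recovers an engineered share", {
  expect_equal(joint_epistatic_variance(magicmap:::empty_pairs(), fx_pop()$genotypes,
                                        stats::rnorm(150))$r2, 0)

  pop <- fx_big_pop()
  geno <- pop$genotypes
  maf <- marker_maf(geno)
  idx <- which(maf > 0.2)
  mk <- geno$markers$marker_id[idx[c(5, length(idx) - 5)]]
  est <- vapply(1:20, function(s) {
    spec <- qtn_spec(mk, ranks = c(1, 2), h2 = 0.4,
                     epi_pairs = cbind(mk[1], mk[2]), epi_pve = 0.10)
    ph <- simulate_phenotype(geno, spec, seed = 900 + s)
    y <- stats::setNames(ph$value, ph$line)
    pairs <- data.frame(marker_a = mk[1], marker_b = mk[2],
                        chrom_a = "chr1", pos_a = 1, chrom_b = "chr1",
                        pos_b = 2, beta_int = 1, raw_p = 0, adj_p = 0)
    joint_epistatic_variance(pairs, geno, y)$r2
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.10), 0.03)

  # nesting: joint R2 at least the largest single-pair PVE
  spec <- qtn_spec(mk, ranks = c(1, 2), h2 = 0.3,
                   epi_pairs = cbind(mk[1], mk[2]), epi_pve = 0.15)
  ph <- simulate_phenotype(geno, spec, seed = 999)
  y <- stats::setNames(ph$value, ph$line)
  pr <- data.frame(marker_a = mk[1], marker_b = mk[2], chrom_a = "chr1",
                   pos_a = 1, chrom_b = "chr1", pos_b = 2, beta_int = 1,
                   raw_p = 0)
  adj <- adjust_pairs(pr, geno, y, final_p = 1)
  expect_gte(joint_epistatic_variance(adj, geno, y)$r2,
             max(adj$pve) - 1e-4)
})

test_that("pair categories follow sQTL linkage of the two sides", {
  sqtl <- data.frame(trait = c("t1", "t1", "t2"),
                     chrom = c("chr1", "chr2", "chr1"),
                     start_bp = c(1e6, 5e6, 40e6),
                     end_bp = c(1.2e6, 5.2e6, 40.2e6))
  pairs <- data.frame(
    marker_a = paste0("a", 1:4), marker_b = paste0("b", 1:4),
    chrom_a = c("chr1", "chr1", "chr1", "chr3"),
    pos_a = c(1.1e6, 1.21e6, 1.1e6, 1e6),
    chrom_b = c("chr2", "chr1", "chr9", "chr3"),
    pos_b = c(5.1e6, 40.1e6, 1e6, 9e6),
    beta_int = 1, raw_p = 0, adj_p = 0)
  out <- categorize_pairs(pairs, sqtl, link_bp = 50000)
  expect_equal(out$pairs$category, c("SS-1", "SS-2", "SN", "NN"))
  expect_equal(unname(out$fractions), rep(0.25, 4))
})

test_that("recombinant fractions count lines with different founder origins", {
  bins <- fx_bins()
  b <- bins$bins$bin_id[c(3, 900)]
  rf <- recombinant_fraction(bins, b[1], b[2])
  st <- bins$states[, c(3, 900)]
  ok <- !is.na(st[, 1]) & !is.na(st[, 2])
  expect_equal(rf, mean(st[ok, 1] != st[ok, 2]))
  expect_equal(recombinant_fraction(bins, b[1], b[1]), 0)
})
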