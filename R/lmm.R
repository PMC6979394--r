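# Single-kinship REML machinery (EMMA-style): the model is
#   y = X beta + u + e,  u ~ N(0, sg2 K),  e ~ N(0, se2 I).
# On the eigenbasis of K the covariance is diagonal, so the restricted
# likelihood is profiled over delta = se2/sg2 by 1-D optimisation.

#' Fit the null linear mixed model by REML
#'
#' @param y numeric response (one value per line).
#' @param X fixed-effect design matrix (include the intercept column).
#' @param K positive semidefinite kinship matrix.
#' @return list with `delta` (se2/sg2), `sigma_g2`, `sigma_e2`, `logL_reml`,
#'   `U` (eigenvectors of K), `lambda` (eigenvalues), `beta`.
#' @export
lmm_null_fit <- function(y, X, K) {
  n <- length(y)
  X <- as.matrix(X)
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
    stop(sprintf("kinship not PSD (smallest eigenvalue %.3g)", min(eg$values)))
  }
  lambda <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  p <- ncol(X)

  reml <- function(log_delta) {
    delta <- exp(log_delta)
    w <- lambda + delta
    sw <- 1 / sqrt(w)
    Xw <- Xt * sw
    yw <- yt * sw
    qr_x <- qr(Xw)
    res <- qr.resid(qr_x, yw)
    rss <- sum(res^2)
    sg2 <- rss / (n - p)
    XtX <- crossprod(Xw)
    -0.5 * ((n - p) * log(2 * pi * sg2) + sum(log(w)) +
            determinant(XtX, logarithm = TRUE)$modulus + (n - p))
  }
  grid <- seq(log(1e-5), log(1e5), length.out = 40)
  vals <- vapply(grid, reml, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(reml, c(lo, hi), maximum = TRUE, tol = 1e-6)
  delta <- exp(opt$maximum)
  w <- lambda + delta
  sw <- 1 / sqrt(w)
  Xw <- Xt * sw
  yw <- yt * sw
  qr_x <- qr(Xw)
  beta <- qr.coef(qr_x, yw)
  rss <- sum(qr.resid(qr_x, yw)^2)
  sg2 <- rss / (n - p)
  list(delta = delta, sigma_g2 = sg2, sigma_e2 = sg2 * delta,
       logL_reml = opt$objective, U = U, lambda = lambda, beta = beta)
}

#' Principal components of the genotype matrix
#'
#' PCs of the centered, unit-variance-scaled dosage matrix, computed from the
#' eigendecomposition of the realized covariance between lines. Missing
#' dosages are mean-imputed; monomorphic markers are ignored. Signs are fixed
#' by making the largest-magnitude marker loading of each PC positive.
#'
#' @param geno a [genotype_matrix()].
#' @param k number of components (default 10).
#' @return matrix of PC scores (lines x k) with eigenvalue-based variance
#'   fractions in attribute `var_explained`.
#' @export
genotype_pca <- function(geno, k = 10) {
  n <- length(geno$samples)
  if (k >= n) stop("k must be smaller than the number of lines")
  Xs <- standardize_dosage(geno$dosage)
  G <- tcrossprod(Xs) / ncol(Xs)
  eg <- eigen(G, symmetric = TRUE)
  scores <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    loading <- crossprod(Xs, scores[, j])
    if (loading[which.max(abs(loading))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(geno$samples, paste0("PC", seq_len(k)))
  attr(scores, "var_explained") <- eg$values[seq_len(k)] / sum(pmax(eg$values, 0))
  scores
}

standardize_dosage <- function(D) {
  D[is.na(D)] <- matrix(colMeans(D, na.rm = TRUE),
                        nrow(D), ncol(D), byrow = TRUE)[is.na(D)]
  mu <- colMeans(D)
  sdv <- apply(D, 2, stats::sd)
  keep <- sdv > 0
  scale(D[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
}

#' SNP-based kinship matrix
#'
#' Centered cross-product of the dosage matrix divided by the number of
#' markers (missing dosages mean-imputed).
#'
#' @param geno a [genotype_matrix()].
#' @return N x N kinship matrix.
#' @export
snp_kinship <- function(geno) {
  D <- geno$dosage
  D[is.na(D)] <- matrix(colMeans(D, na.rm = TRUE),
                        nrow(D), ncol(D), byrow = TRUE)[is.na(D)]
  C <- sweep(D, 2, colMeans(D))
  K <- tcrossprod(C) / ncol(C)
  dimnames(K) <- list(geno$samples, geno$samples)
  K
}
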