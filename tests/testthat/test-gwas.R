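make_geno <- function(n, m, seed = 1) {
  set.seed(seed)
  sapply(runif(m, 0.1, 0.9), function(p) rbinom(n, 2, p))
}

test_that("standardized GRM has unit diagonal mean and honors exclusions", {
  X <- make_geno(60, 1200, seed = 2)
  G <- standardized_grm(X)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
  # dataset path: excluding an absent chromosome changes nothing
  ds <- tiny_dataset(t(X[, 1:50]), pos = (1:50) * 1000,
                     pops = rep("p", 60))
  expect_equal(standardized_grm(ds, exclude_chromosome = "chrQ"),
               standardized_grm(ds), ignore_attr = TRUE)
  # duplicated sample: off-diagonal equals both diagonals
  X2 <- rbind(X, X[1, ])
  G2 <- standardized_grm(X2)
  expect_equal(G2[1, 61], G2[1, 1], tolerance = 1e-12)
  expect_equal(G2[61, 61], G2[1, 1], tolerance = 1e-12)
})

test_that("mixed model collapses to ordinary least squares when G = I", {
  set.seed(3)
  n <- 120
  X <- make_geno(n, 100, seed = 4)
  batches <- factor(rep_len(1:3, n))
  y <- rnorm(n) + c(0, 0.5, 1)[batches] + 0.3 * X[, 1]
  res <- lmm_assoc(y, batches, X, diag(n))
  ols <- t(sapply(seq_len(ncol(X)), function(j) {
    s <- summary(lm(y ~ X[, j] + batches))$coefficients["X[, j]", ]
    c(beta = s[[1]], se = s[[2]],
      p = pchisq((s[[1]] / s[[2]])^2, 1, lower.tail = FALSE))
  }))
  expect_lt(max(abs(res$wald_p - ols[, "p"])), 1e-6)
  expect_lt(max(abs(res$beta - ols[, "beta"])), 1e-6)
})

test_that("association is invariant to a constant phenotype shift", {
  set.seed(5)
  n <- 80
  X <- make_geno(n, 30, seed = 6)
  G <- standardized_grm(make_geno(n, 500, seed = 7))
  batches <- factor(rep_len(1:2, n))
  y <- rnorm(n)
  r1 <- lmm_assoc(y, batches, X, G)
  r2 <- lmm_assoc(y + 100, batches, X, G)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-6)
  expect_equal(r1$wald_p, r2$wald_p, tolerance = 1e-6)
})

test_that("degenerate designs and SNPs are refused or flagged", {
  n <- 40
  X <- make_geno(n, 5, seed = 8)
  y <- rnorm(n)
  expect_error(lmm_assoc(y, factor(rep(1, n), levels = 1:2)[1:n], X,
                         diag(n)), "singular")
  Xm <- cbind(X, mono = rep(1L, n))
  res <- lmm_assoc(y, NULL, Xm, diag(n))
  expect_true(is.na(res$wald_p[6]))
  expect_false(anyNA(res$wald_p[1:5]))
})

test_that("identical chromosomes give identical LOCO results", {
  set.seed(9)
  n <- 50; m <- 80
  g <- t(make_geno(n, m, seed = 10))
  ds <- genotype_dataset(
    samples = data.frame(sample = sprintf("s%02d", 1:n),
                         population = "p"),
    sites = data.frame(chrom = rep(c("chr1", "chr2"), each = m),
                       pos = rep((1:m) * 1000, 2),
                       ref = "A", alt = "C"),
    geno = rbind(g, g))
  ph <- data.frame(sample = sprintf("s%02d", 1:n), trait = rnorm(n),
                   batch = factor(rep_len(1:2, n)))
  res <- loco_scan(ds, ph)
  r1 <- res$snps[res$snps$chrom == "chr1", c("beta", "se", "wald_p")]
  r2 <- res$snps[res$snps$chrom == "chr2", c("beta", "se", "wald_p")]
  expect_equal(r1, r2, ignore_attr = TRUE)
  # single-chromosome input needs the explicit no-LOCO override
  ds1 <- subset_sites(ds, 1:m)
  expect_error(loco_scan(ds1, ph), "loco = FALSE")
  expect_s3_class(loco_scan(ds1, ph, loco = FALSE), "assoc_result")
})

test_that("a planted causal SNP is the genome-wide top hit in most seeds", {
  hits <- vapply(1:6, function(s) {
    cfg <- sim_config(n_pop1 = 300, n_pop2 = 10, n_chrom = 2,
                      chrom_length_bp = 2e6, n_sites = 500,
                      missing_rate = 0, sweep_alpha = NULL, n_causal = 1,
                      h2_snp = 0.1, h2_poly = 0.2, seed = 100 + s)
    ds <- simulate_divergent_genotypes(cfg)
    ph <- simulate_phenotypes(ds, cfg)
    focal <- subset_samples(ds, 1:300)
    res <- loco_scan(focal, ph$phenotypes)
    res$snps$pos[which.min(res$snps$wald_p)] == ph$causal$pos[1]
  }, logical(1))
  expect_gte(sum(hits), 5)
})

test_that("null traits give a calibrated genomic inflation factor", {
  lambdas <- vapply(1:6, function(s) {
    cfg <- sim_config(n_pop1 = 200, n_pop2 = 10, n_chrom = 2,
                      chrom_length_bp = 2e6, n_sites = 400,
                      missing_rate = 0, sweep_alpha = NULL, n_causal = 0,
                      h2_snp = 0, h2_poly = 0, seed = 200 + s)
    ds <- simulate_divergent_genotypes(cfg)
    ph <- simulate_phenotypes(ds, cfg)
    res <- loco_scan(subset_samples(ds, 1:200), ph$phenotypes)
    res$lambda_gc
  }, numeric(1))
  expect_gt(mean(lambdas), 0.9)
  expect_lt(mean(lambdas), 1.1)
})

test_that("SimpleM counts principal components per chromosome", {
  # two perfectly correlated SNPs: a single effective test
  x <- rbinom(30, 2, 0.5)
  ds <- tiny_dataset(rbind(x, x), pos = c(100, 200), pops = rep("p", 30))
  expect_equal(simpleM_eff(ds), 1L)
  # mutually orthogonal dosage columns: ceiling(0.99 M) effective tests
  H <- as.matrix(expand.grid(rep(list(c(-1, 1)), 3)))   # 8 x 3 orthogonal
  X <- cbind(H, H[, 1] * H[, 2]) + 1                    # dosages 0/2
  ds2 <- tiny_dataset(t(X), pos = (1:4) * 100, pops = rep("p", 8))
  expect_equal(simpleM_eff(ds2), ceiling(0.99 * 4))
  # random correlated block equals a direct eigen decomposition oracle
  set.seed(11)
  base <- rbinom(40, 2, 0.5)
  X3 <- sapply(1:12, function(i) {
    flip <- runif(40) < 0.2
    out <- base; out[flip] <- rbinom(sum(flip), 2, 0.5); out
  })
  ds3 <- tiny_dataset(t(X3), pos = (1:12) * 50, pops = rep("p", 40))
  ev <- eigen(cor(X3), symmetric = TRUE, only.values = TRUE)$values
  want <- which(cumsum(ev) / sum(ev) >= 0.99)[1]
  expect_equal(simpleM_eff(ds3), want)
  # the sample-space path agrees when SNPs outnumber samples
  X4 <- make_geno(10, 25, seed = 12)
  ds4 <- tiny_dataset(t(X4), pos = (1:25) * 50, pops = rep("p", 10))
  ev4 <- eigen(cor(X4), symmetric = TRUE, only.values = TRUE)$values
  want4 <- which(cumsum(ev4) / sum(ev4) >= 0.99 - 1e-12)[1]
  expect_equal(simpleM_eff(ds4), want4)
  # duplicating an existing SNP never increases the effective count
  ds5 <- tiny_dataset(rbind(t(X3), X3[, 1]), pos = c((1:12) * 50, 1000),
                      pops = rep("p", 40))
  expect_lte(simpleM_eff(ds5), simpleM_eff(ds3) + 0)
})

test_that("the SimpleM threshold follows alpha over the effective count", {
  thr <- significance_threshold(4853)
  expect_equal(signif(thr$threshold, 3), 1.03e-5)
  expect_equal(thr$neglog10, 4.98)
  expect_equal(significance_threshold(1)$threshold, 0.05)
  expect_error(significance_threshold(0), "m_eff")
})
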