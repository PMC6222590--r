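test_that("generators are deterministic under a fixed seed", {
  cfg <- quick_sim(seed = 11)
  d1 <- simulate_divergent_genotypes(cfg)
  d2 <- simulate_divergent_genotypes(cfg)
  expect_identical(d1$geno, d2$geno)
  expect_identical(d1$sites, d2$sites)
  s <- site_sfs(1 / (1:39), 40)
  sw1 <- simulate_sweep_sites(s, 40, 1e-5, 5e5, c(1e5, 4e5, 9e5), seed = 3)
  sw2 <- simulate_sweep_sites(s, 40, 1e-5, 5e5, c(1e5, 4e5, 9e5), seed = 3)
  expect_identical(sw1, sw2)
})

test_that("Balding-Nichols differentiation is recovered by Weir-Cockerham",
{
  # F = 0: no differentiation, mean per-site theta within 0.01 of zero
  cfg0 <- sim_config(n_pop1 = 50, n_pop2 = 50, n_chrom = 1,
                     chrom_length_bp = 5e6, n_sites = 5000, fst_param = 0,
                     sweep_alpha = NULL, missing_rate = 0, seed = 5)
  st0 <- fst_site_table(simulate_divergent_genotypes(cfg0))
  expect_lt(abs(mean(st0$theta, na.rm = TRUE)), 0.01)
  # F = 0.2: the variance-component ratio estimates F
  cfg2 <- sim_config(n_pop1 = 50, n_pop2 = 50, n_chrom = 1,
                     chrom_length_bp = 5e6, n_sites = 5000, fst_param = 0.2,
                     sweep_alpha = NULL, missing_rate = 0, seed = 5)
  st2 <- fst_site_table(simulate_divergent_genotypes(cfg2))
  est <- sum(st2$a) / sum(st2$a + st2$b + st2$c)
  expect_lt(abs(est - 0.2), 0.02)
})

test_that("invalid differentiation or heritability parameters are rejected", {
  expect_error(sim_config(fst_param = 1), "fst_param")
  expect_error(sim_config(fst_param = -0.1), "fst_param")
  expect_error(sim_config(h2_snp = 0.6, h2_poly = 0.5), "h2_snp")
})

test_that("sweep sampler recovers the background spectrum at large alpha*d", {
  # goodness of fit against the background at escape probability ~ 1
  n <- 40
  s <- site_sfs(1 / (1:(n - 1)), n)
  sw <- simulate_sweep_sites(s, n, 1e-3, 0, rep(1e6, 5000), seed = 7)
  gof <- chisq.test(tabulate(sw$count, n - 1), p = s$probs)
  expect_gt(gof$p.value, 0.01)
  # total-variation agreement where class counts keep the TV noise floor low
  n2 <- 10
  s2 <- site_sfs(1 / (1:(n2 - 1)), n2)
  sw2 <- simulate_sweep_sites(s2, n2, 1e-3, 0, rep(1e6, 5000), seed = 8)
  tv <- sum(abs(tabulate(sw2$count, n2 - 1) / 5000 - s2$probs)) / 2
  expect_lt(tv, 0.02)
})

test_that("sweep sampler matches the model law and skews to extreme classes",
{
  n <- 20
  s <- site_sfs(1 / (1:(n - 1)), n)
  alpha <- 1e-4; d <- 3000              # escape probability ~ 0.26
  want <- sweep_dist_oracle(s$probs, n, alpha, d)
  sw <- simulate_sweep_sites(s, n, alpha, 0, rep(d, 20000), seed = 9)
  emp <- tabulate(sw$count, n - 1) / 20000
  expect_lt(max(abs(emp - want)), 0.02)
  # excess mass at classes 1 and n-1 relative to the background
  expect_gt(want[1], s$probs[1])
  expect_gt(want[n - 1], s$probs[n - 1])
  expect_error(simulate_sweep_sites(s, n, alpha, 500, c(400, 500), seed = 1),
               "distance 0")
  empty <- simulate_sweep_sites(s, n, alpha, 0, numeric(0))
  expect_equal(nrow(empty), 0)
})

test_that("null phenotypes are batch plus noise with uniform test p-values", {
  cfg <- sim_config(n_pop1 = 200, n_pop2 = 20, n_chrom = 1,
                    chrom_length_bp = 2e6, n_sites = 300, missing_rate = 0,
                    sweep_alpha = NULL, n_causal = 0, h2_snp = 0,
                    h2_poly = 0, seed = 21)
  ds <- simulate_divergent_genotypes(cfg)
  ph <- simulate_phenotypes(ds, cfg)
  expect_equal(nrow(ph$causal), 0)
  ph2 <- simulate_phenotypes(ds, cfg)
  expect_identical(ph$phenotypes$trait, ph2$phenotypes$trait)
  # per-SNP OLS p-values (batch-adjusted) should be uniform
  X <- t(ds$geno[, 1:200])
  y <- ph$phenotypes$trait
  b <- ph$phenotypes$batch
  pv <- apply(X, 2, function(x) {
    if (sd(x) == 0) return(NA_real_)
    summary(lm(y ~ x + b))$coefficients["x", 4]
  })
  ks <- suppressWarnings(ks.test(pv[!is.na(pv)], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("causal SNPs jointly explain the configured variance fraction", {
  r2_sums <- vapply(1:10, function(s) {
    cfg <- sim_config(n_pop1 = 300, n_pop2 = 20, n_chrom = 1,
                      chrom_length_bp = 5e6, n_sites = 5000,
                      missing_rate = 0, sweep_alpha = NULL, n_causal = 3,
                      h2_snp = 0.3, h2_poly = 0, seed = s)
    ds <- simulate_divergent_genotypes(cfg)
    ph <- simulate_phenotypes(ds, cfg)
    y <- ph$phenotypes$trait
    b <- ph$phenotypes$batch
    y_adj <- resid(lm(y ~ b))
    sum(vapply(ph$causal$site, function(i) {
      summary(lm(y_adj ~ ds$geno[i, 1:300]))$r.squared
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(r2_sums) - 0.3), 0.1)
})

test_that("written VCF and companions round-trip through read_vcf", {
  cfg <- quick_sim(seed = 31)
  cfg$n_pop1 <- 6L; cfg$n_pop2 <- 4L; cfg$n_sites <- 100L
  cfg$n_chrom <- 1L; cfg$missing_rate <- 0.1
  ds <- simulate_divergent_genotypes(cfg)
  prefix <- file.path(tempdir(), "rt", "sim")
  paths <- write_dataset(ds, data.frame(sample = ds$samples$sample[1:6],
                                        trait = rnorm(6), batch = 1L),
                         prefix)
  lines <- readLines(paths[["vcf"]])
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 100)
  expect_equal(length(strsplit(body[1], "\t")[[1]]), 9 + 10)
  back <- read_vcf(paths[["vcf"]], paths[["popmap"]])
  expect_identical(back$geno, ds$geno)
  expect_equal(back$sites$pos, ds$sites$pos)
  expect_true(file.exists(paths[["genes"]]))
})

test_that("missingness rate in written VCF matches the configuration", {
  cfg <- sim_config(n_pop1 = 50, n_pop2 = 50, n_chrom = 1,
                    chrom_length_bp = 1e6, n_sites = 100,
                    missing_rate = 0.1, sweep_alpha = NULL, seed = 41)
  ds <- simulate_divergent_genotypes(cfg)
  prefix <- file.path(tempdir(), "miss", "sim")
  paths <- write_dataset(ds, NULL, prefix)
  body <- readLines(paths[["vcf"]])
  body <- body[!startsWith(body, "#")]
  gt <- unlist(lapply(strsplit(body, "\t"), function(x) x[-(1:9)]))
  expect_lt(abs(mean(gt == "./.") - 0.1), 0.02)   # 10,000 genotypes
})
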