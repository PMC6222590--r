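write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

test_that("multi-allelic and non-SNP records are skipped with a count", {
  recs <- sprintf("chr1\t%d\t.\tA\tC\t.\t.\t.\tGT\t0/1\t1/1", (1:10) * 100)
  recs[4] <- "chr1\t400\t.\tA\tC,G\t.\t.\t.\tGT\t0/1\t1/1"
  path <- write_test_vcf(c(vcf_header(c("s1", "s2")), recs))
  pm <- data.frame(sample = c("s1", "s2"), population = "p")
  ds <- suppressMessages(read_vcf(path, pm))
  expect_equal(nrow(ds$sites), 9)
  expect_equal(attr(ds, "n_skipped"), 1)
})

test_that("phased and unphased heterozygotes both give dosage 1", {
  recs <- c("chr1\t100\t.\tA\tC\t.\t.\t.\tGT\t0|1\t0/1",
            "chr1\t200\t.\tA\tC\t.\t.\t.\tGT\t1|1\t./.")
  path <- write_test_vcf(c(vcf_header(c("s1", "s2")), recs))
  pm <- data.frame(sample = c("s1", "s2"), population = "p")
  ds <- read_vcf(path, pm)
  expect_equal(ds$geno[1, ], c(1L, 1L))
  expect_equal(ds$geno[2, ], c(2L, NA))
})

test_that("missing files and unknown samples give distinct errors", {
  expect_error(read_vcf("no/such/file.vcf", data.frame(sample = "s",
                                                       population = "p")),
               "not found")
  recs <- "chr1\t100\t.\tA\tC\t.\t.\t.\tGT\t0/1"
  path <- write_test_vcf(c(vcf_header("s1"), recs))
  expect_error(read_vcf(path, data.frame(sample = c("s1", "ghost"),
                                         population = "p")),
               "ghost")
})

test_that("exact HWE test matches full enumeration and its edge cases", {
  expect_equal(hwe_exact_test(0, 1, 0), 1)
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25))
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  # random-count agreement with the enumeration oracle
  set.seed(4)
  for (i in 1:25) {
    cts <- as.vector(rmultinom(1, 60, c(0.3, 0.5, 0.2)))
    expect_equal(hwe_exact_test(cts[1], cts[2], cts[3]),
                 hwe_oracle(cts[1], cts[2], cts[3]), tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("HWE p is symmetric under allele relabeling", {
  set.seed(8)
  for (i in 1:20) {
    cts <- as.vector(rmultinom(1, 40, runif(3, 0.1, 1)))
    expect_equal(hwe_exact_test(cts[1], cts[2], cts[3]),
                 hwe_exact_test(cts[3], cts[2], cts[1]), tolerance = 1e-12)
  }
})

test_that("adjacency rule keeps greedy left-to-right survivors", {
  g <- matrix(1L, 3, 8)
  g[, 1] <- 0L  # polymorphic
  ds <- tiny_dataset(g, pos = c(100, 103, 109))
  out <- filter_sites(ds, qc_thresholds(min_maf = 0))
  expect_equal(out$sites$pos, c(100, 109))
  rep_tab <- attr(out, "filter_report")
  expect_equal(rep_tab$sites_removed[rep_tab$criterion == "adjacency"], 1L)
})

test_that("MAF filter removes rare variants at the documented cutoff", {
  set.seed(2)
  n <- 300
  g <- rbind(c(1L, rep(0L, n - 1)),            # MAF 1/600 ~ 0.0017
             c(rep(1L, 10), rep(0L, n - 10)))  # MAF 10/600 ~ 0.017
  ds <- tiny_dataset(g, pos = c(1000, 2000), pops = rep("p", n))
  out <- filter_sites(ds, qc_thresholds())
  expect_equal(out$sites$pos, 2000)
})

test_that("filter report attributes each site to its first failed criterion", {
  # plant known violations: 2 depth, 1 mapq, 1 adjacency, 1 missingness,
  # 1 maf -- the depth-failing site would also fail maf but must count once
  set.seed(9)
  n <- 40
  g <- matrix(rbinom(8 * n, 2, 0.4), 8, n)
  g[1, ] <- 0L; g[1, 1] <- 1L               # low maf AND low depth
  g[5, seq_len(n / 2)] <- NA_integer_       # missing in pop1
  g[7, ] <- 0L; g[7, 2] <- 1L               # low maf only
  ds <- tiny_dataset(g, pos = c(1000, 2000, 3000, 3002, 5000, 6000, 7000,
                                8000),
                     pops = rep(c("p1", "p2"), each = n / 2))
  ds$sites$depth <- c(2, 50, 50, 50, 50, 2, 50, 50)     # sites 1, 6
  ds$sites$mapq <- c(50, 10, 50, 50, 50, 50, 50, 50)    # site 2
  out <- filter_sites(ds, qc_thresholds(max_missing = 0.4, min_maf = 0.02))
  rep_tab <- attr(out, "filter_report")
  counts <- setNames(rep_tab$sites_removed, rep_tab$criterion)
  expect_equal(counts[["depth"]], 2L)
  expect_equal(counts[["mapq"]], 1L)
  expect_equal(counts[["adjacency"]], 1L)
  expect_equal(counts[["missingness"]], 1L)
  expect_equal(counts[["maf"]], 1L)
  expect_equal(sum(rep_tab$sites_removed), 8L - nrow(out$sites))
})

test_that("HWE filter applies only when requested", {
  n <- 60
  g <- rbind(c(rep(0L, n / 2), rep(2L, n / 2)),        # het deficit
             rep(c(0L, 1L, 2L), length.out = n))
  g[2, 1] <- 1L
  ds <- tiny_dataset(g, pos = c(1000, 2000), pops = rep("p", n))
  no_hwe <- filter_sites(ds, qc_thresholds())
  expect_equal(nrow(no_hwe$sites), 2)
  with_hwe <- filter_sites(ds, qc_thresholds(), hwe = TRUE)
  expect_equal(with_hwe$sites$pos, 2000)
})

test_that("imputation is frequency-faithful and never touches observed data",
{
  g <- matrix(2L, 4, 10)
  ds0 <- tiny_dataset(g, pops = rep("p", 10))
  expect_identical(impute_missing(ds0)$geno, ds0$geno)   # nothing missing
  # population frequency 1.0 -> the only possible imputation is 2
  g1 <- g; g1[2, 3] <- NA_integer_
  ds1 <- tiny_dataset(g1, pops = rep("p", 10))
  expect_equal(impute_missing(ds1)$geno[2, 3], 2L)
  # frequency 0.5 -> imputed dosage mean ~ 1 over many imputations
  set.seed(5)
  n <- 200
  g2 <- matrix(rep(c(0L, 2L), n / 2), 100, n, byrow = TRUE)  # freq 0.5
  na_mask <- matrix(runif(100 * n) < 0.5, 100, n)
  g2[na_mask] <- NA_integer_
  ds2 <- tiny_dataset(g2, pos = (1:100) * 10, pops = rep("p", n))
  imp <- impute_missing(ds2, seed = 6)
  expect_lt(abs(mean(imp$geno[na_mask]) - 1), 0.05)
  expect_identical(imp$geno[!na_mask], g2[!na_mask])
  # a site with one population entirely missing is an error naming the site
  g3 <- matrix(1L, 2, 6); g3[, 1] <- 0L
  g3[2, 1:3] <- NA_integer_
  ds3 <- tiny_dataset(g3, pos = c(10, 20),
                      pops = rep(c("pa", "pb"), each = 3))
  expect_error(impute_missing(ds3), "chr1:20.*pa")
})
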