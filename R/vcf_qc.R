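#' Site-level quality-control thresholds
#'
#' Defaults follow common GBS practice for this kind of two-population scan:
#' per-site depth >= 4, RMS mapping quality >= 20, adjacent-SNP distance >= 5
#' bp, per-population missing ratio < 50% (tightened to < 20% for the
#' selection-scan input), pooled MAF >= 0.01 and, for the GWAS set only, a
#' Hardy-Weinberg exact-test floor of 1e-6.
#'
#' @param min_depth minimum per-site coverage depth (sites lacking depth
#'   information pass this criterion).
#' @param min_mapq minimum per-site RMS mapping quality (same rule).
#' @param min_adjacent_bp minimum distance to the previous retained SNP.
#' @param max_missing maximum per-population missing ratio (exclusive).
#' @param min_maf minimum pooled minor allele frequency.
#' @param hwe_p_floor Hardy-Weinberg exact p-value floor (applied only when
#'   the HWE flag is set in \code{\link{filter_sites}}).
#' @return list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(min_depth = 4, min_mapq = 20, min_adjacent_bp = 5,
                          max_missing = 0.5, min_maf = 0.01,
                          hwe_p_floor = 1e-6) {
  check_number(min_depth, "min_depth", 0)
  check_number(min_mapq, "min_mapq", 0)
  check_number(min_adjacent_bp, "min_adjacent_bp", 0)
  check_number(max_missing, "max_missing", 0, 1)
  check_number(min_maf, "min_maf", 0, 0.5)
  check_number(hwe_p_floor, "hwe_p_floor", 0, 1)
  structure(list(min_depth = min_depth, min_mapq = min_mapq,
                 min_adjacent_bp = min_adjacent_bp,
                 max_missing = max_missing, min_maf = min_maf,
                 hwe_p_floor = hwe_p_floor), class = "qc_thresholds")
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Loads a VCF 4.x file, skips multi-allelic and non-SNP records (with a
#' message and a count in \code{attr(, "n_skipped")}), and encodes genotypes
#' as alt-allele dosage; phased and unphased GT are treated identically.
#' Per-site DP and MQ are taken from INFO when present.
#'
#' @param path VCF file path.
#' @param population_map data.frame with columns \code{sample} and
#'   \code{population}, a named character vector, or the path of a
#'   tab-separated two-column file. Every mapped sample must be in the VCF;
#'   VCF samples absent from the map are dropped.
#' @return A \code{\link{genotype_dataset}}.
#' @export
read_vcf <- function(path, population_map) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  if (is.character(population_map) && length(population_map) == 1 &&
      file.exists(population_map))
    population_map <- read.table(population_map, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  if (is.character(population_map))
    population_map <- data.frame(sample = names(population_map),
                                 population = unname(population_map),
                                 stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(population_map)))
    stopf("population_map needs columns 'sample' and 'population'")
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stopf("malformed VCF '%s': %s", path,
                                          conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT != "."
  n_skip <- sum(!is_snp)
  if (n_skip)
    message(sprintf("read_vcf: skipped %d multi-allelic/non-SNP record(s)",
                    n_skip))
  gt_raw <- v@gt[is_snp, -1, drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  vcf_samples <- colnames(gt_raw)
  missing_samples <- setdiff(population_map$sample, vcf_samples)
  if (length(missing_samples))
    stopf("sample(s) in population map absent from VCF: %s",
          paste(missing_samples, collapse = ", "))
  gt_raw <- gt_raw[, population_map$sample, drop = FALSE]
  gt <- sub(":.*", "", gt_raw)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  geno <- matrix(code[gt], nrow = nrow(gt))  # unmatched -> NA
  info_field <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]+"),
                                      fix$INFO))
    out <- rep(NA_real_, nrow(fix))
    hit <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    out[hit] <- as.numeric(sub(paste0(".*", key, "="), "", m))
    out
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      depth = info_field("DP"), mapq = info_field("MQ"),
                      stringsAsFactors = FALSE)
  ds <- genotype_dataset(population_map[, c("sample", "population")], sites,
                         geno)
  attr(ds, "n_skipped") <- n_skip
  ds
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test from genotype counts: given the observed
#' allele counts, the p-value is the total probability of all heterozygote
#' counts (of matching parity) whose conditional probability under the HWE
#' null does not exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts (vectorized).
#' @return p-value(s) in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (length(n_AA) > 1L || length(n_Aa) > 1L || length(n_aa) > 1L) {
    return(mapply(hwe_exact_test, n_AA, n_Aa, n_aa))
  }
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stopf("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stopf("at least one observation is required")
  nA <- 2 * n_AA + n_Aa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  # log P(h | n, nA) = log multinomial * 2^h / C(2n, nA)
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (nA + hets) / 2) + hets * log(2) - lchoose(2 * n, nA)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  sum(p[p <= obs * (1 + 1e-9)])
}

#' Apply site-level quality-control filters
#'
#' Filters are applied in a fixed order — depth, mapping quality, adjacency,
#' per-population missingness, pooled MAF, and (when \code{hwe = TRUE})
#' Hardy-Weinberg — and each removed site is attributed to the first
#' criterion it fails. The adjacency rule scans each chromosome left to right
#' and drops any site closer than \code{min_adjacent_bp} to the last retained
#' site. The HWE test is computed within each population and a site fails
#' when any population's exact p falls below the floor.
#'
#' @param dataset a \code{\link{genotype_dataset}}.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @param hwe apply the Hardy-Weinberg filter (GWAS set only).
#' @return The filtered dataset; \code{attr(, "filter_report")} is a
#'   data.frame (criterion, sites_removed) whose counts sum to the number of
#'   sites removed.
#' @export
filter_sites <- function(dataset, thresholds = qc_thresholds(),
                         hwe = FALSE) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(thresholds, "qc_thresholds"))
  m <- nrow(dataset$sites)
  alive <- rep(TRUE, m)
  report <- c(depth = 0L, mapq = 0L, adjacency = 0L, missingness = 0L,
              maf = 0L, hwe = 0L)
  fail_first <- function(bad) {
    bad <- bad & alive
    alive[bad] <<- FALSE
    sum(bad)
  }
  dp <- dataset$sites$depth
  if (!is.null(dp))
    report["depth"] <- fail_first(!is.na(dp) & dp < thresholds$min_depth)
  mq <- dataset$sites$mapq
  if (!is.null(mq))
    report["mapq"] <- fail_first(!is.na(mq) & mq < thresholds$min_mapq)
  # greedy left-to-right adjacency among sites still alive
  adj_bad <- rep(FALSE, m)
  for (ch in unique(dataset$sites$chrom)) {
    idx <- which(alive & dataset$sites$chrom == ch)
    if (length(idx) < 2) next
    last <- dataset$sites$pos[idx[1]]
    for (i in idx[-1]) {
      if (dataset$sites$pos[i] - last < thresholds$min_adjacent_bp)
        adj_bad[i] <- TRUE
      else last <- dataset$sites$pos[i]
    }
  }
  report["adjacency"] <- fail_first(adj_bad)
  pops <- unique(dataset$samples$population)
  miss_bad <- rep(FALSE, m)
  for (p in pops) {
    gp <- dataset$geno[, dataset$samples$population == p, drop = FALSE]
    miss_bad <- miss_bad |
      rowMeans(is.na(gp)) >= thresholds$max_missing
  }
  report["missingness"] <- fail_first(miss_bad)
  maf <- pooled_maf(dataset)
  report["maf"] <- fail_first(is.na(maf) | maf < thresholds$min_maf)
  if (hwe) {
    hwe_bad <- rep(FALSE, m)
    cand <- which(alive)
    for (p in pops) {
      gp <- dataset$geno[cand, dataset$samples$population == p,
                         drop = FALSE]
      nAA <- rowSums(gp == 0L, na.rm = TRUE)
      nAa <- rowSums(gp == 1L, na.rm = TRUE)
      naa <- rowSums(gp == 2L, na.rm = TRUE)
      nz <- nAA + nAa + naa > 0
      pv <- rep(1, length(cand))
      pv[nz] <- hwe_exact_test(nAA[nz], nAa[nz], naa[nz])
      hwe_bad[cand[pv < thresholds$hwe_p_floor]] <- TRUE
    }
    report["hwe"] <- fail_first(hwe_bad)
  }
  out <- subset_sites(dataset, which(alive))
  attr(out, "filter_report") <- data.frame(
    criterion = names(report), sites_removed = as.integer(report),
    stringsAsFactors = FALSE)
  out
}

#' Impute missing genotypes from per-population allele frequencies
#'
#' Each missing genotype is replaced by a draw from Binomial(2, p) where p is
#' the alt-allele frequency among the observed genotypes of the same
#' population at that site. Observed genotypes are never altered; the result
#' is deterministic given \code{seed}. This is a deliberately simple,
#' frequency-based imputer — no haplotype phasing or reference panel is used,
#' which is recorded in the returned metadata.
#'
#' @param dataset a \code{\link{genotype_dataset}}.
#' @param seed integer seed.
#' @return The completed dataset; \code{attr(, "imputation")} records method
#'   and the number of imputed genotypes.
#' @export
impute_missing <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  g <- dataset$geno
  if (!anyNA(g)) {
    attr(dataset, "imputation") <-
      list(method = "population-frequency binomial draw", n_imputed = 0L)
    return(dataset)
  }
  set.seed(seed)
  n_imp <- 0L
  for (p in unique(dataset$samples$population)) {
    cols <- which(dataset$samples$population == p)
    gp <- g[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(gp))
    empty <- which(n_obs == 0L)
    if (length(empty))
      stopf("site %s:%d is entirely missing in population '%s'",
            dataset$sites$chrom[empty[1]], dataset$sites$pos[empty[1]], p)
    freq <- rowSums(gp, na.rm = TRUE) / (2 * n_obs)
    na_idx <- which(is.na(gp))
    if (length(na_idx)) {
      site_of <- ((na_idx - 1L) %% nrow(gp)) + 1L
      gp[na_idx] <- rbinom(length(na_idx), 2L, freq[site_of])
      g[, cols] <- gp
      n_imp <- n_imp + length(na_idx)
    }
  }
  dataset$geno <- g
  attr(dataset, "imputation") <-
    list(method = "population-frequency binomial draw", n_imputed = n_imp)
  dataset
}
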