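#' Simulation configuration for the two-population study design
#'
#' Bundles the parameters of the synthetic study: two diploid populations with
#' Balding-Nichols differentiation, an optional hard sweep distorting the
#' focal population's site-frequency spectrum around a chosen locus, GBS-like
#' uniform missingness, and a quantitative trait with a batch fixed effect,
#' sparse causal SNPs and a polygenic background.
#'
#' @param n_pop1,n_pop2 diploid sample counts for the focal and reference
#'   population.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @param n_sites segregating sites simulated per chromosome (the dense
#'   variant panel used by the scan branch).
#' @param gwas_site_frac fraction of sites retained as the sparser
#'   genotyping panel for the association branch, emulating study designs
#'   where sweep scans use deeply sequenced data while the association
#'   cohort is genotyped by sequencing at much lower marker density. Planted
#'   causal sites are always retained.
#' @param fst_param Balding-Nichols differentiation parameter F in [0, 1);
#'   0 gives identical population frequencies.
#' @param sweep_alpha sweep intensity (per bp) for the hard sweep planted in
#'   the focal population, or \code{NULL} for no sweep. The per-lineage escape
#'   probability at distance d from the swept site is 1 - exp(-alpha * d).
#' @param sweep_position_bp coordinate of the swept site.
#' @param sweep_chrom chromosome carrying the sweep.
#' @param missing_rate per-genotype missingness probability in [0, 1).
#' @param n_causal number of causal SNPs behind the simulated trait.
#' @param h2_snp,h2_poly fractions of (non-batch) trait variance explained by
#'   the causal SNPs and by the polygenic background; their sum must be < 1.
#' @param n_batches number of batch levels (samples assigned in balanced
#'   rotation).
#' @param batch_effects numeric vector of length \code{n_batches}: additive
#'   batch means on the trait scale.
#' @param anc_freq_range range of the uniform law for ancestral allele
#'   frequencies; the default avoids near-fixed sites for which
#'   differentiation estimators are degenerate.
#' @param pop_names labels for the two populations.
#' @param seed integer random seed; every generator is deterministic given it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_pop1 = 282, n_pop2 = 50, n_chrom = 3,
                       chrom_length_bp = 5e6, n_sites = 4000,
                       gwas_site_frac = 0.3,
                       fst_param = 0.2, sweep_alpha = 1e-5,
                       sweep_position_bp = 2.5e6, sweep_chrom = "chr1",
                       missing_rate = 0.05, n_causal = 3, h2_snp = 0.3,
                       h2_poly = 0.3, n_batches = 3,
                       batch_effects = seq(0, by = 0.5,
                                           length.out = n_batches),
                       anc_freq_range = c(0.05, 0.95),
                       pop_names = c("focal", "reference"), seed = 1L) {
  check_number(n_pop1, "n_pop1", 1)
  check_number(n_pop2, "n_pop2", 1)
  check_number(n_chrom, "n_chrom", 1)
  check_number(chrom_length_bp, "chrom_length_bp", 1)
  check_number(n_sites, "n_sites", 1)
  check_number(gwas_site_frac, "gwas_site_frac", 1e-6, 1)
  check_number(fst_param, "fst_param", 0, 1 - 1e-12)
  if (!is.null(sweep_alpha)) check_number(sweep_alpha, "sweep_alpha", 1e-12)
  check_number(missing_rate, "missing_rate", 0, 1 - 1e-12)
  check_number(n_causal, "n_causal", 0)
  check_number(h2_snp, "h2_snp", 0, 1)
  check_number(h2_poly, "h2_poly", 0, 1)
  if (h2_snp + h2_poly >= 1)
    stopf("h2_snp + h2_poly must be < 1 (got %s)", h2_snp + h2_poly)
  check_number(n_batches, "n_batches", 1)
  if (length(batch_effects) != n_batches)
    stopf("batch_effects must have length n_batches = %d", n_batches)
  if (length(anc_freq_range) != 2 || anc_freq_range[1] <= 0 ||
      anc_freq_range[2] >= 1 || diff(anc_freq_range) <= 0)
    stopf("anc_freq_range must be an increasing pair inside (0, 1)")
  cfg <- list(n_pop1 = as.integer(n_pop1), n_pop2 = as.integer(n_pop2),
              n_chrom = as.integer(n_chrom),
              chrom_length_bp = as.integer(chrom_length_bp),
              n_sites = as.integer(n_sites),
              gwas_site_frac = gwas_site_frac, fst_param = fst_param,
              sweep_alpha = sweep_alpha,
              sweep_position_bp = sweep_position_bp,
              sweep_chrom = sweep_chrom, missing_rate = missing_rate,
              n_causal = as.integer(n_causal), h2_snp = h2_snp,
              h2_poly = h2_poly, n_batches = as.integer(n_batches),
              batch_effects = batch_effects, anc_freq_range = anc_freq_range,
              pop_names = pop_names, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d + %d diploids, %d chrom x %s bp, ",
                     "%d sites/chrom, F = %s\n"),
              x$n_pop1, x$n_pop2, x$n_chrom,
              format(x$chrom_length_bp, big.mark = ","), x$n_sites,
              x$fst_param))
  if (!is.null(x$sweep_alpha))
    cat(sprintf("  sweep: alpha = %g at %s:%s\n", x$sweep_alpha,
                x$sweep_chrom, format(x$sweep_position_bp, big.mark = ",")))
  cat(sprintf("  trait: %d causal SNPs, h2_snp = %s, h2_poly = %s, %d batches\n",
              x$n_causal, x$h2_snp, x$h2_poly, x$n_batches))
  invisible(x)
}

#' Simulate two divergent populations under the Balding-Nichols model
#'
#' For each site an ancestral frequency p is drawn uniformly on
#' \code{anc_freq_range}; each population's frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), whose mean is p and whose expected
#' Weir-Cockerham differentiation is F. With F = 0 both populations use p
#' exactly. Genotypes are Binomial(2, population frequency); missingness is
#' applied uniformly at \code{missing_rate}. No sweep is planted here (see
#' \code{\link{simulate_sweep_sites}} and \code{\link{simulate_study}}).
#'
#' @param config a \code{\link{sim_config}}.
#' @return A \code{\link{genotype_dataset}}.
#' @export
simulate_divergent_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genotypes"))
  F <- config$fst_param
  n1 <- config$n_pop1; n2 <- config$n_pop2
  chroms <- paste0("chr", seq_len(config$n_chrom))
  sites_list <- vector("list", length(chroms))
  geno_list <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    m <- config$n_sites
    pos <- sort(sample.int(config$chrom_length_bp, m))
    p_anc <- runif(m, config$anc_freq_range[1], config$anc_freq_range[2])
    if (F > 0) {
      a <- p_anc * (1 - F) / F
      b <- (1 - p_anc) * (1 - F) / F
      p1 <- rbeta(m, a, b)
      p2 <- rbeta(m, a, b)
    } else {
      p1 <- p_anc
      p2 <- p_anc
    }
    g1 <- matrix(rbinom(m * n1, 2L, p1), nrow = m)
    g2 <- matrix(rbinom(m * n2, 2L, p2), nrow = m)
    g <- cbind(g1, g2)
    sites_list[[ci]] <- data.frame(chrom = chroms[ci], pos = pos,
                                   ref = "A", alt = "C",
                                   stringsAsFactors = FALSE)
    geno_list[[ci]] <- g
  }
  geno <- do.call(rbind, geno_list)
  if (config$missing_rate > 0) {
    drop <- runif(length(geno)) < config$missing_rate
    geno[drop] <- NA_integer_
  }
  samples <- data.frame(
    sample = c(sprintf("%s_%03d", config$pop_names[1], seq_len(n1)),
               sprintf("%s_%03d", config$pop_names[2], seq_len(n2))),
    population = rep(config$pop_names, c(n1, n2)),
    stringsAsFactors = FALSE)
  genotype_dataset(samples, do.call(rbind, sites_list), geno)
}

#' Draw derived-allele counts at sites flanking a hard sweep
#'
#' Each site's derived count is drawn from the sweep-distorted allele-count
#' distribution \code{\link{sweep_site_distribution}} at its physical distance
#' from the swept site, conditioned on polymorphism. The generative law is
#' exactly the model the composite-likelihood scan fits, so position recovery
#' by \code{\link{clr_genome_scan}} is a well-posed closed loop.
#'
#' @param sfs background \code{\link{site_sfs}} (normalized over polymorphic
#'   classes).
#' @param n haploid sample size.
#' @param alpha sweep intensity per bp (> 0).
#' @param sweep_position_bp coordinate of the swept site.
#' @param site_positions positions of the sites to draw; none may coincide
#'   with \code{sweep_position_bp} (the model gives such a site zero
#'   polymorphism probability).
#' @param seed integer seed.
#' @return data.frame with columns \code{position} and \code{count}.
#' @export
simulate_sweep_sites <- function(sfs, n, alpha, sweep_position_bp,
                                 site_positions, seed = 1L) {
  stopifnot(inherits(sfs, "site_sfs"))
  check_number(alpha, "alpha", 1e-300)
  if (!length(site_positions))
    return(data.frame(position = numeric(0), count = integer(0)))
  d <- abs(site_positions - sweep_position_bp)
  if (any(d == 0))
    stopf("site at distance 0 from the sweep has polymorphism probability 0")
  set.seed(seed)
  # Composition sampling of the sweep mixture, conditioned on polymorphism
  # by rejection: draw the escape count e ~ Binomial(n, p_escape), a
  # background class J from the spectrum, the ancestral-sample count j by
  # hypergeometric subsampling to e+1 lineages, then resolve the sweep
  # ancestor's allele. Identical in law to sweep_site_distribution but O(1)
  # per site, which matters at large n.
  p_esc <- -expm1(-alpha * d)
  counts <- rep(NA_integer_, length(d))
  pending <- seq_along(d)
  classes <- seq_len(n - 1L)
  for (iter in 1:10000) {
    m <- length(pending)
    if (m == 0L) break
    e <- rbinom(m, n, p_esc[pending])
    J <- sample(classes, m, replace = TRUE, prob = sfs$probs)
    b <- integer(m)
    esc_all <- e == n
    b[esc_all] <- J[esc_all]                 # no sweep-ancestor lineage
    if (any(!esc_all)) {
      ei <- e[!esc_all]; Ji <- J[!esc_all]
      k <- ei + 1L
      j <- rhyper(length(ei), Ji, n - Ji, k)
      anc <- runif(length(ei)) < j / k
      b[!esc_all] <- ifelse(anc, j - 1L + (n - ei), j)
    }
    ok <- b >= 1L & b <= n - 1L
    counts[pending[ok]] <- b[ok]
    pending <- pending[!ok]
  }
  if (length(pending))
    stopf("sweep sampler failed to accept at site distance %g", d[pending[1]])
  data.frame(position = site_positions, count = counts)
}

#' Simulate phenotypes from genotypes under the GWAS model
#'
#' Generates, for the focal population, y = mu + batch effect + sum of causal
#' dosage effects + polygenic term + iid noise. The polygenic term is
#' multivariate normal with covariance proportional to the realized
#' standardized GRM, matching the mixed-model assumption of the association
#' scan. The causal and polygenic components are rescaled to their target
#' variance fractions \code{h2_snp} and \code{h2_poly} of the non-batch trait
#' variance (batch means are added on top).
#'
#' @param genotypes a \code{\link{genotype_dataset}}; missing genotypes are
#'   mean-imputed internally for the generative model only.
#' @param config a \code{\link{sim_config}}.
#' @param causal_sites optional integer site indices to use as causal SNPs
#'   (defaults to a random draw among focal-population sites with MAF >=
#'   0.05).
#' @return list with \code{phenotypes} (data.frame sample/trait/batch) and
#'   \code{causal} (data.frame site/chrom/pos/effect).
#' @export
simulate_phenotypes <- function(genotypes, config, causal_sites = NULL) {
  stopifnot(inherits(genotypes, "genotype_dataset"),
            inherits(config, "sim_config"))
  if (config$h2_snp + config$h2_poly >= 1)
    stopf("h2_snp + h2_poly must be < 1")
  set.seed(derive_seed(config$seed, "phenotypes"))
  focal <- subset_samples(genotypes, pop_index(genotypes,
                                               config$pop_names[1]))
  n <- nrow(focal$samples)
  X <- t(focal$geno)                       # samples x sites
  site_mean <- colMeans(X, na.rm = TRUE)
  na_idx <- which(is.na(X))
  if (length(na_idx))
    X[na_idx] <- site_mean[((na_idx - 1L) %/% n) + 1L]
  batch <- rep_len(seq_len(config$n_batches), n)[sample.int(n)]
  y <- 10 + config$batch_effects[batch]
  causal <- data.frame(site = integer(0), chrom = character(0),
                       pos = numeric(0), effect = numeric(0))
  n_causal <- if (config$h2_snp > 0) config$n_causal else 0L
  if (n_causal > 0) {
    p <- site_mean / 2
    eligible <- which(pmin(p, 1 - p) >= 0.05)
    if (is.null(causal_sites)) {
      if (length(eligible) < n_causal)
        stopf("only %d sites are eligible as causal (need %d)",
              length(eligible), n_causal)
      causal_sites <- sort(sample(eligible, n_causal))
    }
    eff <- rnorm(length(causal_sites))
    g_causal <- drop(X[, causal_sites, drop = FALSE] %*% eff)
    s <- sd(g_causal)
    if (s == 0) stopf("causal sites are monomorphic in the focal population")
    scale_c <- sqrt(config$h2_snp) / s
    g_causal <- g_causal * scale_c
    y <- y + g_causal
    causal <- data.frame(site = causal_sites,
                         chrom = focal$sites$chrom[causal_sites],
                         pos = focal$sites$pos[causal_sites],
                         effect = eff * scale_c)
  }
  if (config$h2_poly > 0) {
    G <- standardized_grm(focal)
    L <- chol(G + diag(1e-6, n))
    g_poly <- drop(crossprod(L, rnorm(n)))
    g_poly <- g_poly * sqrt(config$h2_poly) / sd(g_poly)
    y <- y + g_poly
  }
  h2_e <- 1 - config$h2_snp - config$h2_poly
  e <- rnorm(n)
  y <- y + e * sqrt(h2_e) / sd(e)
  list(phenotypes = data.frame(sample = focal$samples$sample, trait = y,
                               batch = factor(batch),
                               stringsAsFactors = FALSE),
       causal = causal)
}

#' Simulate the full study: divergence, sweep, missingness, phenotypes
#'
#' Composes \code{\link{simulate_divergent_genotypes}},
#' \code{\link{simulate_sweep_sites}} (re-drawing focal-population genotypes
#' near the swept site from the sweep model) and
#' \code{\link{simulate_phenotypes}}. The background spectrum handed to the
#' sweep generator is the focal population's realized spectrum away from the
#' sweep. When a sweep and causal SNPs are both requested, the first causal
#' SNP is planted within 100 kb of the swept site so that joint recovery of a
#' selection region and an association hit is a defined event.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{dataset} (genotype_dataset), \code{phenotypes},
#'   \code{causal}, and \code{truth} (sweep chromosome/position or NULL).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  miss_cfg <- config
  miss_cfg$missing_rate <- 0            # apply missingness after the sweep
  dataset <- simulate_divergent_genotypes(miss_cfg)
  truth <- NULL
  if (!is.null(config$sweep_alpha)) {
    n1 <- config$n_pop1
    n_hap <- 2L * n1
    focal_idx <- seq_len(n1)
    on_chrom <- dataset$sites$chrom == config$sweep_chrom
    counts_bg <- rowSums(dataset$geno[!on_chrom, focal_idx, drop = FALSE])
    sfs_bg <- background_sfs(counts_bg, n = n_hap)
    sweep_idx <- which(on_chrom &
                       abs(dataset$sites$pos - config$sweep_position_bp) > 0)
    swept <- simulate_sweep_sites(sfs_bg, n_hap, config$sweep_alpha,
                                  config$sweep_position_bp,
                                  dataset$sites$pos[sweep_idx],
                                  seed = derive_seed(config$seed, "sweep"))
    set.seed(derive_seed(config$seed, "sweep-assign"))
    for (k in seq_along(sweep_idx)) {
      hap <- integer(n_hap)
      hap[sample.int(n_hap, swept$count[k])] <- 1L
      dataset$geno[sweep_idx[k], focal_idx] <-
        hap[seq(1, n_hap, by = 2)] + hap[seq(2, n_hap, by = 2)]
    }
    truth <- list(chrom = config$sweep_chrom,
                  position = config$sweep_position_bp)
  }
  ph <- NULL
  causal_sites <- NULL
  if (!is.null(truth) && config$n_causal > 0 && config$h2_snp > 0) {
    set.seed(derive_seed(config$seed, "causal-pick"))
    focal_idx <- seq_len(config$n_pop1)
    p <- rowMeans(dataset$geno[, focal_idx, drop = FALSE]) / 2
    ok <- pmin(p, 1 - p) >= 0.05
    near <- which(ok & dataset$sites$chrom == config$sweep_chrom &
                  abs(dataset$sites$pos - config$sweep_position_bp) <= 1e5)
    far <- which(ok)
    if (!length(near))
      stopf("no polymorphic site within 100 kb of the sweep to plant a causal SNP")
    first <- near[which.min(abs(dataset$sites$pos[near] -
                                config$sweep_position_bp))]
    rest <- setdiff(far, first)
    extra <- if (config$n_causal > 1)
      sort(sample(rest, config$n_causal - 1L)) else integer(0)
    causal_sites <- sort(c(first, extra))
  }
  ph <- simulate_phenotypes(dataset, config, causal_sites = causal_sites)
  if (config$missing_rate > 0) {
    set.seed(derive_seed(config$seed, "missing"))
    drop <- runif(length(dataset$geno)) < config$missing_rate
    dataset$geno[drop] <- NA_integer_
  }
  list(dataset = dataset, phenotypes = ph$phenotypes, causal = ph$causal,
       truth = truth)
}

#' Write a simulated dataset to VCF, phenotype, population-map and BED files
#'
#' Emits a VCF 4.2 file (GT-only, missing genotypes as "./."), a tab-separated
#' phenotype table (\code{sample<TAB>trait<TAB>batch}), a tab-separated
#' population map, and a BED6 file of simulated gene models tiled along each
#' chromosome. The VCF round-trips losslessly through \code{\link{read_vcf}}.
#'
#' @param dataset a \code{\link{genotype_dataset}}.
#' @param phenotypes optional phenotype data.frame (sample, trait, batch).
#' @param out_prefix path prefix for the output files.
#' @param chrom_length_bp chromosome length used for the contig headers and
#'   the simulated gene tiling (default: max position per chromosome).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_dataset <- function(dataset, phenotypes = NULL, out_prefix,
                          chrom_length_bp = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (nrow(dataset$sites) == 0) stopf("dataset has no sites")
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  chroms <- unique(dataset$sites$chrom)
  lens <- vapply(chroms, function(ch)
    max(dataset$sites$pos[dataset$sites$chrom == ch]), numeric(1))
  if (!is.null(chrom_length_bp)) lens[] <- chrom_length_bp

  vcf_path <- paste0(out_prefix, ".vcf")
  con <- file(vcf_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("##fileformat=VCFv4.2",
               "##source=artisel_simulate",
               sprintf("##contig=<ID=%s,length=%d>", chroms,
                       as.integer(lens)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", dataset$samples$sample),
                   collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(dataset$geno), ncol(dataset$geno))
  obs <- !is.na(dataset$geno)
  gt[obs] <- gt_code[dataset$geno[obs] + 1L]
  body <- paste(dataset$sites$chrom, dataset$sites$pos, ".",
                dataset$sites$ref, dataset$sites$alt, ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)

  popmap_path <- paste0(out_prefix, ".popmap.tsv")
  write.table(dataset$samples, popmap_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  paths <- c(vcf = vcf_path, popmap = popmap_path)
  if (!is.null(phenotypes)) {
    ph_path <- paste0(out_prefix, ".pheno.tsv")
    write.table(phenotypes, ph_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, pheno = ph_path)
  }

  # simulated gene models: 20-kb genes every 150 kb, BED6 (0-based half-open)
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- seq(50000, max(lens[ch] - 20000, 50000), by = 150000)
    data.frame(chrom = ch, start = starts, end = starts + 20000,
               name = sprintf("gene_%s_%03d", ch, seq_along(starts)),
               score = 0L, strand = "+", stringsAsFactors = FALSE)
  }))
  bed_path <- paste0(out_prefix, ".genes.bed")
  write.table(genes, bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(paths, genes = bed_path))
}
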