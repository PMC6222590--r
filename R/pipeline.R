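#' Pipeline run configuration
#'
#' Collects every knob of the two-branch pipeline: either a
#' \code{\link{sim_config}} (synthetic input) or file paths (VCF, population
#' map, phenotypes, gene models), the QC thresholds, the scan settings and
#' the GWAS settings. Defaults follow the study design: 25-kb scan grid and
#' F_ST windows, 98th-percentile empirical significance, 200-kb region
#' merging, 100-kb gene flank, SimpleM at 99% variance.
#'
#' @param sim a \code{\link{sim_config}}, or NULL when files are given.
#' @param vcf,popmap,pheno,genes input file paths (ignored when \code{sim}
#'   is given).
#' @param qc a \code{\link{qc_thresholds}}.
#' @param scan_max_missing per-population missingness cap for the scan input.
#' @param scan_panel diploid panel size per population for the scan branch:
#'   each population is subsampled to at most this many individuals before
#'   the CLR and F_ST scans, mirroring study designs in which sweep detection
#'   uses a small deeply-sequenced panel while the association cohort is much
#'   larger. Set Inf to scan everyone.
#' @param grid_bp,window_bp,quantile,gap_bp,flank_bp scan/region settings.
#' @param casr_mode "either" or "both" F_ST tracks must overlap a CLR region.
#' @param var_fraction,alpha,hit_dist_bp GWAS settings.
#' @param seed integer seed governing every stochastic stage.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(sim = NULL, vcf = NULL, popmap = NULL, pheno = NULL,
                       genes = NULL, qc = qc_thresholds(),
                       scan_max_missing = 0.2, scan_panel = 50,
                       grid_bp = 25000,
                       window_bp = 25000, quantile = 0.98, gap_bp = 200000,
                       flank_bp = 100000, casr_mode = "either",
                       var_fraction = 0.99, alpha = 0.05, hit_dist_bp = 1e6,
                       seed = 1L) {
  if (is.null(sim) && is.null(vcf))
    stopf("either 'sim' or 'vcf' (+ popmap) must be given")
  if (!is.null(sim) && !is.null(vcf))
    stopf("give either 'sim' or input files, not both")
  if (is.null(sim)) {
    for (f in c(vcf, popmap, pheno, genes))
      if (!is.null(f) && !file.exists(f)) stopf("input file not found: %s", f)
  }
  structure(list(sim = sim, vcf = vcf, popmap = popmap, pheno = pheno,
                 genes = genes, qc = qc, scan_max_missing = scan_max_missing,
                 scan_panel = scan_panel, grid_bp = grid_bp, window_bp = window_bp,
                 quantile = quantile, gap_bp = gap_bp, flank_bp = flank_bp,
                 casr_mode = casr_mode, var_fraction = var_fraction,
                 alpha = alpha, hit_dist_bp = hit_dist_bp,
                 seed = as.integer(seed)), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of \code{\link{run_config}}; a
#' \code{sim:} block is passed to \code{\link{sim_config}} and a \code{qc:}
#' block to \code{\link{qc_thresholds}}.
#'
#' @param path YAML file.
#' @return A \code{run_config}.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$qc)) raw$qc <- do.call(qc_thresholds, raw$qc)
  do.call(run_config, raw)
}

acquire_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    study <- simulate_study(sim)
    list(dataset = study$dataset, phenotypes = study$phenotypes,
         genes = NULL, truth = study$truth, causal = study$causal)
  } else {
    dataset <- read_vcf(config$vcf, config$popmap)
    pheno <- if (!is.null(config$pheno))
      read.table(config$pheno, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE) else NULL
    list(dataset = dataset, phenotypes = pheno, genes = config$genes,
         truth = NULL, causal = NULL)
  }
}

write_manifest <- function(path, config, stage, extra = list()) {
  cfg <- unclass(config)
  cfg$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim) else NULL
  cfg$qc <- unclass(cfg$qc)
  manifest <- c(list(
    stage = stage,
    package_version = as.character(utils::packageVersion("artisel")),
    seed = config$seed,
    decisions = list(
      imputation = "population-frequency binomial draw (no phasing)",
      fst = "mean of per-site Weir-Cockerham theta per window; negatives retained",
      percentile_rule = "strictly above the ceiling(q*N)-th order statistic",
      polarization = "alt allele treated as derived (unfolded spectrum)"),
    config = cfg), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
}

write_track <- function(track, path) {
  write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Run the selection-signature scan branch
#'
#' QC (with the tighter scan missingness cap), imputation, genome-wide
#' background spectrum, CLR scan, per-reference-population F_ST window
#' tracks, empirical p-values, 98th-percentile selection, 200-kb merging
#' into candidate selection regions (CSR) and CLR-by-F_ST intersection into
#' candidate artificial-selection regions (CASR). All tracks, regions and a
#' JSON run manifest are written under \code{out_dir}.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, list(clr_track, fst_tracks, clr_csr, fst_csr, casr,
#'   dataset, truth).
#' @export
run_scan <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- acquire_inputs(config)
  dataset <- inputs$dataset
  pops <- unique(dataset$samples$population)
  if (length(pops) < 2)
    stopf("scan stage: need a focal and at least one reference population")
  qc <- config$qc
  qc$max_missing <- config$scan_max_missing
  ds <- tryCatch(filter_sites(dataset, qc, hwe = FALSE),
                 error = function(e) stopf("qc stage: %s",
                                           conditionMessage(e)))
  ds <- tryCatch(impute_missing(ds, seed = derive_seed(config$seed,
                                                       "impute-scan")),
                 error = function(e) stopf("imputation stage: %s",
                                           conditionMessage(e)))
  focal <- pops[1]
  if (is.finite(config$scan_panel)) {
    set.seed(derive_seed(config$seed, "scan-panel"))
    keep <- unlist(lapply(pops, function(p) {
      idx <- which(ds$samples$population == p)
      if (length(idx) > config$scan_panel)
        sort(sample(idx, config$scan_panel)) else idx
    }))
    ds <- subset_samples(ds, keep)
  }
  clr_track <- tryCatch(
    empirical_pvalues(clr_genome_scan(ds, grid_bp = config$grid_bp,
                                      population = focal)),
    error = function(e) stopf("clr stage: %s", conditionMessage(e)))
  fst_tracks <- lapply(pops[-1], function(ref) {
    st <- fst_site_table(ds, pop1 = focal, pop2 = ref)
    empirical_pvalues(fst_window_average(st, window_bp = config$window_bp))
  })
  names(fst_tracks) <- pops[-1]
  clr_sel <- significant_windows(clr_track, config$quantile)
  clr_csr <- merge_windows(clr_sel, config$gap_bp, source = "CLR_CSR")
  fst_csr <- lapply(names(fst_tracks), function(ref) {
    sel <- significant_windows(fst_tracks[[ref]], config$quantile)
    merge_windows(sel, config$gap_bp, source = paste0("FST_CSR_", ref))
  })
  names(fst_csr) <- names(fst_tracks)
  casr <- intersect_regions(clr_csr, fst_csr[[1]],
                            if (length(fst_csr) > 1) fst_csr[[2]] else NULL,
                            mode = config$casr_mode)
  write_track(clr_track, file.path(out_dir, "clr_track.tsv"))
  for (ref in names(fst_tracks))
    write_track(fst_tracks[[ref]],
                file.path(out_dir, sprintf("fst_track_%s.tsv", ref)))
  write.table(clr_csr, file.path(out_dir, "csr_clr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (ref in names(fst_csr))
    write.table(fst_csr[[ref]],
                file.path(out_dir, sprintf("csr_fst_%s.tsv", ref)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(casr, file.path(out_dir, "casr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_regions_bed(casr, file.path(out_dir, "casr.bed"))
  write_manifest(file.path(out_dir, "scan_manifest.json"), config, "scan",
                 list(n_sites_post_qc = nrow(ds$sites),
                      filter_report = attr(ds, "filter_report")))
  invisible(list(clr_track = clr_track, fst_tracks = fst_tracks,
                 clr_csr = clr_csr, fst_csr = fst_csr, casr = casr,
                 dataset = ds, truth = inputs$truth))
}

#' Run the association branch
#'
#' QC with the Hardy-Weinberg filter, imputation, the leave-one-chromosome-
#' out mixed-model scan, the SimpleM threshold, and — when candidate
#' artificial-selection regions are supplied — the overlap report joining
#' genome-wide-significant SNPs to their nearest region.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory.
#' @param regions optional CASR data.frame (e.g. \code{run_scan()$casr}) or
#'   the path of a casr.tsv written by \code{\link{run_scan}}.
#' @return Invisibly, list(assoc, overlap, causal).
#' @export
run_gwas <- function(config, out_dir, regions = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- acquire_inputs(config)
  phenotypes <- inputs$phenotypes
  if (is.null(phenotypes) || !nrow(phenotypes))
    stopf("gwas stage: phenotype table is missing or empty")
  dataset <- inputs$dataset
  missing_ids <- setdiff(phenotypes$sample, dataset$samples$sample)
  if (length(missing_ids))
    stopf("gwas stage: phenotyped sample(s) missing from genotypes: %s",
          paste(missing_ids, collapse = ", "))
  if (!is.null(config$sim) && config$sim$gwas_site_frac < 1) {
    # the association branch types a sparser marker panel than the scan
    set.seed(derive_seed(config$seed, "gbs-panel"))
    m <- nrow(dataset$sites)
    keep <- sort(sample.int(m, max(2L, round(config$sim$gwas_site_frac * m))))
    if (!is.null(inputs$causal) && nrow(inputs$causal))
      keep <- sort(union(keep, inputs$causal$site))
    dataset <- subset_sites(dataset, keep)
  }
  ds <- filter_sites(dataset, config$qc, hwe = TRUE)
  ds <- impute_missing(ds, seed = derive_seed(config$seed, "impute-gwas"))
  assoc <- loco_scan(ds, phenotypes, var_fraction = config$var_fraction,
                     alpha = config$alpha)
  if (is.character(regions))
    regions <- read.table(regions, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  overlap <- NULL
  if (!is.null(regions)) {
    gene_models <- inputs$genes
    if (is.null(gene_models))
      gene_models <- data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), name = character(0),
                                stringsAsFactors = FALSE)
    ann <- annotate_regions(regions, gene_models, assoc,
                            flank_bp = config$flank_bp,
                            hit_dist_bp = config$hit_dist_bp)
    overlap <- ann$hits
    write.table(ann$regions, file.path(out_dir, "casr_annotated.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(overlap, file.path(out_dir, "overlap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(assoc$snps, file.path(out_dir, "assoc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pd <- assoc_plot_data(assoc)
  write.table(pd$manhattan, file.path(out_dir, "manhattan.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(pd$qq, file.path(out_dir, "qq.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(file.path(out_dir, "gwas_manifest.json"), config, "gwas",
                 list(m_eff = assoc$m_eff, threshold = assoc$threshold,
                      lambda_gc = assoc$lambda_gc))
  invisible(list(assoc = assoc, overlap = overlap, causal = inputs$causal))
}
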