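# Small programmatic fixtures shared across test files.

make_track <- function(scores, chrom = "chr1", window_bp = 25000) {
  k <- seq_along(scores) - 1
  artisel:::new_window_track(chrom, k * window_bp, (k + 1) * window_bp,
                             scores, "TEST")
}

# A tiny hand-wired dataset: two populations, one chromosome.
tiny_dataset <- function(geno, pos = NULL, pops = NULL) {
  m <- nrow(geno); n <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 100
  if (is.null(pops)) pops <- rep(c("p1", "p2"), length.out = n)
  genotype_dataset(
    samples = data.frame(sample = sprintf("s%02d", seq_len(n)),
                         population = pops),
    sites = data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "C"),
    geno = geno)
}

quick_sim <- function(..., seed = 1) {
  sim_config(n_pop1 = 40, n_pop2 = 30, n_chrom = 2, chrom_length_bp = 2e6,
             n_sites = 400, missing_rate = 0.05, sweep_alpha = NULL,
             n_causal = 0, h2_snp = 0, h2_poly = 0.2, seed = seed, ...)
}
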