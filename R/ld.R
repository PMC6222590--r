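#' Squared dosage correlation between two SNPs
#'
#' r-squared computed as the squared Pearson correlation of genotype dosages
#' over the samples non-missing at both sites (genotypes are unphased, so no
#' haplotype-frequency EM is attempted). Undefined — returned as NA — when
#' fewer than 2 complete pairs remain or either site is monomorphic among
#' them.
#'
#' @param g1,g2 dosage vectors of equal length.
#' @return r-squared in [0, 1], or NA when undefined.
#' @export
pair_r2 <- function(g1, g2) {
  if (length(g1) != length(g2) || length(g1) < 2)
    stopf("dosage vectors must have equal length >= 2")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Linkage-disequilibrium decay curve
#'
#' Scores every intra-chromosome SNP pair with distance <= \code{max_dist_bp}
#' and averages the defined r-squared values in half-open
#' [k*bin_bp, (k+1)*bin_bp) distance bins. Missing genotypes are handled by
#' pairwise-complete deletion; monomorphic pairs are excluded from the
#' averages.
#'
#' @param dataset a \code{\link{genotype_dataset}} (QC-passed).
#' @param max_dist_bp maximum pair distance considered.
#' @param bin_bp bin width (default 1000 bp).
#' @param population restrict to one population's samples.
#' @return data.frame(bin_start, bin_end, mean_r2, n_pairs); empty bins have
#'   n_pairs = 0 and mean_r2 = NA.
#' @export
ld_decay_curve <- function(dataset, max_dist_bp, bin_bp = 1000,
                           population = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (max_dist_bp < bin_bp) stopf("max_dist_bp must be >= bin_bp")
  g <- dataset$geno
  if (!is.null(population))
    g <- g[, pop_index(dataset, population), drop = FALSE]
  # a pair at exactly max_dist_bp falls in the half-open bin starting there
  n_bins <- as.integer(max_dist_bp %/% bin_bp) +
    as.integer(max_dist_bp %% bin_bp == 0)
  if (max_dist_bp %% bin_bp != 0) n_bins <- ceiling(max_dist_bp / bin_bp)
  sum_r2 <- numeric(n_bins)
  n_pairs <- integer(n_bins)
  for (ch in unique(dataset$sites$chrom)) {
    idx <- which(dataset$sites$chrom == ch)
    pos <- dataset$sites$pos[idx]
    gm <- t(g[idx, , drop = FALSE])        # samples x sites
    for (i in seq_along(idx)) {
      hi <- findInterval(pos[i] + max_dist_bp, pos)
      if (hi <= i) next
      js <- (i + 1L):hi
      r2 <- suppressWarnings(
        cor(gm[, i], gm[, js, drop = FALSE],
            use = "pairwise.complete.obs"))^2
      r2 <- as.numeric(r2)
      dist <- pos[js] - pos[i]
      bin <- dist %/% bin_bp + 1L
      ok <- !is.na(r2)
      if (any(ok)) {
        tb <- tapply(r2[ok], bin[ok], sum)
        b <- as.integer(names(tb))
        sum_r2[b] <- sum_r2[b] + as.numeric(tb)
        cnt <- table(bin[ok])
        n_pairs[b] <- n_pairs[b] + as.integer(cnt)
      }
    }
  }
  data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_bp,
             bin_end = seq_len(n_bins) * bin_bp,
             mean_r2 = ifelse(n_pairs > 0, sum_r2 / pmax(n_pairs, 1L),
                              NA_real_),
             n_pairs = n_pairs)
}
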