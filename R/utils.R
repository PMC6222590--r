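#' @importFrom stats rbinom rbeta rnorm runif dbinom dhyper rhyper pchisq
#'   qchisq optimize rchisq var cor sd complete.cases median quantile
#'   setNames model.matrix lm coef resid
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stopf("'%s' must be a single number", name)
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single non-missing number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

# Deterministic sub-seed for a named pipeline stage, keeping results
# reproducible from one user-facing seed while decoupling the stages' streams.
# Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Construct a genotype dataset
#'
#' Container for biallelic SNP genotypes: an ordered site table, an ordered
#' sample table with population labels, and a sites-by-samples dosage matrix
#' coded 0/1/2 (alt-allele count) with \code{NA} for missing genotypes.
#'
#' @param samples data.frame with columns \code{sample} and \code{population}.
#' @param sites data.frame with columns \code{chrom}, \code{pos} (1-based bp),
#'   \code{ref}, \code{alt}, and optionally \code{depth} and \code{mapq}.
#' @param geno integer matrix, \code{nrow(sites)} x \code{nrow(samples)},
#'   values in \{0, 1, 2, NA\}.
#' @return An object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(samples, sites, geno) {
  samples <- as.data.frame(samples)
  sites <- as.data.frame(sites)
  if (!all(c("sample", "population") %in% names(samples)))
    stopf("'samples' needs columns 'sample' and 'population'")
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
    stopf("'sites' needs columns 'chrom', 'pos', 'ref', 'alt'")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(sites) || ncol(geno) != nrow(samples))
    stopf("genotype matrix is %d x %d but there are %d sites and %d samples",
          nrow(geno), ncol(geno), nrow(sites), nrow(samples))
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stopf("genotypes must be 0, 1, 2 or NA")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stopf("positions must be strictly increasing within chromosome '%s'", ch)
  }
  structure(list(samples = samples, sites = sites, geno = geno),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d sites x %d samples\n",
              nrow(x$sites), nrow(x$samples)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$sites$chrom), collapse = ", ")))
  pops <- table(x$samples$population)
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s (n=%d)", names(pops), as.integer(pops)),
                    collapse = ", ")))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_dataset <- function(object, ...) {
  maf <- pooled_maf(object)
  out <- list(n_sites = nrow(object$sites), n_samples = nrow(object$samples),
              missing_rate = mean(is.na(object$geno)),
              maf_quartiles = quantile(maf, c(.25, .5, .75), na.rm = TRUE))
  class(out) <- "summary.genotype_dataset"
  out
}

#' @export
print.summary.genotype_dataset <- function(x, ...) {
  cat(sprintf("%d sites x %d samples, %.2f%% missing; MAF quartiles %s\n",
              x$n_sites, x$n_samples, 100 * x$missing_rate,
              paste(signif(x$maf_quartiles, 3), collapse = "/")))
  invisible(x)
}

subset_sites <- function(dataset, idx) {
  dataset$sites <- dataset$sites[idx, , drop = FALSE]
  rownames(dataset$sites) <- NULL
  dataset$geno <- dataset$geno[idx, , drop = FALSE]
  dataset
}

subset_samples <- function(dataset, idx) {
  dataset$samples <- dataset$samples[idx, , drop = FALSE]
  rownames(dataset$samples) <- NULL
  dataset$geno <- dataset$geno[, idx, drop = FALSE]
  dataset
}

pop_index <- function(dataset, population) {
  idx <- which(dataset$samples$population == population)
  if (!length(idx)) stopf("no samples in population '%s'", population)
  idx
}

# Pooled minor allele frequency per site, over non-missing genotypes.
pooled_maf <- function(dataset) {
  g <- dataset$geno
  n_obs <- rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * n_obs)
  pmin(p, 1 - p)
}

new_window_track <- function(chrom, start, end, score, statistic,
                             extra = NULL) {
  df <- data.frame(chrom = chrom, start = start, end = end, score = score,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  attr(df, "statistic") <- statistic
  class(df) <- c("window_track", "data.frame")
  df
}

#' @export
print.window_track <- function(x, ...) {
  cat(sprintf("window_track (%s): %d windows on %d chromosome(s)\n",
              attr(x, "statistic") %||% "?", nrow(x),
              length(unique(x$chrom))))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more windows\n", nrow(x) - 6L))
  invisible(x)
}
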