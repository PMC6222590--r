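# Weir-Cockerham (1984) two-population variance components. Inputs are
# per-population genotype counts at one biallelic site; theta-hat is returned
# unclamped (negative estimates are informative in window averages).

wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(denom == 0, NA_real_, a / denom)
  list(a = a, b = b, c = cc, theta = theta)
}

#' Weir-Cockerham F_ST at a single site
#'
#' Variance-component estimator of differentiation between two populations
#' from genotype counts (n_AA, n_Aa, n_aa). Returns the among-population (a),
#' among-individual (b) and within-individual (c) components and
#' theta = a/(a+b+c), unclamped; theta is NA (undefined) when a+b+c = 0,
#' i.e. the site is monomorphic in both populations.
#'
#' @param pop1,pop2 integer vectors (n_AA, n_Aa, n_aa), or 3-column matrices
#'   for many sites at once.
#' @return list(a, b, c, theta), vectorized over rows when matrices are
#'   given.
#' @export
wc_fst_site <- function(pop1, pop2) {
  p1m <- if (is.matrix(pop1)) pop1 else matrix(pop1, nrow = 1)
  p2m <- if (is.matrix(pop2)) pop2 else matrix(pop2, nrow = 1)
  if (ncol(p1m) != 3 || ncol(p2m) != 3 || nrow(p1m) != nrow(p2m))
    stopf("genotype counts must be (n_AA, n_Aa, n_aa) per population")
  n1 <- rowSums(p1m); n2 <- rowSums(p2m)
  small <- which(n1 < 2 | n2 < 2)
  if (length(small))
    stopf("site %d has fewer than 2 individuals in one population",
          small[1])
  p1 <- (2 * p1m[, 1] + p1m[, 2]) / (2 * n1)
  h1 <- p1m[, 2] / n1
  p2 <- (2 * p2m[, 1] + p2m[, 2]) / (2 * n2)
  h2 <- p2m[, 2] / n2
  out <- wc_components(n1, p1, h1, n2, p2, h2)
  if (!is.matrix(pop1)) out <- lapply(out, unname)
  out
}

#' Per-site Weir-Cockerham F_ST table for a dataset
#'
#' Builds genotype counts from non-missing genotypes of the two named
#' populations and computes the per-site components. Sites where either
#' population has fewer than 2 non-missing individuals are dropped (count in
#' \code{attr(, "n_dropped")}).
#'
#' @param dataset a \code{\link{genotype_dataset}}.
#' @param pop1,pop2 population labels (defaults: the first two).
#' @return data.frame(chrom, pos, a, b, c, theta); undefined sites carry
#'   theta = NA.
#' @export
fst_site_table <- function(dataset, pop1 = NULL, pop2 = NULL) {
  pops <- unique(dataset$samples$population)
  pop1 <- pop1 %||% pops[1]
  pop2 <- pop2 %||% pops[2]
  g1 <- dataset$geno[, pop_index(dataset, pop1), drop = FALSE]
  g2 <- dataset$geno[, pop_index(dataset, pop2), drop = FALSE]
  cnt <- function(g) cbind(rowSums(g == 0L, na.rm = TRUE),
                           rowSums(g == 1L, na.rm = TRUE),
                           rowSums(g == 2L, na.rm = TRUE))
  c1 <- cnt(g1); c2 <- cnt(g2)
  ok <- rowSums(c1) >= 2 & rowSums(c2) >= 2
  comp <- wc_fst_site(c1[ok, , drop = FALSE], c2[ok, , drop = FALSE])
  out <- data.frame(chrom = dataset$sites$chrom[ok],
                    pos = dataset$sites$pos[ok],
                    a = comp$a, b = comp$b, c = comp$c, theta = comp$theta,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Average per-site F_ST in non-overlapping windows
#'
#' Arithmetic mean of the defined per-site theta values within each half-open
#' window [k*window_bp, (k+1)*window_bp) (0-based coordinates). Windows with
#' fewer than \code{min_sites} defined sites carry no score and are excluded.
#' The non-default \code{method = "ratio"} instead forms the ratio of summed
#' components sum(a)/sum(a+b+c) per window.
#'
#' @param site_table output of \code{\link{fst_site_table}} (or any
#'   data.frame with chrom, pos, a, b, c, theta).
#' @param window_bp window size in bp (default 25 kb).
#' @param min_sites minimum defined sites per scored window.
#' @param method "average" (mean of per-site ratios, default) or "ratio"
#'   (ratio of sums).
#' @return A \code{window_track} (statistic "FST") with an n_sites column.
#' @export
fst_window_average <- function(site_table, window_bp = 25000, min_sites = 1,
                               method = c("average", "ratio")) {
  method <- match.arg(method)
  st <- site_table[!is.na(site_table$theta), , drop = FALSE]
  win <- floor((st$pos - 1) / window_bp)
  key <- paste(st$chrom, win, sep = ":")
  n_sites <- as.integer(table(key)[unique(key)])
  first <- !duplicated(key)
  score <- if (method == "average") {
    tapply(st$theta, key, mean)[unique(key)]
  } else {
    num <- tapply(st$a, key, sum)[unique(key)]
    den <- tapply(st$a + st$b + st$c, key, sum)[unique(key)]
    ifelse(den == 0, NA_real_, num / den)
  }
  df <- data.frame(chrom = st$chrom[first], win = win[first],
                   score = as.numeric(score), n_sites = n_sites,
                   stringsAsFactors = FALSE)
  df <- df[df$n_sites >= min_sites & !is.na(df$score), , drop = FALSE]
  df <- df[order(df$chrom, df$win), , drop = FALSE]
  new_window_track(df$chrom, df$win * window_bp, (df$win + 1) * window_bp,
                   df$score, "FST", extra = df[, "n_sites", drop = FALSE])
}
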