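# Composite-likelihood-ratio sweep scan.
#
# The sweep model: at distance d from the swept site, each of the n sampled
# lineages escapes the sweep independently with probability
# p_escape = 1 - exp(-alpha * d). The e escaped lineages plus one lineage for
# the sweep ancestor form an ancestral sample of size e + 1 whose derived
# count j follows the background spectrum projected to that size; with
# probability j/(e+1) the ancestor carries the derived allele, so the modern
# derived count is (j - 1) + (n - e), otherwise j. When all n lineages escape
# there is no sweep-ancestor lineage and the modern count follows the
# background spectrum directly. The observed-site distribution conditions on
# polymorphism (classes 1..n-1).

# Mixture components independent of (alpha, d): row e+1 holds the
# unconditioned mass over modern counts b = 0..n given e escaped lineages.
sweep_mixture_matrix <- function(sfs, n) {
  stopifnot(inherits(sfs, "site_sfs"))
  if (sfs$folded) stopf("the sweep model requires an unfolded spectrum")
  if (sfs$n != n) stopf("sfs is at n = %d, expected %d", sfs$n, n)
  E <- matrix(0, n + 1L, n + 1L)
  for (e in 0:(n - 1L)) {
    k <- e + 1L
    q <- project_raw(sfs$probs, n, k)     # j = 0..k
    j <- 0:k
    b_anc <- j - 1L + (n - e)             # ancestor derived
    w_anc <- q * j / k
    b_esc <- j                            # ancestor ancestral
    w_esc <- q * (1 - j / k)
    for (t in seq_along(j)) {
      if (w_anc[t] > 0) E[e + 1L, b_anc[t] + 1L] <-
        E[e + 1L, b_anc[t] + 1L] + w_anc[t]
      if (w_esc[t] > 0) E[e + 1L, b_esc[t] + 1L] <-
        E[e + 1L, b_esc[t] + 1L] + w_esc[t]
    }
  }
  E[n + 1L, 2:n] <- sfs$probs             # e = n: background
  E
}

sweep_probs_from_matrix <- function(E, n, alpha, d) {
  p_esc <- -expm1(-alpha * d)
  w <- dbinom(0:n, n, p_esc)
  mass <- drop(w %*% E)
  poly <- mass[2:n]
  s <- sum(poly)
  if (s <= 0) stopf("polymorphism probability is 0 at alpha*d = %g", alpha * d)
  poly / s
}

#' Sweep-distorted allele-count distribution
#'
#' Probability of each derived-allele count b in 1..n-1 at a site a physical
#' distance d from a hard sweep of intensity alpha, given the background
#' spectrum, conditioned on the site being polymorphic. As alpha*d grows the
#' escape probability tends to 1 and the distribution returns to the
#' background spectrum; at small alpha*d mass piles onto the extreme classes
#' 1 and n-1.
#'
#' @param sfs unfolded background \code{\link{site_sfs}} at size \code{n}.
#' @param n haploid sample size.
#' @param alpha sweep intensity per bp (> 0).
#' @param d distance in bp from the test point to the site (> 0).
#' @return Probability vector over counts 1..n-1 (sums to 1).
#' @export
sweep_site_distribution <- function(sfs, n, alpha, d) {
  check_number(alpha, "alpha", 1e-300)
  check_number(d, "d")
  if (d <= 0) stopf("d must be > 0: a site at the swept position has polymorphism probability 0")
  E <- sweep_mixture_matrix(sfs, n)
  sweep_probs_from_matrix(E, n, alpha, d)
}

# Precomputed lookup table of log sweep probabilities on a log-spaced grid of
# u = alpha * d, used by the genome scan. u above u_max is treated as
# background (escape probability ~ 1); u is clamped below at u_min.
make_clr_table <- function(sfs, n, u_min = 1e-4, u_max = 50, K = 600L) {
  E <- sweep_mixture_matrix(sfs, n)
  log_u <- seq(log(u_min), log(u_max), length.out = K)
  W <- outer(-expm1(-exp(log_u)), 0:n, function(p, k) dbinom(k, n, p))
  mass <- W %*% E                          # K x (n+1)
  poly <- mass[, 2:n, drop = FALSE]
  poly <- poly / rowSums(poly)
  list(log_u = log_u, step = log_u[2] - log_u[1], u_min = u_min,
       u_max = u_max, logP = log(poly), log_bg = log(sfs$probs), n = n)
}

table_loglik <- function(tbl, u, counts) {
  lp <- numeric(length(u))
  bg <- u >= tbl$u_max
  if (any(bg)) lp[bg] <- tbl$log_bg[counts[bg]]
  if (any(!bg)) {
    idx <- round((log(pmax(u[!bg], tbl$u_min)) - tbl$log_u[1]) / tbl$step) + 1
    idx <- pmin(pmax(idx, 1L), length(tbl$log_u))
    lp[!bg] <- tbl$logP[cbind(idx, counts[!bg])]
  }
  sum(lp)
}

default_alpha_grid <- function(d_near, n_alpha = 20L) {
  a_min <- -log1p(-0.01) / d_near
  a_max <- -log(1 - 0.999) / d_near
  exp(seq(log(a_min), log(a_max), length.out = n_alpha))
}

#' Composite likelihood ratio at one test point
#'
#' Maximizes, over a grid of sweep intensities, twice the difference between
#' the composite log-likelihood of the observed derived counts under the
#' sweep model centred at \code{test_position} and under the background
#' spectrum. The background model is always part of the comparison, so the
#' CLR is nonnegative; ties are broken toward the smallest alpha.
#'
#' @param sites data.frame with columns \code{position} and \code{count}
#'   (derived counts in 1..n-1). Sites at distance 0 are excluded.
#' @param sfs unfolded background \code{\link{site_sfs}}.
#' @param test_position grid-point coordinate in bp.
#' @param alpha_grid optional vector of sweep intensities; default: 20
#'   log-spaced values giving the nearest site an escape probability from
#'   0.01 to 0.999.
#' @param n_alpha grid size when \code{alpha_grid} is NULL.
#' @param table optional precomputed lookup table (internal use by the scan).
#' @return list(clr, alpha_hat) — alpha_hat is NA when the background
#'   maximizes the likelihood.
#' @export
clr_at_gridpoint <- function(sites, sfs, test_position, alpha_grid = NULL,
                             n_alpha = 20L, table = NULL) {
  stopifnot(inherits(sfs, "site_sfs"))
  n <- sfs$n
  counts <- as.integer(sites$count)
  if (any(counts < 1L | counts > n - 1L))
    stopf("derived counts must lie in 1..%d", n - 1L)
  d <- abs(sites$position - test_position)
  keep <- d > 0
  d <- d[keep]; counts <- counts[keep]
  if (!length(d)) return(list(clr = 0, alpha_hat = NA_real_))
  if (is.null(alpha_grid)) alpha_grid <- default_alpha_grid(min(d), n_alpha)
  ll_bg <- sum(log(sfs$probs)[counts])
  if (is.null(table)) {
    E <- sweep_mixture_matrix(sfs, n)
    ll <- vapply(alpha_grid, function(a) {
      ud <- split(seq_along(d), d)  # share work across equal distances
      tot <- 0
      for (grp in ud) {
        pr <- sweep_probs_from_matrix(E, n, a, d[grp[1]])
        tot <- tot + sum(log(pr)[counts[grp]])
      }
      tot
    }, numeric(1))
  } else {
    ll <- vapply(alpha_grid, function(a) table_loglik(table, a * d, counts),
                 numeric(1))
  }
  diffs <- ll - ll_bg
  best <- max(diffs)
  if (best <= 0) return(list(clr = 0, alpha_hat = NA_real_))
  hit <- which(diffs >= best - 1e-12)
  list(clr = 2 * best, alpha_hat = alpha_grid[min(hit)])
}

#' Genome-wide composite-likelihood-ratio scan
#'
#' Places test points every \code{grid_bp} along each chromosome (starting at
#' \code{grid_bp/2}) and computes the CLR at each from the derived counts of
#' sites within \code{max_radius_bp}, against the genome-wide background
#' spectrum. Each test point is reported as the window
#' [point - grid_bp/2, point + grid_bp/2).
#'
#' @param x a complete (imputation-finished) \code{\link{genotype_dataset}},
#'   or a data.frame with columns \code{chrom}, \code{position},
#'   \code{count}.
#' @param sfs background spectrum; default: computed genome-wide from
#'   \code{x}.
#' @param grid_bp test-point spacing (default 25 kb).
#' @param max_radius_bp only sites within this distance of a test point enter
#'   its likelihood (default 1 Mb).
#' @param n_alpha size of the per-point alpha grid.
#' @param chrom_length named vector of chromosome lengths; default: the last
#'   site position per chromosome.
#' @param population population whose genotypes are scanned when \code{x} is
#'   a dataset (default: first population).
#' @return A \code{window_track} with columns chrom, start, end, score (CLR),
#'   alpha_hat, n_sites. Windows with no usable site carry score NA.
#' @export
clr_genome_scan <- function(x, sfs = NULL, grid_bp = 25000,
                            max_radius_bp = 1e6, n_alpha = 20L,
                            chrom_length = NULL, population = NULL) {
  if (inherits(x, "genotype_dataset")) {
    pop <- population %||% x$samples$population[1]
    idx <- pop_index(x, pop)
    g <- x$geno[, idx, drop = FALSE]
    if (anyNA(g))
      stopf("scan requires complete genotypes; run impute_missing() first")
    counts <- rowSums(g)
    sites <- data.frame(chrom = x$sites$chrom, position = x$sites$pos,
                        count = counts, stringsAsFactors = FALSE)
    n <- 2L * length(idx)
  } else {
    sites <- x
    n <- if (!is.null(sfs)) sfs$n else
      stopf("'sfs' is required when passing a site table")
  }
  poly <- sites$count >= 1L & sites$count <= n - 1L
  sites <- sites[poly, , drop = FALSE]
  if (!nrow(sites)) stopf("no polymorphic sites to scan")
  if (is.null(sfs)) sfs <- background_sfs(sites$count, n = n)
  tbl <- make_clr_table(sfs, n)
  out <- lapply(unique(sites$chrom), function(ch) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    len <- if (!is.null(chrom_length) && ch %in% names(chrom_length))
      chrom_length[[ch]] else max(s$position)
    points <- if (len < grid_bp) len / 2 else
      seq(grid_bp / 2, len, by = grid_bp)
    pos <- s$position
    score <- rep(NA_real_, length(points))
    ahat <- rep(NA_real_, length(points))
    nsit <- integer(length(points))
    for (i in seq_along(points)) {
      lo <- findInterval(points[i] - max_radius_bp, pos) + 1L
      hi <- findInterval(points[i] + max_radius_bp, pos)
      if (hi < lo) next
      res <- clr_at_gridpoint(
        data.frame(position = pos[lo:hi], count = s$count[lo:hi]),
        sfs, points[i], n_alpha = n_alpha, table = tbl)
      score[i] <- res$clr
      ahat[i] <- res$alpha_hat
      nsit[i] <- hi - lo + 1L
    }
    data.frame(chrom = ch, start = points - grid_bp / 2,
               end = points + grid_bp / 2, score = score,
               alpha_hat = ahat, n_sites = nsit, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  new_window_track(df$chrom, pmax(df$start, 0), df$end, df$score, "CLR",
                   extra = df[, c("alpha_hat", "n_sites")])
}
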