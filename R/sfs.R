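#' Construct a site-frequency spectrum object
#'
#' @param probs probabilities over derived-count classes 1..n-1 (unfolded) or
#'   1..floor(n/2) (folded); normalized internally.
#' @param n haploid sample size.
#' @param folded logical flag.
#' @return Object of class \code{site_sfs}.
#' @export
site_sfs <- function(probs, n, folded = FALSE) {
  n <- as.integer(n)
  if (n < 2) stopf("haploid sample size must be >= 2")
  len <- if (folded) n %/% 2L else n - 1L
  if (length(probs) != len)
    stopf("probs must have length %d for n = %d (%s)", len, n,
          if (folded) "folded" else "unfolded")
  if (any(probs < 0) || !any(probs > 0))
    stopf("probs must be nonnegative with positive total mass")
  structure(list(n = n, probs = probs / sum(probs), folded = folded),
            class = "site_sfs")
}

#' @export
print.site_sfs <- function(x, ...) {
  cat(sprintf("site_sfs: n = %d haploids, %s, %d classes\n", x$n,
              if (x$folded) "folded" else "unfolded", length(x$probs)))
  invisible(x)
}

#' Background site-frequency spectrum of a dataset
#'
#' Tabulates derived-allele counts across polymorphic sites into a normalized
#' spectrum over classes 1..n-1 (the alt allele is taken as derived). Sites
#' with missing genotypes are either projected down to the common haploid size
#' n by adding their exact hypergeometric mass, or excluded.
#'
#' @param x a \code{\link{genotype_dataset}}, or an integer vector of
#'   derived-allele counts (in which case \code{n} is required and all counts
#'   are taken at size \code{n}).
#' @param n common haploid size. Default for a dataset: twice the number of
#'   samples when data are complete, otherwise the smallest per-site observed
#'   haploid count (projection target).
#' @param population restrict to one population's samples (default: all).
#' @param missing "project" (hypergeometric downsampling, the default) or
#'   "exclude" (drop sites not fully observed at size n).
#' @param folded fold the spectrum over minor-allele count.
#' @return A \code{\link{site_sfs}}.
#' @export
background_sfs <- function(x, n = NULL, population = NULL,
                           missing = c("project", "exclude"),
                           folded = FALSE) {
  missing <- match.arg(missing)
  if (inherits(x, "genotype_dataset")) {
    g <- x$geno
    if (!is.null(population)) g <- g[, pop_index(x, population), drop = FALSE]
    n_obs <- 2L * rowSums(!is.na(g))
    counts <- rowSums(g, na.rm = TRUE)
    keep <- n_obs >= 2L
    n_obs <- n_obs[keep]; counts <- counts[keep]
    if (is.null(n)) n <- if (all(n_obs == 2L * ncol(g))) 2L * ncol(g)
                         else min(n_obs)
    n <- as.integer(n)
    if (missing == "exclude") {
      sel <- n_obs >= n & counts > 0 & counts < n_obs
      counts <- counts[sel]; n_obs <- n_obs[sel]
      full <- n_obs == n
      q <- tabulate(counts[full], nbins = n - 1L) + 0
      part <- which(!full)
    } else {
      sel <- n_obs >= n & counts > 0 & counts < n_obs
      counts <- counts[sel]; n_obs <- n_obs[sel]
      full <- n_obs == n
      q <- tabulate(counts[full], nbins = n - 1L) + 0
      part <- which(!full)
    }
    if (missing == "project" && length(part)) {
      # accumulate exact projection mass of each partially observed site
      key <- paste(n_obs[part], counts[part])
      for (grp in split(part, key)) {
        i <- grp[1]
        mass <- dhyper(1:(n - 1L), counts[i], n_obs[i] - counts[i], n)
        q <- q + length(grp) * mass
      }
    }
    if (!any(q > 0)) stopf("no polymorphic sites at haploid size n = %d", n)
  } else {
    counts <- as.integer(x)
    if (is.null(n)) stopf("'n' is required when passing a count vector")
    n <- as.integer(n)
    counts <- counts[counts > 0L & counts < n]
    if (!length(counts)) stopf("no polymorphic sites")
    q <- tabulate(counts, nbins = n - 1L) + 0
  }
  if (folded) {
    half <- n %/% 2L
    qf <- q[seq_len(half)]
    upper <- q[n - seq_len(half)]
    upper[n - seq_len(half) == seq_len(half)] <- 0  # middle class once
    qf <- qf + upper
    return(site_sfs(qf, n, folded = TRUE))
  }
  site_sfs(q, n, folded = FALSE)
}

# Raw hypergeometric projection of an unfolded spectrum (classes 1..n-1 at
# size n) to size m, returning mass over 0..m. Internal; allows m = 1.
project_raw <- function(probs, n, m) {
  q <- numeric(m + 1L)
  for (J in which(probs > 0)) {
    q <- q + probs[J] * dhyper(0:m, J, n - J, m)
  }
  q
}

#' Project a site-frequency spectrum to a smaller sample size
#'
#' Hypergeometric downsampling: the probability of derived count j' in a
#' subsample of m haploids is the spectrum-weighted hypergeometric mass.
#'
#' @param sfs an unfolded \code{\link{site_sfs}} at size n.
#' @param m target haploid size, 2 <= m <= n.
#' @param condition "raw" returns the full vector over 0..m (including the
#'   monomorphic classes); "polymorphic" renormalizes over 1..m-1 and returns
#'   a \code{site_sfs}.
#' @return Numeric vector (raw) or \code{site_sfs} (polymorphic).
#' @export
project_sfs <- function(sfs, m, condition = c("raw", "polymorphic")) {
  stopifnot(inherits(sfs, "site_sfs"))
  if (sfs$folded) stopf("projection requires an unfolded spectrum")
  condition <- match.arg(condition)
  m <- as.integer(m)
  if (m < 2) stopf("target size m must be >= 2")
  if (m > sfs$n) stopf("cannot project upward (m = %d > n = %d)", m, sfs$n)
  q <- project_raw(sfs$probs, sfs$n, m)
  names(q) <- 0:m
  if (condition == "raw") return(q)
  site_sfs(q[2:m] / sum(q[2:m]), m, folded = FALSE)
}
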