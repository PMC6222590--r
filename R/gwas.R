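#' Standardized genomic relationship matrix
#'
#' Centers and scales each SNP dosage column to unit variance and forms
#' G = ZZ'/m over the m retained SNPs. Monomorphic SNPs are skipped (count in
#' \code{attr(, "n_monomorphic")}); SNPs on \code{exclude_chromosome} are left
#' out, giving the leave-one-chromosome-out matrix used by
#' \code{\link{loco_scan}}.
#'
#' @param x a complete \code{\link{genotype_dataset}}, or a samples-x-SNPs
#'   dosage matrix.
#' @param exclude_chromosome chromosome whose SNPs are excluded (dataset
#'   input only).
#' @return n x n numeric matrix.
#' @export
standardized_grm <- function(x, exclude_chromosome = NULL) {
  if (inherits(x, "genotype_dataset")) {
    keep <- rep(TRUE, nrow(x$sites))
    if (!is.null(exclude_chromosome))
      keep <- x$sites$chrom != exclude_chromosome
    if (sum(keep) < 2)
      stopf("fewer than 2 SNPs outside chromosome '%s'",
            exclude_chromosome %||% "")
    X <- t(x$geno[keep, , drop = FALSE])
  } else {
    X <- as.matrix(x)
  }
  if (anyNA(X)) stopf("GRM requires complete genotypes; impute first")
  sds <- apply(X, 2, sd)
  mono <- sds == 0
  Z <- scale(X[, !mono, drop = FALSE])
  m <- ncol(Z)
  if (m < 1) stopf("no polymorphic SNPs for the GRM")
  G <- tcrossprod(Z) / m
  attr(G, "n_monomorphic") <- sum(mono)
  G
}

# Restricted-likelihood fit of the variance ratio delta = sigma2_e/sigma2_a
# for one SNP, in the eigenspace of G. Returns beta, se, wald_p, delta_hat.
fit_one_snp <- function(d, UtS, Uty, utx, grid, yy_w = NULL) {
  N <- length(d)
  Xf <- cbind(UtS, utx)
  p <- ncol(Xf)
  nll <- function(logdelta) {
    lam <- d + exp(logdelta)
    w <- 1 / lam
    Xw <- Xf * w
    M <- crossprod(Xf, Xw)
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    rhs <- crossprod(Xw, Uty)
    beta <- backsolve(R, forwardsolve(t(R), rhs))
    rss <- sum(Uty^2 * w) - sum(rhs * beta)
    if (rss <= 0) return(1e10)
    (N - p) * log(rss) + sum(log(lam)) + 2 * sum(log(diag(R)))
  }
  vals <- vapply(grid, nll, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- if (hi > lo) optimize(nll, c(lo, hi), tol = 1e-6) else
    list(minimum = grid[i])
  delta <- exp(opt$minimum)
  lam <- d + delta
  w <- 1 / lam
  Xw <- Xf * w
  M <- crossprod(Xf, Xw)
  Minv <- solve(M)
  beta <- drop(Minv %*% crossprod(Xw, Uty))
  rss <- sum((Uty - drop(Xf %*% beta))^2 * w)
  sigma2 <- rss / (N - p)
  se <- sqrt(sigma2 * Minv[p, p])
  b <- beta[p]
  c(beta = b, se = se,
    wald_p = pchisq((b / se)^2, df = 1, lower.tail = FALSE),
    delta_hat = delta)
}

#' Mixed-model association test for one or more SNPs
#'
#' Fits y = intercept + batch effects + SNP effect + polygenic term + error,
#' with the polygenic covariance proportional to \code{G}. G is
#' eigendecomposed once; for each SNP the variance ratio
#' delta = sigma2_e/sigma2_a is estimated by restricted maximum likelihood
#' over a log-scale grid on [1e-5, 1e5] refined to tolerance 1e-6 in log
#' delta, and the SNP effect is tested with a Wald chi-square (1 df) at the
#' GLS estimates. With G = I the model collapses to ordinary least squares.
#'
#' @param y phenotype vector.
#' @param batches factor of batch labels (or NULL for intercept only).
#' @param x dosage vector, or a samples-x-SNPs matrix to test many SNPs
#'   against the same G.
#' @param G genomic relationship matrix from \code{\link{standardized_grm}}.
#' @param grid_points number of coarse REML grid points.
#' @return data.frame(beta, se, wald_p, delta_hat); monomorphic SNPs get NA.
#' @export
lmm_assoc <- function(y, batches, x, G, grid_points = 13L) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  N <- length(y)
  stopifnot(nrow(X) == N, nrow(G) == N, ncol(G) == N)
  b <- if (is.null(batches)) NULL else as.factor(batches)
  S <- if (is.null(b) || nlevels(b) < 2) matrix(1, N, 1) else
    model.matrix(~ b, data.frame(b = b))
  if (qr(S)$rank < ncol(S))
    stopf("fixed-effect design is singular (collinear batch dummies)")
  eig <- eigen(G, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  Uty <- drop(crossprod(U, y))
  UtS <- crossprod(U, S)
  UtX <- crossprod(U, X)
  grid <- seq(log(1e-5), log(1e5), length.out = grid_points)
  sds <- apply(X, 2, sd)
  out <- matrix(NA_real_, ncol(X), 4,
                dimnames = list(colnames(X),
                                c("beta", "se", "wald_p", "delta_hat")))
  for (j in seq_len(ncol(X))) {
    if (is.na(sds[j]) || sds[j] == 0) next
    out[j, ] <- fit_one_snp(d, UtS, Uty, UtX[, j], grid)
  }
  as.data.frame(out)
}

#' Leave-one-chromosome-out mixed-model genome scan
#'
#' For each chromosome, builds the standardized GRM from all other
#' chromosomes' SNPs, eigendecomposes it once, and tests every SNP on the
#' held-out chromosome with \code{\link{lmm_assoc}}. Results are concatenated
#' genome-wide and paired with the SimpleM effective-test count and its
#' significance threshold.
#'
#' @param dataset a complete, QC-passed \code{\link{genotype_dataset}}
#'   restricted to the phenotyped samples (extra samples are dropped by
#'   matching on \code{phenotypes$sample}).
#' @param phenotypes data.frame(sample, trait, batch).
#' @param loco set FALSE to reuse the whole-genome GRM (required for
#'   single-chromosome data).
#' @param var_fraction variance fraction for \code{\link{simpleM_eff}}.
#' @param alpha family-wise error rate for the threshold.
#' @return An \code{assoc_result}: list(snps, m_eff, threshold, lambda_gc).
#' @export
loco_scan <- function(dataset, phenotypes, loco = TRUE, var_fraction = 0.99,
                      alpha = 0.05) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  need <- c("sample", "trait", "batch")
  if (!all(need %in% names(phenotypes)))
    stopf("phenotypes needs columns %s", paste(need, collapse = ", "))
  if (!nrow(phenotypes)) stopf("phenotype table is empty")
  missing_ids <- setdiff(phenotypes$sample, dataset$samples$sample)
  if (length(missing_ids))
    stopf("phenotyped sample(s) absent from genotypes: %s",
          paste(head(missing_ids, 5), collapse = ", "))
  ds <- subset_samples(dataset,
                       match(phenotypes$sample, dataset$samples$sample))
  if (anyNA(ds$geno)) stopf("scan requires complete genotypes; impute first")
  chroms <- unique(ds$sites$chrom)
  if (loco && length(chroms) < 2)
    stopf("LOCO needs >= 2 chromosomes; rerun with loco = FALSE")
  y <- phenotypes$trait
  batches <- phenotypes$batch
  res <- lapply(chroms, function(ch) {
    G <- if (loco) standardized_grm(ds, exclude_chromosome = ch)
         else standardized_grm(ds)
    on_ch <- which(ds$sites$chrom == ch)
    X <- t(ds$geno[on_ch, , drop = FALSE])
    r <- lmm_assoc(y, batches, X, G)
    cbind(data.frame(chrom = ch, pos = ds$sites$pos[on_ch],
                     stringsAsFactors = FALSE), r)
  })
  snps <- do.call(rbind, res)
  m_eff <- simpleM_eff(ds, var_fraction = var_fraction)
  thr <- significance_threshold(m_eff, alpha = alpha)
  chi <- (snps$beta / snps$se)^2
  lambda_gc <- median(chi, na.rm = TRUE) / qchisq(0.5, 1)
  structure(list(snps = snps, m_eff = m_eff, threshold = thr$threshold,
                 neglog10_threshold = thr$neglog10, alpha = alpha,
                 lambda_gc = lambda_gc),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  n_sig <- sum(x$snps$wald_p < x$threshold, na.rm = TRUE)
  cat(sprintf("assoc_result: %d SNPs tested, lambda_GC = %.3f\n",
              sum(!is.na(x$snps$wald_p)), x$lambda_gc))
  cat(sprintf("  SimpleM: %d effective tests, threshold %.3g (-log10 >= %.2f)\n",
              x$m_eff, x$threshold, x$neglog10_threshold))
  cat(sprintf("  genome-wide significant SNPs: %d\n", n_sig))
  invisible(x)
}

#' Effective number of independent tests (SimpleM)
#'
#' Per chromosome, takes the eigenvalues of the SNP-SNP correlation matrix
#' and counts the principal components needed to reach \code{var_fraction}
#' of the total variance; the genome-wide effective test count is the sum
#' over chromosomes. Monomorphic SNPs are excluded. When a chromosome has
#' more SNPs than samples the eigenvalues are obtained from the (identical
#' nonzero) spectrum of the sample-space cross-product.
#'
#' @param dataset a complete \code{\link{genotype_dataset}}.
#' @param var_fraction variance fraction (default 0.99).
#' @return Integer effective test count.
#' @export
simpleM_eff <- function(dataset, var_fraction = 0.99) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (anyNA(dataset$geno)) stopf("SimpleM requires complete genotypes")
  total <- 0L
  for (ch in unique(dataset$sites$chrom)) {
    X <- t(dataset$geno[dataset$sites$chrom == ch, , drop = FALSE])
    sds <- apply(X, 2, sd)
    X <- X[, sds > 0, drop = FALSE]
    m <- ncol(X)
    if (m == 0) next
    if (m == 1) { total <- total + 1L; next }
    n <- nrow(X)
    ev <- if (m <= n) {
      eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
    } else {
      Z <- scale(X)
      eigen(tcrossprod(Z), symmetric = TRUE,
            only.values = TRUE)$values / (n - 1)
    }
    ev <- pmax(ev, 0)
    k <- which(cumsum(ev) / m >= var_fraction - 1e-12)[1]
    if (is.na(k)) k <- length(ev)
    total <- total + k
  }
  if (total < 1) stopf("no polymorphic SNPs")
  total
}

#' SimpleM significance threshold
#'
#' @param m_eff effective number of independent tests (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return list(threshold = alpha/m_eff, neglog10 = -log10 threshold
#'   truncated to 2 decimals).
#' @export
significance_threshold <- function(m_eff, alpha = 0.05) {
  if (m_eff < 1) stopf("m_eff must be >= 1")
  thr <- alpha / m_eff
  list(threshold = thr, neglog10 = floor(-log10(thr) * 100) / 100)
}

#' Manhattan- and QQ-plot coordinate tables
#'
#' @param assoc an \code{assoc_result}.
#' @return list(manhattan = data.frame(chrom, pos, neglog10_p),
#'   qq = data.frame(expected, observed)) of -log10 p coordinates.
#' @export
assoc_plot_data <- function(assoc) {
  snps <- assoc$snps[!is.na(assoc$snps$wald_p), , drop = FALSE]
  man <- data.frame(chrom = snps$chrom, pos = snps$pos,
                    neglog10_p = -log10(snps$wald_p),
                    stringsAsFactors = FALSE)
  p <- sort(snps$wald_p)
  qq <- data.frame(expected = -log10((seq_along(p) - 0.5) / length(p)),
                   observed = -log10(p))
  list(manhattan = man, qq = qq)
}
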