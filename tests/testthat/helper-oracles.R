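# Independent oracle implementations, deliberately written as plain
# transcriptions (scalar loops, no shared code with R/) so the package paths
# can be checked against them.

# Weir & Cockerham (1984) two-population variance components, straight from
# the published equations, one site at a time.
wc_fst_oracle <- function(c1, c2) {
  r <- 2
  n1 <- sum(c1); n2 <- sum(c2)
  p1 <- (2 * c1[1] + c1[2]) / (2 * n1)
  p2 <- (2 * c2[1] + c2[2]) / (2 * n2)
  h1 <- c1[2] / n1
  h2 <- c2[2] / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  theta <- if (a + b + cc == 0) NA_real_ else a / (a + b + cc)
  c(a = a, b = b, c = cc, theta = theta)
}

# Exact conditional HWE null by full enumeration of heterozygote counts.
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hets, function(h) {
    naa_h <- (nA - h) / 2
    nbb_h <- n - naa_h - h
    exp(lfactorial(n) - lfactorial(naa_h) - lfactorial(h) -
          lfactorial(nbb_h) + h * log(2) - lchoose(2 * n, nA))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# Exhaustive hypergeometric projection (double loop, explicit binomials).
project_oracle <- function(probs, n, m) {
  q <- numeric(m + 1)
  for (J in 1:(n - 1)) {
    for (j in 0:m) {
      q[j + 1] <- q[j + 1] + probs[J] * choose(J, j) * choose(n - J, m - j) /
        choose(n, m)
    }
  }
  q
}

# Brute-force enumeration of the sweep-distorted count distribution over the
# escape count e, the ancestral-sample count j, and the ancestor's state.
sweep_dist_oracle <- function(probs, n, alpha, d) {
  p_esc <- 1 - exp(-alpha * d)
  mass <- numeric(n + 1)      # modern counts 0..n
  for (e in 0:n) {
    we <- dbinom(e, n, p_esc)
    if (e == n) {
      for (J in 1:(n - 1)) mass[J + 1] <- mass[J + 1] + we * probs[J]
      next
    }
    k <- e + 1
    q <- project_oracle(probs, n, k)
    for (j in 0:k) {
      b_anc <- j - 1 + (n - e)
      mass[b_anc + 1] <- mass[b_anc + 1] + we * q[j + 1] * j / k
      mass[j + 1] <- mass[j + 1] + we * q[j + 1] * (1 - j / k)
    }
  }
  poly <- mass[2:n]
  poly / sum(poly)
}

# Union-find style interval merge: windows closer than gap_bp join a group.
merge_oracle <- function(windows, gap_bp) {
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    grp <- rep(1, nrow(w))
    for (i in seq_len(nrow(w))[-1]) {
      prev_end <- max(w$end[grp == grp[i - 1] &
                              seq_len(nrow(w)) < i])
      grp[i] <- if (w$start[i] - prev_end < gap_bp) grp[i - 1]
                else grp[i - 1] + 1
    }
    for (g in unique(grp)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(w$start[grp == g]),
        end = max(w$end[grp == g]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Naive O(n*m) interval intersection of one set against the union of others,
# with abutting/overlapping outputs coalesced.
intersect_oracle <- function(a, b) {
  pieces <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      s <- max(a$start[i], b$start[j])
      e <- min(a$end[i], b$end[j])
      if (s < e)
        pieces[[length(pieces) + 1]] <- data.frame(
          chrom = a$chrom[i], start = s, end = e, stringsAsFactors = FALSE)
    }
  }
  if (!length(pieces))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, pieces)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    last <- nrow(out)
    if (df$chrom[i] == out$chrom[last] && df$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], df$end[i])
    } else {
      out <- rbind(out, df[i, ])
    }
  }
  rownames(out) <- NULL
  out
}
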