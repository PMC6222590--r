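---
title: "Detecting artificial-selection signatures and trait associations with artisel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting artificial-selection signatures and trait associations with artisel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Modern livestock breeds carry the footprints of decades of artificial
selection. Two complementary signals identify the loci involved. First, a
completed (hard) selective sweep distorts the site-frequency spectrum (SFS)
around the selected site: linked neutral variants are dragged toward fixation,
leaving an excess of very rare and very common derived alleles. Second,
selection in one breed but not in a related wild population inflates allele
frequency differentiation (F~ST~) locally. Where both signals coincide, and
where a quantitative-trait association maps nearby, there is a strong case
that the region responds to selection on a breeding goal.

`artisel` implements this reasoning as a tested pipeline for a focal
population contrasted with one or more reference populations:

1. a composite-likelihood-ratio (CLR) scan of the SFS against the genome-wide
   background spectrum, on a 25-kb grid;
2. per-site Weir–Cockerham F~ST~ averaged in non-overlapping 25-kb windows,
   one track per reference population;
3. empirical-percentile significance (98th percentile by genome-wide
   ranking), 200-kb merging into candidate selection regions (CSRs), and
   CLR-by-F~ST~ intersection into candidate artificial-selection regions
   (CASRs);
4. a leave-one-chromosome-out (LOCO) mixed-model GWAS with a SimpleM
   multiple-testing threshold, joined back to the CASRs.

Because real two-population sequencing data are large and access-restricted,
the package ships a synthetic-data generator with the exact statistical
structure every stage assumes, so the whole pipeline is exercised end to end
by its test suite.

## The sweep model behind the CLR

Let the background spectrum $p_b$, $b = 1, \dots, n-1$, be the genome-wide
distribution of derived-allele counts among $n$ sampled haploid lineages
(`background_sfs()`). At physical distance $d$ from a swept site, each
lineage escapes the sweep by recombination independently with probability

$$p_e = 1 - e^{-\alpha d},$$

where $\alpha$ is the sweep intensity per bp (large $\alpha$ = strong/fast
sweep = narrow footprint). Conditional on $e$ escaped lineages, the
non-escaped lineages coalesce into the sweep ancestor, so the ancestral
sample has $e + 1$ lineages (or $n$ when everyone escapes). Its derived count
$j$ follows the background spectrum projected down to that size by exact
hypergeometric sampling (`project_sfs()`); with probability $j/(e+1)$ the
sweep ancestor itself carries the derived allele, in which case the modern
count is $(j - 1) + (n - e)$, otherwise it is $j$. Conditioning on
polymorphism gives the sweep-distorted site distribution
(`sweep_site_distribution()`). As $\alpha d \to \infty$ this returns to the
background; as $\alpha d \to 0$ the mass piles onto counts $1$ and $n-1$ —
the classic sweep skew.

The CLR at a test point is twice the log-ratio of the maximized composite
likelihood under this model to the background likelihood,

$$\mathrm{CLR} = 2\Big[\max_\alpha \sum_i \log P(b_i \mid \alpha, d_i) -
\sum_i \log p_{b_i}\Big],$$

maximized over a log-spaced grid of 20 intensities chosen per test point so
that the nearest site's escape probability spans 0.01–0.999. The background
model always participates, so the statistic is nonnegative; ties break toward
the smallest $\alpha$. Test points sit every 25 kb (`clr_genome_scan()`),
each scoring the sites within 1 Mb.

Numerical notes: the scan precomputes the mixture distribution on a 600-point
log-spaced lookup table in $u = \alpha d$ over $[10^{-4}, 50]$ ($u > 50$ is
treated as background, which is exact to $10^{-6}$ well before that point);
the exported `sweep_site_distribution()` and `clr_at_gridpoint()` (without a
table) are exact and are what the enumeration oracles in the test suite
check. Sites at $d = 0$ are excluded from a test point's likelihood — under
the model a site at the swept position cannot be polymorphic. Alleles are
polarized by taking the alt allele as derived (the generator makes alt the
derived state); a folded spectrum can be built for data without reliable
polarization, though the scan itself operates unfolded.

## Weir–Cockerham F~ST~ in windows

`wc_fst_site()` computes the 1984 variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$ (within
individuals) from the two populations' genotype counts, with
$\hat\theta = a/(a+b+c)$, undefined when the site is monomorphic in both
populations and *not* clamped when negative — truncating negatives would
bias window means upward. `fst_window_average()` averages per-site
$\hat\theta$ in non-overlapping 25-kb windows (the default, matching how the
scan statistics are ranked) or, with `method = "ratio"`, forms
$\sum a / \sum(a+b+c)$ per window.

The distinction matters. Under the Balding–Nichols model (below) the
*ratio of sums* is a consistent estimator of the differentiation parameter
$F$, while the mean of per-site ratios is biased low by Jensen's inequality
(about 0.15 at $F = 0.2$ in the generator's regime). The package therefore
uses the per-site average for ranking windows — a monotone transformation of
evidence is harmless there — but the ratio form whenever the goal is to
estimate $F$ itself, which is how the parameter-recovery checks are run.

## Regions: empirical percentiles, merging, intersection

Window scores from either statistic get empirical p-values by genome-wide
descending rank ($p = \mathrm{rank}/N$, ties sharing their maximum rank).
Windows scoring strictly above the $\lceil 0.98N \rceil$-th smallest score
are significant; with all-distinct scores this selects exactly
$N - \lceil 0.98N \rceil$ windows (1,811 of 90,588; 1,806 of 90,322), and
ties can only shrink the selection, which is why a tied track can yield
slightly fewer. Selected windows merge into a CSR whenever the inter-window
gap is below 200 kb — the merge radius justified by the LD-decay analysis
(`ld_decay_curve()`, squared dosage correlation in 1000-bp bins; dosage
$r^2$ is used rather than haplotype-EM $r^2$ because genotypes are
unphased). A CLR CSR becomes a CASR where it overlaps, by at least 1 bp, the
union of the reference-population F~ST~ CSR tracks (`mode = "both"` demands
overlap with each track; the union is the default because either wild
reference is evidence of differentiation). Genes are annotated within region
± 100 kb — a 200-kb window centred on the signature.

## The mixed model and SimpleM

For the association branch the trait is modelled as

$$y = \mu + S s + x\beta + g + e, \qquad
g \sim N(0, \sigma^2_a G), \quad e \sim N(0, \sigma^2_e I),$$

with $S$ the batch design, $x$ the SNP dosage and $G$ the standardized
genomic relationship matrix $ZZ^\top/m$ over centred, unit-variance dosage
columns. To avoid fitting the tested SNP into its own polygenic term, the
$G$ used for a SNP excludes every SNP on the same chromosome (LOCO,
`loco_scan()`): one GRM and one eigendecomposition per chromosome. In the
eigenbasis of $G$ the model is heteroscedastic ordinary regression with
per-sample variance $\sigma^2_a(\lambda_i + \delta)$,
$\delta = \sigma^2_e/\sigma^2_a$; $\delta$ is estimated per SNP by
restricted maximum likelihood on a log-scale grid over $[10^{-5}, 10^5]$
refined by 1-D optimization to $10^{-6}$ in $\log\delta$, and the SNP effect
is tested by a Wald $\chi^2_1$ at the GLS estimates. With $G = I$ the whole
machinery collapses to ordinary least squares, which the tests verify to
$10^{-6}$.

The genome-wide threshold divides $\alpha = 0.05$ by the effective number of
independent tests: per chromosome, the number of principal components of the
SNP correlation matrix needed to reach 99% of total variance, summed over
chromosomes (`simpleM_eff()`). The block-wise sum is both the tractable and
the established form of this correction; when a chromosome carries more SNPs
than samples the spectrum is computed in sample space, which shares the
nonzero eigenvalues. At 4,853 effective tests the threshold is
$1.03 \times 10^{-5}$, i.e. $-\log_{10} p \ge 4.98$.

## What the synthetic generator emulates

`simulate_study()` composes three layers, each inverted from a model the
pipeline fits:

* **Divergence.** Per site, an ancestral frequency $p \sim U(0.05, 0.95)$
  (avoiding near-fixed sites where differentiation estimators degenerate);
  each population draws its frequency from the Balding–Nichols law
  $\mathrm{Beta}\big(p(1-F)/F,\ (1-p)(1-F)/F\big)$, with mean $p$ and
  variance $F p(1-p)$, so the Weir–Cockerham ratio-of-sums recovers $F$.
  $F = 0$ short-circuits to both populations using $p$. Genotypes are
  $\mathrm{Binomial}(2, p_k)$.
* **Sweep.** Focal-population derived counts near the swept site are
  redrawn from the CLR sweep model itself at each site's distance, using the
  realized off-sweep spectrum as background. This makes position recovery a
  well-posed closed loop rather than an approximation claim; coalescent or
  forward simulation is deliberately out of scope.
* **Phenotype.** $y$ = intercept + batch effect + causal dosage effects +
  polygenic term + noise, with the polygenic term drawn with covariance
  proportional to the realized standardized GRM — exactly the association
  model's assumption — and the causal and polygenic parts rescaled to their
  target fractions `h2_snp` and `h2_poly` of the non-batch variance.

Missingness is uniform at random at `missing_rate`; real
genotyping-by-sequencing missingness is structured (depth- and
locus-dependent), but its structure is not identifiable from the published
description, so no structure is invented. Consequences for interpretation:
passing tests demonstrate correctness of the estimators and the pipeline
plumbing under the models' own assumptions, not robustness to unmodelled
features of real data — reference bias, batch-correlated missingness,
genotyping error, LD between simulated sites (sites are exchangeable given
frequencies here), or soft/incomplete sweeps.

Default study design (chosen once to mirror the kind of study the pipeline
targets): a 282-animal focal cohort with a 50-animal reference population,
three 5-Mb chromosomes carrying a dense variant panel of 4,000 segregating
sites each (~0.8 SNPs/kb — a scaled-down stand-in for whole-genome-sequence
density), $F = 0.2$, sweep intensity $\alpha = 10^{-5}$ per bp (half-escape
radius $\ln 2/\alpha \approx 69$ kb, i.e. a sub-100-kb footprint), 5%
missingness, three batches with effects 0/0.5/1 trait SD, and
`h2_snp = 0.3` across three causal SNPs over a polygenic background of
`h2_poly = 0.3`.

The two branches deliberately see different slices of this data, the way
such studies are actually run. Sweep detection favours deep sequencing of a
modest panel, whereas association favours genotyping a large cohort at
sparse marker density; the pipeline mirrors both axes. The scan branch
subsamples each population to a 50-diploid panel (`scan_panel`) but scans
the full dense site panel — window-level F~ST~ discrimination depends
directly on sites per 25-kb window, and at sparse marker density the
98th-percentile rule is dominated by few-site window noise rather than by
signal. The association branch uses the whole focal cohort but a
`gwas_site_frac = 0.3` thinning of the sites (~0.24 SNPs/kb, a typical GBS
marker density), with planted causal sites always retained (assumed typed).
The `scan_panel` subsampling also bounds the $O(n^3)$ setup of the sweep
mixture at scan time.

## QC and imputation choices

Site filters run in a fixed order — depth ≥ 4, RMS mapping quality ≥ 20,
adjacent-SNP distance ≥ 5 bp, per-population missing ratio (< 50% generally,
< 20% for the scan input), pooled MAF ≥ 0.01, and, for the GWAS set only, a
Hardy–Weinberg exact-test floor of $10^{-6}$ — with each removed site
attributed to the first criterion it fails, so the report columns sum to the
sites removed. The adjacency rule is greedy left-to-right (drop a site
closer than 5 bp to the last *retained* site); symmetric pair-dropping can
cascade through dense clusters and was rejected. The HWE test is the
two-sided exact conditional test on genotype counts, computed within each
population. Missing genotypes are imputed by a per-site, per-population
binomial draw at the observed alt-allele frequency — a deliberately simple,
honest imputer (no phasing, no reference panel), deterministic under the run
seed, recorded in every run manifest.

## Open choices resolved here

* Depth and mapping-quality thresholds are applied per site (INFO-level),
  the only level at which a VCF is guaranteed to carry them.
* "Fell into the 98th percentile" is operationalized as strictly above the
  $\lceil 0.98N \rceil$-th order statistic; this reproduces the printed
  selection counts for distinct scores and explains smaller counts as tie
  effects.
* CASRs require overlap with *either* reference F~ST~ track by default
  (config switch for *both*).
* The distance at which an associated SNP counts as "near" a selection
  region is not dictated by the method; the default is 1 Mb
  (`hit_dist_bp`), surfaced in the configuration and the overlap report.
* Per-SNP REML estimation of $\delta$ (exact, GEMMA-like) is used instead of
  reusing a single null-model $\delta$; the cost is bounded by the
  eigendecomposition reuse per chromosome.

## Problem sizes used by the checks

The statistical checks run at: 2 × 50 diploids × 5,000 sites per
differentiation level for F~ST~ recovery; 50 replicates of a 10-Mb
chromosome with 5,000 sites for CLR localization (≥ 90% of argmax windows
within 100 kb of the truth); 2,000 SNPs × 10 permutation seeds for null
calibration of the mixed model (type-I error within the binomial 95% CI of
0.05, $\lambda_{GC}$ near 1); and 20 full pipeline runs of the default
study design for joint recovery of the planted sweep and causal SNP
(≥ 80% CASR coverage of the sweep, ≥ 70% joint CASR–hit recovery). These
sizes keep each property estimable with useful Monte-Carlo precision while
the whole suite stays comfortably runnable on a laptop.

## Known limitations

* The CLR uses physical distance; recombination-map-aware distances and
  background-selection corrections are out of scope.
* Only biallelic SNPs and two-population F~ST~ are supported; no
  multi-population $\hat\theta$, no haplotype statistics.
* The imputer does not use LD; with high missingness it attenuates
  association signals relative to haplotype-aware imputation.
* Empirical-percentile significance is a ranking rule, not an error-rate
  guarantee: 2% of windows are always selected, whatever the genome-wide
  evidence.
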