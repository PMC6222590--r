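# Empirical-percentile significance, region merging and intersection.
# All region coordinates are 0-based half-open (BED convention); conversion
# from 1-based VCF positions happens upstream when windows are built.

#' Empirical p-values by genome-wide ranking
#'
#' p = rank / N where rank 1 is the largest score and N the number of scored
#' windows; tied scores share the maximum rank of their group.
#'
#' @param track a \code{window_track}.
#' @return The track with an \code{empirical_p} column (NA for unscored
#'   windows).
#' @export
empirical_pvalues <- function(track) {
  scored <- !is.na(track$score)
  p <- rep(NA_real_, nrow(track))
  N <- sum(scored)
  if (N > 0)
    p[scored] <- rank(-track$score[scored], ties.method = "max") / N
  track$empirical_p <- p
  track
}

#' Select windows above the empirical percentile cutoff
#'
#' The cutoff is the ceiling(quantile * N)-th smallest score among the N
#' scored windows; selected windows are those scoring strictly above it.
#' With all-distinct scores this selects exactly N - ceiling(quantile * N)
#' windows; ties at the cutoff reduce the selection.
#'
#' @param track a \code{window_track}.
#' @param quantile empirical quantile (default 0.98).
#' @return The selected rows of \code{track}; the cutoff is in
#'   \code{attr(, "cutoff")}.
#' @export
significant_windows <- function(track, quantile = 0.98) {
  scored <- which(!is.na(track$score))
  if (!length(scored)) stopf("no scored windows")
  s <- track$score[scored]
  cutoff <- sort(s)[ceiling(quantile * length(s))]
  sel <- track[scored[s > cutoff], , drop = FALSE]
  attr(sel, "cutoff") <- cutoff
  sel
}

#' Merge selected windows into candidate selection regions
#'
#' Consecutive selected windows on one chromosome are merged into one region
#' when the gap between them (next start minus previous end) is smaller than
#' \code{gap_bp}; the region spans from the first window's start to the last
#' window's end.
#'
#' @param selected data.frame of selected windows (chrom, start, end), e.g.
#'   from \code{\link{significant_windows}}.
#' @param gap_bp maximum merged gap, exclusive (default 200 kb).
#' @param source provenance label stored on the regions.
#' @return data.frame(chrom, start, end, source, n_windows,
#'   member_windows) — member_windows holds comma-separated input row
#'   indices.
#' @export
merge_windows <- function(selected, gap_bp = 200000, source = "CSR") {
  if (!nrow(selected))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), source = character(0),
                      n_windows = integer(0), member_windows = character(0),
                      stringsAsFactors = FALSE))
  ord <- order(selected$chrom, selected$start)
  sel <- selected[ord, , drop = FALSE]
  out <- list()
  cur <- list(chrom = sel$chrom[1], start = sel$start[1], end = sel$end[1],
              members = ord[1])
  flush <- function(cur) data.frame(
    chrom = cur$chrom, start = cur$start, end = cur$end, source = source,
    n_windows = length(cur$members),
    member_windows = paste(sort(cur$members), collapse = ","),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sel))[-1]) {
    if (sel$chrom[i] == cur$chrom && sel$start[i] - cur$end < gap_bp) {
      cur$end <- max(cur$end, sel$end[i])
      cur$members <- c(cur$members, ord[i])
    } else {
      out[[length(out) + 1L]] <- flush(cur)
      cur <- list(chrom = sel$chrom[i], start = sel$start[i],
                  end = sel$end[i], members = ord[i])
    }
  }
  out[[length(out) + 1L]] <- flush(cur)
  do.call(rbind, out)
}

regions_to_granges <- function(regions) {
  if (!nrow(regions))
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1, regions$end))
}

granges_to_regions <- function(gr, source) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr), source = source,
             stringsAsFactors = FALSE)
}

#' Intersect CLR and F_ST candidate selection regions
#'
#' A CLR region contributes to a candidate artificial-selection region (CASR)
#' wherever it overlaps, by at least 1 bp, the union of the F_ST region
#' tracks ("either" mode, default) or their intersection ("both" mode). The
#' emitted CASRs are the intersection intervals, with the matching F_ST
#' track(s) recorded as provenance.
#'
#' @param clr_csrs CLR regions (data.frame chrom/start/end, 0-based
#'   half-open).
#' @param fst_csrs_a F_ST regions for the first reference population.
#' @param fst_csrs_b optional second F_ST track.
#' @param mode "either" or "both".
#' @return data.frame(chrom, start, end, source, fst_tracks).
#' @export
intersect_regions <- function(clr_csrs, fst_csrs_a, fst_csrs_b = NULL,
                              mode = c("either", "both")) {
  mode <- match.arg(mode)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), source = character(0),
                      fst_tracks = character(0), stringsAsFactors = FALSE)
  if (!nrow(clr_csrs)) return(empty)
  gr_clr <- regions_to_granges(clr_csrs)
  gr_a <- regions_to_granges(fst_csrs_a)
  gr_b <- if (!is.null(fst_csrs_b)) regions_to_granges(fst_csrs_b)
          else GenomicRanges::GRanges()
  # suppressWarnings: disjoint seqlevel sets between tracks are a legitimate
  # empty-overlap case, not a coordinate-system problem
  gr_fst <- if (mode == "either" || length(gr_b) == 0)
    suppressWarnings(GenomicRanges::reduce(c(gr_a, gr_b)))
  else
    suppressWarnings(GenomicRanges::intersect(gr_a, gr_b))
  if (length(gr_fst) == 0) return(empty)
  casr <- suppressWarnings(GenomicRanges::intersect(gr_clr, gr_fst))
  if (length(casr) == 0) return(empty)
  out <- granges_to_regions(casr, "CASR")
  tracks <- vapply(seq_along(casr), function(i) {
    hit_a <- length(gr_a) && any(IRanges::overlapsAny(casr[i], gr_a))
    hit_b <- length(gr_b) && any(IRanges::overlapsAny(casr[i], gr_b))
    paste(c(if (hit_a) "fst_a", if (hit_b) "fst_b"), collapse = ",")
  }, character(1))
  out$fst_tracks <- tracks
  out
}

read_gene_models <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gff <- read.table(path, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE,
                      col.names = c("chrom", "source", "type", "start",
                                    "end", "score", "strand", "phase",
                                    "attr"))
    gff <- gff[gff$type %in% c("gene", "mRNA"), , drop = FALSE]
    name <- sub(".*(?:ID|Name)=([^;]+).*", "\\1", gff$attr)
    data.frame(chrom = gff$chrom, start = gff$start - 1, end = gff$end,
               name = name, stringsAsFactors = FALSE)  # to 0-based half-open
  } else {
    bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
               name = if (ncol(bed) >= 4) bed[[4]] else
                 sprintf("gene_%d", seq_len(nrow(bed))),
               stringsAsFactors = FALSE)
  }
}

#' Annotate regions with overlapping genes and nearby association hits
#'
#' Lists, for each region, the gene models overlapping the region extended by
#' \code{flank_bp} on each side (a 200-kb window around the signature at the
#' default 100-kb flank), and reports for each significant associated SNP the
#' nearest region and its distance, flagging it "nearby" within
#' \code{hit_dist_bp}.
#'
#' @param regions data.frame(chrom, start, end, ...) in 0-based half-open
#'   coordinates.
#' @param gene_models path to a BED6 (0-based) or GFF3 (1-based) file, or an
#'   equivalent data.frame(chrom, start, end, name) in 0-based half-open
#'   coordinates.
#' @param assoc optional \code{assoc_result} (see \code{\link{loco_scan}});
#'   only its genome-wide-significant SNPs are matched.
#' @param flank_bp gene-search flank (default 100 kb).
#' @param hit_dist_bp distance within which an associated SNP is called
#'   "nearby" (default 1 Mb).
#' @return list(regions, hits): regions gains a \code{genes} column; hits is
#'   a data.frame of significant SNPs with nearest-region distances (NULL
#'   when no assoc given).
#' @export
annotate_regions <- function(regions, gene_models, assoc = NULL,
                             flank_bp = 100000, hit_dist_bp = 1e6) {
  genes <- if (is.character(gene_models)) read_gene_models(gene_models)
           else gene_models
  known <- unique(regions$chrom)
  unknown <- !(genes$chrom %in% known)
  if (any(unknown) && nrow(regions)) {
    warning(sprintf("skipping %d gene(s) on chromosome(s) absent from regions",
                    sum(unknown)))
    genes <- genes[!unknown, , drop = FALSE]
  }
  gr_genes <- regions_to_granges(genes)
  regions$genes <- vapply(seq_len(nrow(regions)), function(i) {
    win <- GenomicRanges::GRanges(
      regions$chrom[i],
      IRanges::IRanges(max(regions$start[i] - flank_bp, 0) + 1,
                       regions$end[i] + flank_bp))
    hit <- suppressWarnings(IRanges::overlapsAny(gr_genes, win))
    paste(genes$name[hit], collapse = ",")
  }, character(1))
  hits <- NULL
  if (!is.null(assoc)) {
    sig <- assoc$snps[!is.na(assoc$snps$wald_p) &
                      assoc$snps$wald_p < assoc$threshold, , drop = FALSE]
    if (nrow(sig) && nrow(regions)) {
      gr_reg <- regions_to_granges(regions)
      gr_snp <- GenomicRanges::GRanges(sig$chrom,
                                       IRanges::IRanges(sig$pos, sig$pos))
      nearest <- suppressWarnings(
        GenomicRanges::distanceToNearest(gr_snp, gr_reg))
      hits <- data.frame(chrom = sig$chrom, pos = sig$pos,
                         wald_p = sig$wald_p,
                         region = NA_integer_, distance = NA_real_,
                         nearby = FALSE, stringsAsFactors = FALSE)
      qh <- S4Vectors::queryHits(nearest)
      hits$region[qh] <- S4Vectors::subjectHits(nearest)
      hits$distance[qh] <- S4Vectors::mcols(nearest)$distance
      hits$nearby <- !is.na(hits$distance) & hits$distance <= hit_dist_bp
    } else if (nrow(sig)) {
      hits <- data.frame(chrom = sig$chrom, pos = sig$pos,
                         wald_p = sig$wald_p, region = NA_integer_,
                         distance = NA_real_, nearby = FALSE,
                         stringsAsFactors = FALSE)
    } else {
      hits <- data.frame(chrom = character(0), pos = numeric(0),
                         wald_p = numeric(0), region = integer(0),
                         distance = numeric(0), nearby = logical(0),
                         stringsAsFactors = FALSE)
    }
  }
  list(regions = regions, hits = hits)
}

#' Write regions as a BED6 file
#'
#' @param regions data.frame(chrom, start, end, source, ...), 0-based
#'   half-open.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(regions)) {
    df <- data.frame(regions$chrom, as.integer(regions$start),
                     as.integer(regions$end),
                     paste0(regions$source, "_", seq_len(nrow(regions))),
                     0L, ".")
    writeLines(do.call(paste, c(df, sep = "\t")), con)
  }
  invisible(path)
}
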