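# Genomic interval arithmetic over plain data frames.
#
# Intervals are data.frames with columns chrom, start, end (0-based,
# half-open, the BED convention) and optionally name and strand. Strand is
# carried but ignored by all overlap operations: methylation counts are
# strand-combined upstream and ChIP fragments are unstranded.

#' Construct a genomic interval table
#'
#' Builds and validates the plain-data.frame interval representation used
#' throughout the package: 0-based, half-open coordinates (BED convention).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `start < end`, 0-based half-open.
#' @param name Optional identifiers; defaults to `iv_1 .. iv_n`.
#' @param strand Optional strand (`"+"`, `"-"` or `"."`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`
#'   (and `strand` if supplied).
#' @examples
#' genomic_intervals("chr1", 100, 250)
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, strand = NULL) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  x$name <- if (is.null(name)) sprintf("iv_%d", seq_len(nrow(x))) else as.character(name)
  if (!is.null(strand)) x$strand <- as.character(strand)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop_bad(what, " must be a data.frame with columns chrom, start, end")
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop_bad(what, ": chrom must be non-empty")
  if (any(is.na(x$start)) || any(is.na(x$end)) || any(x$start >= x$end))
    stop_bad(what, ": malformed interval (need start < end)")
  if (any(x$start < 0)) stop_bad(what, ": negative start position")
  invisible(x)
}

# convert 0-based half-open data.frame to GRanges (1-based closed) and back
as_granges <- function(x) {
  if (nrow(x) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

granges_to_df <- function(gr) {
  if (length(gr) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge overlapping and book-ended intervals
#'
#' Overlapping intervals on the same chromosome are collapsed into their
#' union. Book-ended intervals (one ending exactly where the next starts)
#' are also merged, matching the common merge-tool default. Output is
#' sorted and pairwise disjoint.
#'
#' @param intervals Interval data.frame (see [genomic_intervals()]).
#' @return Merged interval data.frame with fresh `name`s.
#' @examples
#' x <- genomic_intervals(c("chr1", "chr1"), c(100, 150), c(200, 250))
#' merge_intervals(x)
#' @export
merge_intervals <- function(intervals) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0L)
    return(genomic_intervals(character(), numeric(), numeric()))
  red <- GenomicRanges::reduce(as_granges(intervals))
  out <- granges_to_df(red)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  genomic_intervals(out$chrom, out$start, out$end)
}

#' Filter intervals against a blacklist and a chromosome whitelist
#'
#' Removes intervals overlapping any blacklist region by at least 1 bp and
#' intervals on disallowed chromosomes (e.g. restricting CGIs to autosomes
#' and dropping ENCODE blacklist regions before analysis).
#'
#' @param intervals Interval data.frame.
#' @param blacklist Optional interval data.frame of regions to exclude.
#' @param allowed_chroms Optional character vector; intervals on other
#'   chromosomes are dropped.
#' @return The retained subset of `intervals` (row order preserved).
#' @export
filter_intervals <- function(intervals, blacklist = NULL, allowed_chroms = NULL) {
  validate_intervals(intervals)
  keep <- rep(TRUE, nrow(intervals))
  if (!is.null(allowed_chroms))
    keep <- keep & intervals$chrom %in% allowed_chroms
  if (!is.null(blacklist) && nrow(blacklist) > 0L) {
    validate_intervals(blacklist, "blacklist")
    hits <- suppressWarnings(
      GenomicRanges::countOverlaps(as_granges(intervals), as_granges(blacklist)))
    keep <- keep & hits == 0L
  }
  intervals[keep, , drop = FALSE]
}

#' Construct gene models
#'
#' A gene model is one row per (gene, TSS, transcript) combination:
#' `gene_id`, `chrom`, `tss` (0-based position of the transcription start
#' site), `tx_start`, `tx_end` (0-based half-open transcript span) and
#' optional `strand`. A gene may contribute several rows (alternative TSSs).
#'
#' @param gene_id Character vector of gene identifiers.
#' @param chrom Chromosomes.
#' @param tss 0-based TSS positions; each must lie within its transcript.
#' @param tx_start,tx_end Transcript spans, 0-based half-open.
#' @param strand Optional strand.
#' @return A validated `data.frame` of gene models.
#' @export
gene_models <- function(gene_id, chrom, tss, tx_start, tx_end, strand = NULL) {
  g <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                  tss = as.numeric(tss), tx_start = as.numeric(tx_start),
                  tx_end = as.numeric(tx_end), stringsAsFactors = FALSE)
  if (!is.null(strand)) g$strand <- as.character(strand)
  if (any(g$tx_start >= g$tx_end)) stop_bad("gene models: need tx_start < tx_end")
  if (any(g$tss < g$tx_start | g$tss >= g$tx_end))
    stop_bad("gene models: every TSS must lie within its transcript span")
  g
}

tss_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(start = genes$tss + 1L, width = 1L))
}

tx_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(start = genes$tx_start + 1L, end = genes$tx_end))
}

#' Annotate CGIs relative to gene models
#'
#' Classifies each CGI as `TSS` if it overlaps any protein-coding TSS,
#' otherwise `gene_body` if it overlaps a transcript, otherwise
#' `intergenic`. The precedence makes the three categories exhaustive and
#' mutually exclusive.
#'
#' @param cgis Interval data.frame of CGIs.
#' @param genes Gene models from [gene_models()].
#' @return A data.frame with columns `cgi` (name), `category` and
#'   `assigned_genes` (comma-separated gene ids overlapped in the winning
#'   category; empty for intergenic).
#' @export
annotate_cgis <- function(cgis, genes) {
  validate_intervals(cgis, "cgis")
  if (is.null(genes) || nrow(genes) == 0L) stop_bad("gene models must be non-empty")
  cg <- as_granges(cgis)
  tss_hits <- suppressWarnings(GenomicRanges::findOverlaps(cg, tss_granges(genes)))
  tx_hits <- suppressWarnings(GenomicRanges::findOverlaps(cg, tx_granges(genes)))
  n <- nrow(cgis)
  category <- rep("intergenic", n)
  assigned <- character(n)
  at_tss <- unique(S4Vectors::queryHits(tss_hits))
  in_body <- setdiff(unique(S4Vectors::queryHits(tx_hits)), at_tss)
  category[at_tss] <- "TSS"
  category[in_body] <- "gene_body"
  for (i in at_tss) {
    g <- genes$gene_id[S4Vectors::subjectHits(tss_hits)[S4Vectors::queryHits(tss_hits) == i]]
    assigned[i] <- paste(sort(unique(g)), collapse = ",")
  }
  for (i in in_body) {
    g <- genes$gene_id[S4Vectors::subjectHits(tx_hits)[S4Vectors::queryHits(tx_hits) == i]]
    assigned[i] <- paste(sort(unique(g)), collapse = ",")
  }
  nm <- cgis$name %||% sprintf("cgi_%d", seq_len(n))
  data.frame(cgi = nm, category = category, assigned_genes = assigned,
             stringsAsFactors = FALSE)
}

#' Map CGIs to genes for enrichment analysis
#'
#' A CGI overlapping one or more TSSs is assigned to the genes of those
#' TSSs; failing that, to the gene(s) whose transcript contains it; failing
#' that, to the gene(s) with the closest TSS on the same chromosome
#' (distance measured from the nearest CGI edge to the TSS position; ties
#' at equal distance keep all tied genes). CGIs on chromosomes with no
#' genes are flagged unmapped.
#'
#' @inheritParams annotate_cgis
#' @return A named list mapping CGI name to a character vector of gene ids
#'   (`character(0)` for unmapped CGIs), with attribute `unmapped` listing
#'   CGIs on gene-free chromosomes.
#' @export
map_cgis_to_genes <- function(cgis, genes) {
  validate_intervals(cgis, "cgis")
  cg <- as_granges(cgis)
  tss_hits <- suppressWarnings(GenomicRanges::findOverlaps(cg, tss_granges(genes)))
  tx_hits <- suppressWarnings(GenomicRanges::findOverlaps(cg, tx_granges(genes)))
  n <- nrow(cgis)
  nm <- cgis$name %||% sprintf("cgi_%d", seq_len(n))
  out <- setNames(vector("list", n), nm)
  unmapped <- character()
  for (i in seq_len(n)) {
    g <- genes$gene_id[S4Vectors::subjectHits(tss_hits)[S4Vectors::queryHits(tss_hits) == i]]
    if (length(g) == 0L)
      g <- genes$gene_id[S4Vectors::subjectHits(tx_hits)[S4Vectors::queryHits(tx_hits) == i]]
    if (length(g) == 0L) {
      same <- genes[genes$chrom == cgis$chrom[i], , drop = FALSE]
      if (nrow(same) == 0L) {
        unmapped <- c(unmapped, nm[i])
        out[[i]] <- character(0)
        next
      }
      # distance from CGI edge to TSS position; 0 if TSS inside the CGI
      d <- pmax(same$tss - (cgis$end[i] - 1), cgis$start[i] - same$tss, 0)
      g <- same$gene_id[d == min(d)]
    }
    out[[i]] <- sort(unique(g))
  }
  attr(out, "unmapped") <- unmapped
  out
}

#' Overlap enrichment of a CGI subset in a peak set
#'
#' Tests whether CGIs in `target_set` overlap `feature_peaks` more often
#' than the background CGI universe, with Fisher's exact test on the 2x2
#' table (target vs rest) x (overlaps peak: yes/no). Fold enrichment is the
#' target overlap rate over the background overlap rate.
#'
#' @param target_set Interval data.frame; must be a subset of `background`
#'   (matched by chrom/start/end).
#' @param feature_peaks Interval data.frame of peaks.
#' @param background Interval data.frame: all CGIs under consideration.
#' @param sided `"greater"` (one-sided enrichment, the default) or
#'   `"two.sided"`.
#' @return A list with `fold_enrichment`, `odds_ratio`, `p_value` and the
#'   underlying `table`.
#' @export
overlap_enrichment <- function(target_set, feature_peaks, background,
                               sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  validate_intervals(background, "background")
  validate_intervals(target_set, "target_set")
  if (nrow(background) == 0L) stop_bad("background must be non-empty")
  key <- function(x) paste(x$chrom, x$start, x$end)
  if (!all(key(target_set) %in% key(background)))
    stop_bad("target_set must be a subset of background")
  in_target <- key(background) %in% key(target_set)
  ov <- suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(background), as_granges(feature_peaks))) > 0L
  a <- sum(in_target & ov); b <- sum(in_target & !ov)
  c_ <- sum(!in_target & ov); d <- sum(!in_target & !ov)
  rate_t <- a / (a + b)
  rate_bg <- sum(ov) / nrow(background)
  fold <- if (rate_bg == 0) NA_real_ else rate_t / rate_bg
  p <- fisher_p_2x2(a, b, c_, d, alternative = sided)
  list(fold_enrichment = fold,
       odds_ratio = odds_ratio_2x2(a, b, c_, d),
       p_value = p,
       table = matrix(c(a, b, c_, d), 2, 2,
                      dimnames = list(c("overlap", "no_overlap"),
                                      c("target", "rest"))))
}

#' Count fragments overlapping each region
#'
#' A fragment increments every region it overlaps by at least 1 bp.
#'
#' @param fragments Interval data.frame of reads/fragments.
#' @param regions Interval data.frame of regions (e.g. CGIs or windows).
#' @return Integer vector of counts, one per row of `regions`, named by
#'   region name when present.
#' @export
count_overlaps <- function(fragments, regions) {
  validate_intervals(regions, "regions")
  validate_intervals(fragments, "fragments")
  counts <- suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(regions), as_granges(fragments)))
  names(counts) <- regions$name %||% NULL
  counts
}

#' Tile fixed-size windows centred on a region midpoint
#'
#' Defines `n_windows` contiguous non-overlapping windows of `window_size`
#' bp centred on `floor((start + end) / 2)` of the region. With an even
#' number of windows the midpoint falls on the boundary between the two
#' central windows; with an odd number the middle window is centred on the
#' midpoint. Windows are truncated at position 0.
#'
#' @param region Single-row interval data.frame.
#' @param window_size Window width in bp (> 0).
#' @param n_windows Number of windows (>= 1).
#' @return Interval data.frame of windows, named `<region>_w<k>`.
#' @export
make_windows <- function(region, window_size, n_windows) {
  validate_intervals(region, "region")
  if (nrow(region) != 1L) stop_bad("make_windows expects a single region")
  if (window_size <= 0) stop_bad("window_size must be > 0")
  if (n_windows < 1) stop_bad("n_windows must be >= 1")
  mid <- floor((region$start + region$end) / 2)
  left <- if (n_windows %% 2 == 0) mid - (n_windows %/% 2) * window_size
          else mid - (n_windows %/% 2) * window_size - window_size %/% 2
  starts <- left + window_size * (seq_len(n_windows) - 1)
  ends <- starts + window_size
  starts <- pmax(starts, 0)
  keep <- starts < ends
  nm0 <- region$name %||% "region"
  genomic_intervals(rep(region$chrom, sum(keep)), starts[keep], ends[keep],
                    name = sprintf("%s_w%d", nm0, which(keep)))
}
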