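# Readers and writers for the plain-text formats the pipeline consumes:
# BED3/BED6, Bismark coverage files, gene-model TSVs, ontology edge TSVs.
# All writers emit deterministic, tab-separated output.

#' Read a BED3/BED6 file
#'
#' @param path Path to a tab-separated BED file (0-based half-open).
#' @return Interval data.frame with `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L)
    return(genomic_intervals(character(), numeric(), numeric()))
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#", quote = "")
  if (ncol(x) < 3L) stop_bad("BED file needs at least 3 columns: ", path)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- cols[seq_len(min(ncol(x), 6L))]
  if (is.null(x$name)) x$name <- sprintf("iv_%d", seq_len(nrow(x)))
  validate_intervals(x, path)
  x
}

#' Write intervals as BED
#'
#' @param intervals Interval data.frame.
#' @param path Output path.
#' @param score Optional score column (defaults to 0 when strand is written).
#' @export
write_bed <- function(intervals, path, score = NULL) {
  validate_intervals(intervals)
  cols <- list(intervals$chrom, format(intervals$start, scientific = FALSE, trim = TRUE),
               format(intervals$end, scientific = FALSE, trim = TRUE))
  if (!is.null(intervals$name)) {
    cols <- c(cols, list(intervals$name))
    if (!is.null(intervals$strand))
      cols <- c(cols, list(score %||% rep(0, nrow(intervals)), intervals$strand))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a Bismark-style coverage file for one sample
#'
#' The coverage dialect is six tab-separated columns: chrom, start, end,
#' percent methylation, count methylated, count unmethylated. On-disk
#' positions are 1-based inclusive by default (`zero_based = FALSE`); the
#' returned table keeps the 1-based CpG position in `pos`.
#'
#' @param path Input file.
#' @param sample Sample name attached to every row.
#' @param zero_based Set `TRUE` if the file uses 0-based half-open positions.
#' @return A CpG count table: `data.frame(chrom, pos, sample, meth, unmeth)`
#'   with `pos` 1-based. Rows with zero total coverage are rejected.
#' @export
read_bismark_cov <- function(path, sample = "sample1", zero_based = FALSE) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), pos = numeric(), sample = character(),
                      meth = numeric(), unmeth = numeric(), stringsAsFactors = FALSE))
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) != 6L)
    stop_bad("Bismark coverage file must have 6 columns, found ", ncol(x), ": ", path)
  names(x) <- c("chrom", "start", "end", "pct", "meth", "unmeth")
  if (any(x$meth < 0 | x$unmeth < 0)) stop_bad("negative counts in ", path)
  if (any(x$meth + x$unmeth == 0)) stop_bad("row with zero coverage in ", path)
  pos <- if (zero_based) x$start + 1 else x$start
  data.frame(chrom = x$chrom, pos = pos, sample = sample,
             meth = x$meth, unmeth = x$unmeth, stringsAsFactors = FALSE)
}

#' Write one sample of a CpG count table as a Bismark coverage file
#'
#' The percentage column is recomputed from counts, so a read/write
#' round trip is the identity up to float formatting of that column.
#'
#' @param table CpG count table (`chrom, pos, sample, meth, unmeth`).
#' @param path Output file.
#' @param sample Which sample to write (required if several are present).
#' @param zero_based Write 0-based half-open positions instead of 1-based.
#' @export
write_bismark_cov <- function(table, path, sample = NULL, zero_based = FALSE) {
  stopifnot(all(c("chrom", "pos", "sample", "meth", "unmeth") %in% names(table)))
  smp <- sample %||% unique(table$sample)
  if (length(smp) != 1L) stop_bad("specify one sample to write")
  x <- table[table$sample == smp, , drop = FALSE]
  start <- if (zero_based) x$pos - 1 else x$pos
  end <- if (zero_based) x$pos else x$pos
  pct <- 100 * x$meth / (x$meth + x$unmeth)
  writeLines(paste(x$chrom, format(start, scientific = FALSE, trim = TRUE),
                   format(end, scientific = FALSE, trim = TRUE),
                   formatC(pct, format = "f", digits = 6),
                   x$meth, x$unmeth, sep = "\t"), path)
  invisible(path)
}

#' Export per-CpG betas as bedGraph
#'
#' Writes one sample's per-CpG methylation proportion for CpGs at or above
#' a coverage threshold (default 5) as a 4-column bedGraph (0-based
#' half-open).
#'
#' @inheritParams write_bismark_cov
#' @param min_coverage Minimum total coverage for a CpG to be exported.
#' @export
export_betas_bedgraph <- function(table, path, sample = NULL, min_coverage = 5) {
  smp <- sample %||% unique(table$sample)
  if (length(smp) != 1L) stop_bad("specify one sample to export")
  x <- table[table$sample == smp, , drop = FALSE]
  x <- x[x$meth + x$unmeth >= min_coverage, , drop = FALSE]
  beta <- x$meth / (x$meth + x$unmeth)
  writeLines(paste(x$chrom, format(x$pos - 1, scientific = FALSE, trim = TRUE),
                   format(x$pos, scientific = FALSE, trim = TRUE),
                   formatC(beta, format = "f", digits = 6), sep = "\t"), path)
  invisible(path)
}

#' Read gene models from a TSV
#'
#' Expects a header line with columns `gene_id, chrom, tss, tx_start,
#' tx_end` and optionally `strand` (coordinates 0-based).
#'
#' @param path Input TSV.
#' @return Gene-model data.frame (see [gene_models()]).
#' @export
read_gene_models <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  gene_models(x$gene_id, x$chrom, x$tss, x$tx_start, x$tx_end, strand = x$strand)
}

#' Read an ontology edge list from a TSV
#'
#' Expects header columns `child, parent, relation` with relation one of
#' `is_a`, `part_of`.
#'
#' @param path Input TSV.
#' @return A [term_graph()].
#' @export
read_term_graph <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  term_graph(edges = x)
}

# deterministic TSV writer used for all tabular pipeline artifacts
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}
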