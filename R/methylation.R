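# CGI-level methylation quantification and differential gain calling.
#
# The CpG count table is long-format: one row per (CpG, sample) with 1-based
# CpG position and methylated/unmethylated read counts, as produced by
# read_bismark_cov() or simulate_cpg_counts().

cpg_key <- function(table) paste(table$chrom, table$pos)

#' Filter CpGs by minimum coverage in every sample
#'
#' Retains only CpGs whose total coverage (methylated + unmethylated reads)
#' is at least `min_coverage` in every listed sample. A CpG absent from one
#' of the samples counts as coverage 0 there and is removed. The default
#' threshold of 10 reads is the standard inclusion rule for CGI-level
#' analyses of RRBS data.
#'
#' @param table CpG count table (`chrom, pos, sample, meth, unmeth`).
#' @param min_coverage Minimum per-sample coverage (>= 1), boundary inclusive.
#' @param samples Samples that must all pass; default: all samples in `table`.
#' @return The filtered CpG count table (all samples kept for passing CpGs).
#' @export
filter_cpgs <- function(table, min_coverage = 10, samples = NULL) {
  if (min_coverage < 1) stop_bad("min_coverage must be >= 1")
  all_smp <- unique(table$sample)
  samples <- samples %||% all_smp
  if (!all(samples %in% all_smp))
    stop_bad("unknown sample(s): ", paste(setdiff(samples, all_smp), collapse = ", "))
  if (nrow(table) == 0L) return(table)
  keys <- unique(cpg_key(table))
  pass <- rep(TRUE, length(keys))
  names(pass) <- keys
  for (s in samples) {
    sub <- table[table$sample == s, , drop = FALSE]
    cov <- sub$meth + sub$unmeth
    covered <- setNames(rep(0, length(keys)), keys)
    covered[cpg_key(sub)] <- cov
    pass <- pass & covered >= min_coverage
  }
  table[pass[cpg_key(table)], , drop = FALSE]
}

#' Coverage-weighted CGI methylation
#'
#' For each CGI and sample, pools methylated and unmethylated read counts
#' over the CpGs contained in the CGI and reports the coverage-weighted
#' mean methylation: pooled methylated reads / pooled total reads. CGIs
#' containing no usable CpG are reported with `NA` (missing, not zero).
#'
#' @param table CpG count table, already coverage-filtered as desired.
#' @param cgis Interval data.frame of CGIs (0-based half-open) with `name`.
#' @return A CGI methylation table:
#'   `data.frame(cgi, sample, weighted_mean, n_cpgs, pooled_meth,
#'   pooled_unmeth)`, one row per CGI x sample.
#' @export
cgi_weighted_methylation <- function(table, cgis) {
  validate_intervals(cgis, "cgis")
  nm <- cgis$name %||% sprintf("cgi_%d", seq_len(nrow(cgis)))
  samples <- unique(table$sample)
  if (length(samples) == 0L) samples <- "sample1"
  # CpG pos is 1-based; containment in 0-based half-open CGI: start < pos <= end
  grid <- expand.grid(cgi = nm, sample = samples, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$weighted_mean <- NA_real_
  grid$n_cpgs <- 0L
  grid$pooled_meth <- 0
  grid$pooled_unmeth <- 0
  if (nrow(table) > 0L) {
    cpg_gr <- GenomicRanges::GRanges(table$chrom,
                                     IRanges::IRanges(start = table$pos, width = 1L))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(cpg_gr, as_granges(cgis)))
    if (length(hits) > 0L) {
      idx <- S4Vectors::queryHits(hits)
      cgi_of <- nm[S4Vectors::subjectHits(hits)]
      f <- paste(cgi_of, table$sample[idx], sep = "\r")
      pm <- tapply(table$meth[idx], f, sum)
      pu <- tapply(table$unmeth[idx], f, sum)
      nn <- tapply(table$meth[idx], f, length)
      key_grid <- paste(grid$cgi, grid$sample, sep = "\r")
      m <- match(key_grid, names(pm))
      found <- !is.na(m)
      grid$pooled_meth[found] <- as.numeric(pm[m[found]])
      grid$pooled_unmeth[found] <- as.numeric(pu[m[found]])
      grid$n_cpgs[found] <- as.integer(nn[m[found]])
      tot <- grid$pooled_meth + grid$pooled_unmeth
      grid$weighted_mean[found] <- grid$pooled_meth[found] / tot[found]
    }
  }
  grid
}

pool_condition <- function(meth) {
  # sum pooled counts across samples (replicate libraries) per CGI
  pm <- tapply(meth$pooled_meth, meth$cgi, sum)
  pu <- tapply(meth$pooled_unmeth, meth$cgi, sum)
  data.frame(cgi = names(pm), pooled_meth = as.numeric(pm),
             pooled_unmeth = as.numeric(pu), stringsAsFactors = FALSE)
}

#' Call CGIs significantly gaining methylation between two conditions
#'
#' For each CGI present in both conditions, a two-sided Fisher's exact test
#' is applied to the 2x2 table of pooled (methylated, unmethylated) read
#' counts by condition; p-values are Benjamini-Hochberg adjusted across all
#' tested CGIs. A CGI is called a gainer when its adjusted p-value is below
#' `fdr` and its methylation increased by at least `min_gain` (boundary
#' inclusive: a gain of exactly 20 percentage points qualifies).
#'
#' @param meth_a,meth_b CGI methylation tables (see
#'   [cgi_weighted_methylation()]) for conditions A (reference) and B.
#'   Multiple samples per condition are pooled at the count level.
#' @param min_gain Minimum methylation gain (delta beta), default 0.20.
#' @param fdr Adjusted-p threshold, default 0.05 (strict inequality).
#' @return A `gain_calls` data.frame: `cgi, beta_a, beta_b, delta_beta,
#'   p_value, q_value, is_gainer`, with attribute `excluded` naming CGIs
#'   untestable in one of the conditions.
#' @export
call_methylation_gain <- function(meth_a, meth_b, min_gain = 0.20, fdr = 0.05) {
  check_prob(min_gain, "min_gain"); check_prob(fdr, "fdr")
  a <- pool_condition(meth_a)
  b <- pool_condition(meth_b)
  shared <- intersect(a$cgi, b$cgi)
  a <- a[match(shared, a$cgi), , drop = FALSE]
  b <- b[match(shared, b$cgi), , drop = FALSE]
  tot_a <- a$pooled_meth + a$pooled_unmeth
  tot_b <- b$pooled_meth + b$pooled_unmeth
  testable <- tot_a > 0 & tot_b > 0
  excluded <- c(setdiff(union(unique(meth_a$cgi), unique(meth_b$cgi)), shared),
                shared[!testable])
  a <- a[testable, , drop = FALSE]; b <- b[testable, , drop = FALSE]
  beta_a <- a$pooled_meth / (a$pooled_meth + a$pooled_unmeth)
  beta_b <- b$pooled_meth / (b$pooled_meth + b$pooled_unmeth)
  p <- fisher_p_2x2(a$pooled_meth, a$pooled_unmeth,
                    b$pooled_meth, b$pooled_unmeth, alternative = "two.sided")
  q <- benjamini_hochberg(p)
  delta <- beta_b - beta_a
  out <- data.frame(cgi = a$cgi, beta_a = beta_a, beta_b = beta_b,
                    delta_beta = delta, p_value = p, q_value = q,
                    is_gainer = q < fdr & delta >= min_gain,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  class(out) <- c("gain_calls", "data.frame")
  out
}

#' @export
print.gain_calls <- function(x, ...) {
  cat("CGI methylation gain calls\n")
  cat(sprintf("  %d CGIs tested, %d gainers (q < threshold and delta >= min gain)\n",
              nrow(x), sum(x$is_gainer)))
  excl <- attr(x, "excluded")
  if (length(excl)) cat(sprintf("  %d CGIs excluded (untestable in one condition)\n",
                                length(excl)))
  NextMethod()
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, order-preserving),
#' delegating to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  check_prob(p_values, "p_values")
  p.adjust(p_values, method = "BH")
}

#' Threshold-based methylation calls from a beta matrix
#'
#' Flags a CGI as methylated in a sample when its beta is at or above
#' `threshold` (boundary inclusive: beta = 0.3 is methylated at the default
#' threshold). The per-CGI frequency is the fraction of flagged samples
#' among samples with a non-missing beta.
#'
#' @param beta_matrix Numeric matrix, CGIs x samples, entries in \[0, 1\] or
#'   `NA`.
#' @param threshold Methylation call threshold, default 0.3.
#' @return A list with `flags` (logical matrix, `NA` preserved) and
#'   `frequency` (per-CGI numeric vector).
#' @export
call_methylated_by_beta <- function(beta_matrix, threshold = 0.3) {
  beta_matrix <- as.matrix(beta_matrix)
  check_prob(beta_matrix[!is.na(beta_matrix)], "beta_matrix")
  flags <- beta_matrix >= threshold
  freq <- apply(flags, 1, function(r) {
    ok <- !is.na(r)
    if (!any(ok)) NA_real_ else sum(r[ok]) / sum(ok)
  })
  list(flags = flags, frequency = freq)
}

#' Summarise bisulfite-sequenced clones
#'
#' Clones with a sequencing-error fraction at or above `max_error_fraction`
#' (default 25%, boundary inclusive) are excluded. For retained clones, the
#' per-clone mean methylation is computed over readable (non-error)
#' positions, along with per-CpG column means across clones.
#'
#' @param clones Matrix (clones x CpG positions) with entries 1
#'   (methylated), 0 (unmethylated) or `NA` (sequencing error / missing).
#' @param max_error_fraction Exclusion threshold on the per-clone fraction
#'   of `NA` positions.
#' @return A list with `clone_means` (named vector over retained clones),
#'   `cpg_means` (column means over retained clones) and `excluded`
#'   (names of dropped clones).
#' @export
summarise_clones <- function(clones, max_error_fraction = 0.25) {
  clones <- as.matrix(clones)
  if (is.null(rownames(clones))) rownames(clones) <- sprintf("clone_%d", seq_len(nrow(clones)))
  err <- rowMeans(is.na(clones))
  drop <- err >= max_error_fraction
  if (any(rowMeans(is.na(clones)) == 1))
    warning("clone(s) with no readable positions excluded")
  kept <- clones[!drop, , drop = FALSE]
  clone_means <- rowMeans(kept, na.rm = TRUE)
  cpg_means <- if (nrow(kept)) colMeans(kept, na.rm = TRUE) else
    setNames(rep(NA_real_, ncol(clones)), colnames(clones))
  list(clone_means = clone_means, cpg_means = cpg_means,
       excluded = rownames(clones)[drop])
}

#' Global 5-methylcytosine percentage from mass-spectrometry peak areas
#'
#' The percent 5mC is the ratio of the area under the 5-methylcytosine peak
#' to the area under the guanine peak, times 100.
#'
#' @param area_5mC,area_G Peak areas; `area_G` must be positive.
#' @return Percent 5mC.
#' @export
mass_spec_5mc_percent <- function(area_5mC, area_G) {
  if (any(area_G <= 0)) stop_bad("area_G must be > 0")
  if (any(area_5mC < 0)) stop_bad("areas must be >= 0")
  100 * area_5mC / area_G
}
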