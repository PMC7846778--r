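# ChIP signal quantification at CGIs/windows, input-corrected spike-in
# (ChIP-Rx) scaling, decile association and qPCR percent-input.

#' Construct a ChIP sample count object
#'
#' Holds per-region read/fragment counts for one sequencing run together
#' with its mapped-read totals for the target genome and, for ChIP-Rx, the
#' spike-in genome.
#'
#' @param sample_id Sample identifier.
#' @param role `"ChIP"` or `"input"`.
#' @param counts Named numeric vector of per-region raw counts.
#' @param target_total Total reads mapped to the target genome (> 0).
#' @param spikein_total Total reads mapped to the spike-in genome (0 if no
#'   spike-in was used; must be > 0 for Rx scaling).
#' @return An object of class `chip_sample`.
#' @export
chip_sample <- function(sample_id, role = c("ChIP", "input"), counts,
                        target_total, spikein_total = 0) {
  role <- match.arg(role)
  if (is.null(names(counts))) stop_bad("counts must be named by region")
  if (any(counts < 0)) stop_bad("counts must be non-negative")
  if (target_total <= 0) stop_bad("target_total must be > 0")
  structure(list(sample_id = sample_id, role = role, counts = counts,
                 target_total = target_total, spikein_total = spikein_total),
            class = "chip_sample")
}

#' @export
print.chip_sample <- function(x, ...) {
  cat(sprintf("ChIP sample '%s' (%s): %d regions, %g target reads, %g spike-in reads\n",
              x$sample_id, x$role, length(x$counts), x$target_total, x$spikein_total))
  invisible(x)
}

mapped_total <- function(x, denominator = c("all", "target")) {
  denominator <- match.arg(denominator)
  if (denominator == "all") x$target_total + x$spikein_total else x$target_total
}

#' Drop regions uncovered in every sample
#'
#' Regions with zero coverage in all supplied samples are removed from the
#' analysis before normalisation.
#'
#' @param samples List of [chip_sample()] objects over the same regions.
#' @return Character vector of region names covered in at least one sample.
#' @export
covered_regions <- function(samples) {
  regs <- names(samples[[1]]$counts)
  for (s in samples) stopifnot(identical(names(s$counts), regs))
  tot <- Reduce(`+`, lapply(samples, function(s) s$counts))
  regs[tot > 0]
}

#' Input-normalised scaled ChIP signal
#'
#' Adds a 0.5 offset to every region count (so that regions with zero input
#' reads cannot produce an infinite ratio), scales ChIP and input counts to
#' counts per 10 million mapped reads of their respective runs, and divides
#' ChIP by input:
#' `[(count_ChIP + 0.5) * 1e7 / total_ChIP] / [(count_input + 0.5) * 1e7 / total_input]`.
#'
#' @param chip,input [chip_sample()] objects over the same regions.
#' @param offset Pseudocount added to every region (default 0.5).
#' @param regions Optional region subset (e.g. from [covered_regions()]).
#' @param denominator `"all"`: scale by total mapped reads including
#'   spike-in (default); `"target"`: target-genome reads only.
#' @return An object of class `normalised_signal`: named numeric vector of
#'   strictly positive per-region values, with the sample id, offset and
#'   scale basis as attributes.
#' @export
normalised_signal <- function(chip, input, offset = 0.5, regions = NULL,
                              denominator = c("all", "target")) {
  denominator <- match.arg(denominator)
  if (!identical(names(chip$counts), names(input$counts)))
    stop_bad("ChIP and input must cover identical regions")
  regs <- regions %||% names(chip$counts)
  cc <- chip$counts[regs]; ic <- input$counts[regs]
  num <- (cc + offset) * 1e7 / mapped_total(chip, denominator)
  den <- (ic + offset) * 1e7 / mapped_total(input, denominator)
  structure(num / den, class = "normalised_signal",
            sample_id = chip$sample_id, offset = offset, scale_basis = 1e7)
}

#' Spike-in (ChIP-Rx) scaling factors with input correction
#'
#' For each sample n, the spike-in reads of the ChIP and input runs are
#' expressed per 10 million mapped reads of their run (dRPTM, the spike-in
#' representation). The scaling factor versus the reference is
#' `S_n = (dRPTM_ChIP-n / dRPTM_ChIP-ref) / (dRPTM_IN-n / dRPTM_IN-ref)`,
#' so `S_ref = 1` exactly. `S_n` measures how over-represented the spike-in
#' is in sample n's ChIP relative to the reference after input correction;
#' a genuine global gain of target signal in sample n yields `S_n < 1`.
#' [apply_rx_scaling()] therefore divides sample n's normalised signal by
#' `S_n` to place samples on a common quantitative scale.
#'
#' @param samples Named list; each element a list with components `chip`
#'   and `input`, both [chip_sample()] objects with positive spike-in
#'   totals.
#' @param reference Name of the reference sample.
#' @param denominator Mapped-read denominator for dRPTM (see
#'   [normalised_signal()]).
#' @return An `rx_scaling` data.frame `(sample, drptm_chip, drptm_input,
#'   factor)` with attribute `reference`.
#' @export
rx_scaling_factor <- function(samples, reference, denominator = c("all", "target")) {
  denominator <- match.arg(denominator)
  if (!reference %in% names(samples)) stop_bad("reference sample not found")
  for (nm in names(samples)) {
    pair <- samples[[nm]]
    if (is.null(pair$chip) || is.null(pair$input))
      stop_bad("sample '", nm, "' is missing its ChIP or input run")
    if (pair$chip$spikein_total <= 0 || pair$input$spikein_total <= 0)
      stop_bad("sample '", nm, "' has no spike-in reads in ChIP or input run")
  }
  drptm <- function(x) x$spikein_total * 1e7 / mapped_total(x, denominator)
  dc <- vapply(samples, function(p) drptm(p$chip), numeric(1))
  di <- vapply(samples, function(p) drptm(p$input), numeric(1))
  s <- (dc / dc[[reference]]) / (di / di[[reference]])
  s[[reference]] <- 1  # exact by construction
  out <- data.frame(sample = names(samples), drptm_chip = unname(dc),
                    drptm_input = unname(di), factor = unname(s),
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- reference
  class(out) <- c("rx_scaling", "data.frame")
  out
}

#' Apply spike-in scaling to a normalised signal
#'
#' Rescales one sample's input-normalised signal by its spike-in factor
#' (division by `S_n`; the reference sample is unchanged). Replicates are
#' averaged after scaling: `rx_replicate_mean()` below.
#'
#' @param signal A [normalised_signal()] vector.
#' @param scaling An `rx_scaling` table from [rx_scaling_factor()].
#' @param sample Sample id; defaults to the signal's own id.
#' @return The rescaled `normalised_signal`.
#' @export
apply_rx_scaling <- function(signal, scaling, sample = NULL) {
  sample <- sample %||% attr(signal, "sample_id")
  i <- match(sample, scaling$sample)
  if (is.na(i)) stop_bad("no scaling factor for sample '", sample, "'")
  out <- unclass(signal) / scaling$factor[i]
  attributes(out) <- attributes(signal)
  out
}

#' Mean of replicate signals after scaling
#'
#' @param signals List of (already scaled) `normalised_signal` vectors over
#'   identical regions.
#' @return Named numeric vector of per-region replicate means.
#' @export
rx_replicate_mean <- function(signals) {
  regs <- names(signals[[1]])
  for (s in signals) stopifnot(identical(names(s), regs))
  Reduce(`+`, lapply(signals, unclass)) / length(signals)
}

#' Decile (rank-group) association between a ChIP signal and a response
#'
#' Ranks CGIs by `signal`, splits them into `n_groups` equal-sized groups
#' (any remainder spread over the lowest groups), summarises the response
#' per group (median and quartiles, for boxplot-style display), and
#' computes the Spearman correlation over the individual CGIs (not the
#' group summaries).
#'
#' @param signal Numeric per-CGI signal (e.g. H3K36me3 level), named or not.
#' @param response Numeric per-CGI response (e.g. methylation gain or
#'   DNMT3B level), same length and order.
#' @param n_groups Number of rank groups (default 10).
#' @return An object of class `decile_association`: list with `group`
#'   (integer assignment per CGI, 1 = lowest signal), `summary` (per-group
#'   n, median, q25, q75), `spearman_rho` and `p_value`.
#' @export
decile_association <- function(signal, response, n_groups = 10) {
  if (length(signal) != length(response)) stop_bad("signal and response lengths differ")
  n <- length(signal)
  if (n < n_groups) stop_bad("need at least n_groups observations")
  if (length(unique(signal)) < n_groups)
    warning("heavy ties in signal; rank groups may be arbitrary within ties")
  r <- rank(signal, ties.method = "first")
  base <- n %/% n_groups; rem <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, rem), rep(0L, n_groups - rem))
  grp <- rep(seq_len(n_groups), times = sizes)[r]
  summ <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    y <- response[grp == g]
    data.frame(group = g, n = length(y), median = median(y),
               q25 = unname(quantile(y, 0.25)), q75 = unname(quantile(y, 0.75)))
  }))
  ct <- suppressWarnings(cor.test(signal, response, method = "spearman",
                                  exact = FALSE))
  structure(list(group = grp, summary = summ,
                 spearman_rho = unname(ct$estimate), p_value = ct$p.value),
            class = "decile_association")
}

#' @export
print.decile_association <- function(x, ...) {
  cat(sprintf("Rank-group association (%d groups): Spearman rho = %.3f, p = %.3g\n",
              nrow(x$summary), x$spearman_rho, x$p_value))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Linear model of a ChIP response on histone-mark levels
#'
#' Ordinary least squares with intercept, predictors standardised
#' (z-scored) so coefficients are directly comparable across marks (e.g.
#' predicting DNMT3B occupancy at CGIs from histone modification levels).
#'
#' @param response Numeric per-CGI response.
#' @param predictors data.frame or matrix of per-CGI predictor levels; no
#'   predictor may be constant.
#' @param condition_limit Condition-number threshold above which
#'   predictors are flagged collinear.
#' @return Object of class `histone_model`: `coefficients` table (estimate,
#'   std. error, t, p per standardised predictor), `r_squared`,
#'   `condition_number`, `collinear` flag and the underlying `lm` fit.
#' @export
fit_histone_model <- function(response, predictors, condition_limit = 30) {
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != length(response)) stop_bad("dimension mismatch")
  if (length(response) <= ncol(predictors))
    stop_bad("need more observations than predictors")
  sds <- vapply(predictors, sd, numeric(1))
  if (any(sds == 0))
    stop_bad("constant predictor(s): ",
             paste(names(predictors)[sds == 0], collapse = ", "))
  z <- as.data.frame(scale(predictors))
  fit <- lm(response ~ ., data = cbind(response = response, z))
  ct <- summary(fit)$coefficients
  kappa_x <- kappa(cbind(1, as.matrix(z)), exact = TRUE)
  structure(list(
    coefficients = data.frame(term = rownames(ct), estimate = ct[, 1],
                              std_error = ct[, 2], t_value = ct[, 3],
                              p_value = ct[, 4], row.names = NULL,
                              stringsAsFactors = FALSE),
    r_squared = summary(fit)$r.squared,
    condition_number = kappa_x,
    collinear = kappa_x > condition_limit,
    fit = fit), class = "histone_model")
}

#' @export
print.histone_model <- function(x, ...) {
  cat(sprintf("Histone-mark linear model: R^2 = %.3f, condition number = %.1f%s\n",
              x$r_squared, x$condition_number,
              if (x$collinear) " (collinear predictors flagged)" else ""))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' qPCR ChIP enrichment as percent of input
#'
#' The input Ct is first adjusted to represent 100% of the chromatin
#' (subtracting `log2(1 / input_fraction)` cycles); enrichment assuming a
#' primer efficiency of 2 is then `100 * 2^(adjusted input Ct - IP Ct)`.
#'
#' @param ct_ip IP Ct value(s).
#' @param ct_input Input Ct value(s).
#' @param input_fraction Fraction of chromatin retained as input, in (0, 1].
#' @return Percent of input recovered.
#' @export
qpcr_percent_input <- function(ct_ip, ct_input, input_fraction) {
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stop_bad("input_fraction must be in (0, 1]")
  adj <- ct_input - log2(1 / input_fraction)
  100 * 2^(adj - ct_ip)
}

#' Region x window signal matrix with heatmap display range
#'
#' Assembles per-window normalised signals into a regions-by-windows matrix
#' and records a display range from the minimum to the `cap_quantile`
#' quantile (default 90%, linear interpolation between order statistics).
#' Values themselves are not truncated; the cap is display metadata. Rows
#' can be ordered by mean signal (ties broken by region id, so the order is
#' deterministic).
#'
#' @param values Numeric matrix, regions x windows, with rownames.
#' @param cap_quantile Upper display quantile.
#' @param order_rows Sort rows by decreasing mean signal.
#' @return List with `matrix`, `display_min`, `display_max` and
#'   `degenerate` (TRUE when all values are equal).
#' @export
heatmap_matrix <- function(values, cap_quantile = 0.9, order_rows = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("r%d", seq_len(nrow(values)))
  if (order_rows) {
    mu <- rowMeans(values)
    values <- values[order(-mu, rownames(values)), , drop = FALSE]
  }
  lo <- min(values); hi <- unname(quantile(values, cap_quantile, type = 7))
  degenerate <- lo == hi
  if (degenerate) warning("degenerate display range: all values equal")
  list(matrix = values, display_min = lo, display_max = hi, degenerate = degenerate)
}
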