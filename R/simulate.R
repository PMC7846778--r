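# Synthetic-data generators with known ground truth.
#
# Every generator is a pure function of (config, seed): the caller's RNG
# state is saved and restored, and identical configs reproduce identical
# output. The generators emulate the statistical structure of the real
# inputs (per-CpG binomial bisulfite counts at controlled CGI-level betas,
# re-methylation trajectories under an outgrowth-null or heterogeneous-rate
# regime, spike-in ChIP read counts with a covariate coupled to the signal)
# without any sequence-level simulation.

#' Configuration for the bisulfite count simulator
#'
#' Baseline CGI methylation is drawn from a two-mode Beta mixture (a
#' mostly-unmethylated and a mostly-methylated mode), matching the bimodal
#' CGI methylation landscape of somatic cells. A fraction of CGIs
#' ("gainers") has its condition-B methylation raised by `gain_size`;
#' gainers are drawn only among CGIs whose baseline leaves room for the
#' gain inside \[0, 1\].
#'
#' @param n_cgis Number of CGIs.
#' @param cpgs_per_cgi CpGs per CGI: a single count or a `c(min, max)`
#'   range sampled uniformly.
#' @param coverage_mean Mean per-CpG read coverage; coverage is Poisson
#'   with this mean, truncated at >= 1.
#' @param baseline_low,baseline_high Means of the low/high baseline-beta
#'   modes.
#' @param prop_high Proportion of CGIs in the high mode.
#' @param beta_concentration Concentration of the Beta draws around each
#'   mode (larger = tighter).
#' @param gainer_fraction Fraction of CGIs gaining methylation in
#'   condition B.
#' @param gain_size Methylation gain (delta beta) of gainer CGIs.
#' @param seed RNG seed.
#' @return A validated config list of class `meth_sim_config`.
#' @export
meth_sim_config <- function(n_cgis = 500, cpgs_per_cgi = c(8, 15),
                            coverage_mean = 30, baseline_low = 0.1,
                            baseline_high = 0.8, prop_high = 0.25,
                            beta_concentration = 60, gainer_fraction = 0.2,
                            gain_size = 0.5, seed = 1) {
  check_prob(c(baseline_low, baseline_high, prop_high), "baseline parameters")
  check_prob(gainer_fraction, "gainer_fraction")
  check_prob(gain_size, "gain_size")
  if (coverage_mean <= 0) stop_bad("coverage_mean must be > 0")
  if (n_cgis < 1) stop_bad("n_cgis must be >= 1")
  if (any(cpgs_per_cgi < 1) || any(cpgs_per_cgi != round(cpgs_per_cgi)))
    stop_bad("cpgs_per_cgi must be positive integer count(s)")
  structure(list(n_cgis = n_cgis, cpgs_per_cgi = cpgs_per_cgi,
                 coverage_mean = coverage_mean, baseline_low = baseline_low,
                 baseline_high = baseline_high, prop_high = prop_high,
                 beta_concentration = beta_concentration,
                 gainer_fraction = gainer_fraction, gain_size = gain_size,
                 seed = seed), class = "meth_sim_config")
}

rpois_pos <- function(n, lambda) {
  # Poisson truncated at >= 1 by inverse-CDF on U(P(0), 1)
  u <- runif(n, min = exp(-lambda), max = 1)
  stats::qpois(u, lambda)
}

rbeta_mode <- function(n, mean, conc) {
  rbeta(n, shape1 = mean * conc, shape2 = (1 - mean) * conc)
}

#' Simulate per-CpG bisulfite counts for two conditions
#'
#' Generates a CGI interval set and, for each CpG, methylated counts
#' distributed Binomial(coverage, beta of its CGI in that condition), with
#' truncated-Poisson coverage. Condition A is the baseline; in condition B
#' the gainer CGIs have `beta_B = beta_A + gain_size`.
#'
#' @param cfg A [meth_sim_config()].
#' @return A list with `table_a`, `table_b` (long CpG count tables with
#'   sample names `"A"`, `"B"`), `cgis` (interval data.frame) and `truth`
#'   (`data.frame(cgi, beta_a, beta_b, gainer)`).
#' @export
simulate_cpg_counts <- function(cfg) {
  stopifnot(inherits(cfg, "meth_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_cgis
    n_cpg <- if (length(cfg$cpgs_per_cgi) == 1L) rep(cfg$cpgs_per_cgi, n)
             else sample(seq(cfg$cpgs_per_cgi[1], cfg$cpgs_per_cgi[2]), n, replace = TRUE)
    high <- runif(n) < cfg$prop_high
    beta_a <- ifelse(high,
                     rbeta_mode(n, cfg$baseline_high, cfg$beta_concentration),
                     rbeta_mode(n, cfg$baseline_low, cfg$beta_concentration))
    eligible <- which(beta_a + cfg$gain_size <= 1)
    n_gain <- round(cfg$gainer_fraction * n)
    if (n_gain > length(eligible))
      stop_bad("gain_size pushes beta outside [0, 1] for too many CGIs; ",
               "lower gainer_fraction, gain_size or prop_high")
    gainer <- rep(FALSE, n)
    gainer[sample(eligible, n_gain)] <- TRUE
    beta_b <- beta_a + ifelse(gainer, cfg$gain_size, 0)

    # genomic layout: CGIs tiled across autosomes, CpGs every 50 bp
    chrom <- sprintf("chr%d", ((seq_len(n) - 1L) %% 22L) + 1L)
    idx_on_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
    start <- 10000 * idx_on_chrom
    end <- start + 50 * n_cpg + 10
    cgis <- genomic_intervals(chrom, start, end, name = sprintf("cgi_%04d", seq_len(n)))

    one_condition <- function(beta, sample_name) {
      rows <- lapply(seq_len(n), function(i) {
        pos <- start[i] + 50 * seq_len(n_cpg[i]) - 25  # 1-based, inside the CGI
        cov <- rpois_pos(n_cpg[i], cfg$coverage_mean)
        meth <- rbinom(n_cpg[i], cov, beta[i])
        data.frame(chrom = chrom[i], pos = pos, sample = sample_name,
                   meth = meth, unmeth = cov - meth, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    table_a <- one_condition(beta_a, "A")
    table_b <- one_condition(beta_b, "B")
    list(table_a = table_a, table_b = table_b, cgis = cgis,
         truth = data.frame(cgi = cgis$name, beta_a = beta_a, beta_b = beta_b,
                            gainer = gainer, stringsAsFactors = FALSE))
  })
}

#' Configuration for the re-methylation time-course simulator
#'
#' Day-0 methylation is drawn uniformly on `day0_range` (above the >50%
#' inclusion threshold by default). The normalised trajectory of CGI c is
#' `baseline_recovery + s_c * (t - t_anchor)` from the first post-treatment
#' day onwards; under the `outgrowth_null` regime every CGI shares the
#' common slope `mean_rate` (and `rate_sd`/`intercept_sd` must be 0), while
#' under `heterogeneous` per-CGI slopes are Gaussian
#' `N(mean_rate, rate_sd)` with optional group rate offsets. Gaussian
#' observation noise (`noise_sd`, methylation units on the raw beta scale)
#' is added to post-day-0 measurements, and raw trajectories are clipped
#' to \[0, 1\].
#'
#' @param timepoints Ordered days, including 0 and at least three points
#'   within \[3, 22\].
#' @param n_cgis Number of CGIs.
#' @param day0_range Range of day-0 methylation (uniform draw).
#' @param regime `"outgrowth_null"` or `"heterogeneous"`.
#' @param mean_rate Mean recovery rate, fraction of day-0 methylation per
#'   day.
#' @param rate_sd SD of per-CGI rates (0 under the null regime).
#' @param intercept_sd SD of per-CGI normalised baselines (0 under null).
#' @param noise_sd Observation noise SD on the beta scale.
#' @param baseline_recovery Normalised methylation at `t_anchor`.
#' @param t_anchor Day at which `baseline_recovery` applies (default 3,
#'   the first post-treatment measurement).
#' @param group_offsets Optional named numeric of additive rate offsets;
#'   CGIs are assigned to the named groups uniformly at random.
#' @param seed RNG seed.
#' @return A validated config list of class `kinetics_sim_config`.
#' @export
kinetics_sim_config <- function(timepoints = c(0, 3, 6, 10, 14, 18, 22),
                                n_cgis = 200, day0_range = c(0.55, 0.95),
                                regime = c("heterogeneous", "outgrowth_null"),
                                mean_rate = 0.03, rate_sd = 0.01,
                                intercept_sd = 0.02, noise_sd = 0.02,
                                baseline_recovery = 0.2, t_anchor = 3,
                                group_offsets = NULL, seed = 1) {
  regime <- match.arg(regime)
  if (is.unsorted(timepoints, strictly = TRUE)) stop_bad("timepoints must be sorted")
  if (!0 %in% timepoints) stop_bad("timepoints must include day 0")
  if (sum(timepoints >= 3 & timepoints <= 22) < 3)
    stop_bad("need at least 3 timepoints in [3, 22]")
  if (rate_sd < 0 || noise_sd < 0 || intercept_sd < 0) stop_bad("SDs must be >= 0")
  if (regime == "outgrowth_null" && (rate_sd > 0 || intercept_sd > 0))
    stop_bad("outgrowth_null forces rate_sd = 0 and intercept_sd = 0")
  check_prob(day0_range, "day0_range")
  structure(list(timepoints = timepoints, n_cgis = n_cgis,
                 day0_range = day0_range, regime = regime,
                 mean_rate = mean_rate, rate_sd = rate_sd,
                 intercept_sd = intercept_sd, noise_sd = noise_sd,
                 baseline_recovery = baseline_recovery, t_anchor = t_anchor,
                 group_offsets = group_offsets, seed = seed),
            class = "kinetics_sim_config")
}

#' Simulate a 5-aza-dC re-methylation time course
#'
#' @param cfg A [kinetics_sim_config()].
#' @return A list with `tc` (a [timecourse_table()]) and `truth`
#'   (`data.frame(cgi, day0, slope, intercept, group)`, where `slope` is
#'   the true per-CGI rate on the normalised scale).
#' @export
simulate_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "kinetics_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_cgis
    ids <- sprintf("cgi_%04d", seq_len(n))
    day0 <- runif(n, cfg$day0_range[1], cfg$day0_range[2])
    group <- rep(NA_character_, n)
    offs <- rep(0, n)
    if (!is.null(cfg$group_offsets)) {
      group <- sample(names(cfg$group_offsets), n, replace = TRUE)
      offs <- unname(cfg$group_offsets[group])
    }
    slope <- cfg$mean_rate + offs +
      if (cfg$regime == "heterogeneous") rnorm(n, 0, cfg$rate_sd) else 0
    icpt <- cfg$baseline_recovery +
      if (cfg$regime == "heterogeneous") rnorm(n, 0, cfg$intercept_sd) else 0
    rows <- lapply(seq_along(cfg$timepoints), function(j) {
      t <- cfg$timepoints[j]
      if (t == 0) {
        beta <- day0
      } else {
        m_norm <- icpt + slope * (t - cfg$t_anchor)
        beta <- day0 * m_norm
        if (cfg$noise_sd > 0) beta <- beta + rnorm(n, 0, cfg$noise_sd)
        beta <- pmin(pmax(beta, 0), 1)
      }
      data.frame(cgi = ids, day = t, beta = beta, stringsAsFactors = FALSE)
    })
    tc <- do.call(rbind, rows)
    tc <- timecourse_table(tc$cgi, tc$day, tc$beta)
    list(tc = tc,
         truth = data.frame(cgi = ids, day0 = day0, slope = slope,
                            intercept = icpt, group = group,
                            stringsAsFactors = FALSE))
  })
}

#' Configuration for the spike-in ChIP experiment simulator
#'
#' Two conditions (`ref` and `alt`), each with a ChIP and an input run.
#' Per-CGI ChIP signal intensities are log-normal; in the `alt` ChIP the
#' target-genome signal of every CGI is multiplied by `global_fold_change`
#' while the spike-in chromatin amount is held fixed, so reads are
#' reallocated between target and spike-in exactly as in a ChIP-Rx
#' experiment. Input target material is proportional to CGI length and
#' identical between conditions. Reads are multinomial over (CGIs,
#' spike-in) with probabilities proportional to material.
#'
#' @param n_cgis Number of CGIs.
#' @param signal_meanlog,signal_sdlog Log-normal parameters of per-CGI
#'   ChIP signal.
#' @param coupling Link from signal to the paired per-CGI covariate (e.g.
#'   methylation gain): `"identity"`, `"noisy"` (identity plus Gaussian
#'   noise of SD `coupling_noise_sd`) or `"none"` (independent covariate).
#' @param coupling_noise_sd Noise SD for `coupling = "noisy"`.
#' @param library_size Reads per run.
#' @param spikein_fraction Expected spike-in read fraction in the reference
#'   ChIP and in the inputs, in (0, 1).
#' @param global_fold_change Multiplier on the `alt` ChIP target signal.
#' @param seed RNG seed.
#' @return A validated config list of class `chip_sim_config`.
#' @export
chip_sim_config <- function(n_cgis = 1000, signal_meanlog = 2, signal_sdlog = 1,
                            coupling = c("identity", "noisy", "none"),
                            coupling_noise_sd = 0.5, library_size = 1e6,
                            spikein_fraction = 0.05, global_fold_change = 1,
                            seed = 1) {
  coupling <- match.arg(coupling)
  if (library_size <= 0) stop_bad("library_size must be > 0")
  if (spikein_fraction <= 0 || spikein_fraction >= 1)
    stop_bad("spikein_fraction must be in (0, 1)")
  if (global_fold_change <= 0) stop_bad("global_fold_change must be > 0")
  structure(list(n_cgis = n_cgis, signal_meanlog = signal_meanlog,
                 signal_sdlog = signal_sdlog, coupling = coupling,
                 coupling_noise_sd = coupling_noise_sd,
                 library_size = library_size,
                 spikein_fraction = spikein_fraction,
                 global_fold_change = global_fold_change, seed = seed),
            class = "chip_sim_config")
}

#' Simulate a spike-in ChIP experiment
#'
#' @param cfg A [chip_sim_config()].
#' @param emit_fragments Also generate per-read fragment intervals (150 bp,
#'   placed within the source CGI) for the ChIP runs; intended for small
#'   libraries when testing interval counting.
#' @return A list with `samples` (named list `ref`/`alt`, each holding
#'   `chip` and `input` [chip_sample()] objects), `cgis` (intervals),
#'   `truth` (list: per-CGI `signal` and `covariate`, `fold_change`, and
#'   `expected_scaling_factor`, the expected value of the input-corrected
#'   spike-in factor for `alt` vs `ref`), and optionally `fragments`.
#' @export
simulate_chip_experiment <- function(cfg, emit_fragments = FALSE) {
  stopifnot(inherits(cfg, "chip_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_cgis
    len <- round(runif(n, 500, 2000))
    chrom <- sprintf("chr%d", ((seq_len(n) - 1L) %% 22L) + 1L)
    idx_on_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
    start <- 50000 * idx_on_chrom
    cgis <- genomic_intervals(chrom, start, start + len,
                              name = sprintf("cgi_%04d", seq_len(n)))
    signal <- rlnorm(n, cfg$signal_meanlog, cfg$signal_sdlog)
    covariate <- switch(cfg$coupling,
                        identity = signal,
                        noisy = signal + rnorm(n, 0, cfg$coupling_noise_sd * sd(signal)),
                        none = rnorm(n))
    T_ref <- sum(signal)
    spike_mat <- T_ref * cfg$spikein_fraction / (1 - cfg$spikein_fraction)
    g <- cfg$global_fold_change
    draw_run <- function(material, sample_id, role) {
      pr <- c(material, spike_mat)
      counts <- as.numeric(rmultinom(1, size = cfg$library_size, prob = pr / sum(pr)))
      chip_sample(sample_id, role,
                  counts = setNames(counts[seq_len(n)], cgis$name),
                  target_total = sum(counts[seq_len(n)]),
                  spikein_total = counts[n + 1L])
    }
    input_mat <- len / sum(len) * T_ref  # uniform-coverage input, same scale
    samples <- list(
      ref = list(chip = draw_run(signal, "ref", "ChIP"),
                 input = draw_run(input_mat, "ref_input", "input")),
      alt = list(chip = draw_run(signal * g, "alt", "ChIP"),
                 input = draw_run(input_mat, "alt_input", "input")))
    expected_s <- (T_ref + spike_mat) / (g * T_ref + spike_mat) /
      1  # input spike-in representation identical between conditions
    out <- list(samples = samples, cgis = cgis,
                truth = list(signal = setNames(signal, cgis$name),
                             covariate = setNames(covariate, cgis$name),
                             fold_change = g,
                             expected_scaling_factor = expected_s))
    if (emit_fragments) {
      frag_one <- function(run) {
        counts <- run$counts
        idx <- rep(seq_len(n), counts)
        fstart <- numeric(length(idx))
        for (i in unique(idx)) {
          k <- sum(idx == i)
          span <- max(len[i] - 150, 1)
          fstart[idx == i] <- start[i] + floor(runif(k, 0, span))
        }
        genomic_intervals(chrom[idx], fstart, fstart + 150,
                          name = sprintf("frag_%d", seq_along(idx)))
      }
      out$fragments <- list(ref = frag_one(samples$ref$chip),
                            alt = frag_one(samples$alt$chip))
    }
    out
  })
}

#' Simulate a rooted ontology DAG with a planted enriched term
#'
#' Builds a single-rooted DAG of `n_terms` terms over `depth` levels (each
#' non-root term gets one or two parents in the level above, edges typed
#' `is_a` or `part_of`), assigns each gene a few random terms, and plants
#' one mid-depth term whose gene set is enriched by construction.
#'
#' @param n_terms Number of terms (>= 1).
#' @param depth Number of levels below the root (>= 1).
#' @param n_genes Number of genes.
#' @param seed RNG seed.
#' @param planted_fraction Fraction of genes carrying the planted term.
#' @return A list with `graph` ([term_graph()]), `gene_to_terms` (direct
#'   assignments), and `truth` (`planted_term`, `planted_genes`).
#' @export
simulate_ontology <- function(n_terms = 50, depth = 4, n_genes = 200, seed = 1,
                              planted_fraction = 0.15) {
  if (depth < 1) stop_bad("depth must be >= 1")
  if (n_terms < 1) stop_bad("n_terms must be >= 1")
  with_seed(seed, {
    ids <- sprintf("T%04d", seq_len(n_terms))
    level <- c(0, if (n_terms > 1)
      sort(sample(seq_len(depth), n_terms - 1, replace = TRUE)))
    edges <- NULL
    for (i in seq_len(n_terms)[-1]) {
      cand <- which(level < level[i])
      np <- min(length(cand), sample(1:2, 1))
      par <- if (length(cand) == 1L) cand else sample(cand, np)
      edges <- rbind(edges, data.frame(
        child = ids[i], parent = ids[par],
        relation = sample(c("is_a", "part_of"), length(par),
                          replace = TRUE, prob = c(0.8, 0.2)),
        stringsAsFactors = FALSE))
    }
    graph <- term_graph(edges = edges %||%
                          data.frame(child = character(), parent = character(),
                                     relation = character()),
                        terms = ids)
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    gene_to_terms <- lapply(genes, function(g)
      sort(unique(sample(ids, min(n_terms, sample(1:3, 1))))))
    names(gene_to_terms) <- genes
    planted <- ids[which.min(abs(level - ceiling(depth / 2)))]
    planted_genes <- sort(sample(genes, max(1, round(planted_fraction * n_genes))))
    for (g in planted_genes)
      gene_to_terms[[g]] <- sort(unique(c(gene_to_terms[[g]], planted)))
    # keep the planted signal crisp: remove the planted term from other genes
    for (g in setdiff(genes, planted_genes))
      gene_to_terms[[g]] <- setdiff(gene_to_terms[[g]], planted)
    list(graph = graph, gene_to_terms = gene_to_terms,
         truth = list(planted_term = planted, planted_genes = planted_genes))
  })
}
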