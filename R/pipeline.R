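# End-to-end orchestration on synthetic or file-based inputs, with a
# deterministic run manifest. All artifacts are plain TSV/JSON.

#' Pipeline configuration
#'
#' Collects the analysis thresholds (each with its standard default:
#' coverage >= 10, gain >= 0.20, FDR 0.05, beta >= 0.3, day-0 > 0.5, days
#' 3-22, count offset 0.5, 10 rank groups, Wang similarity 0.7, minimum
#' background 10), the simulator configurations, and the master seed from
#' which all stage seeds are derived.
#'
#' @param seed Master seed; every source of randomness in a run flows from
#'   it.
#' @param min_coverage,min_gain,fdr,beta_threshold,day0_min,t_min,t_max,offset,n_groups,wang_threshold,min_background
#'   Stage thresholds; see the stage functions for their meaning.
#' @param meth_sim,kinetics_sim,chip_sim,ontology_sim Simulator configs /
#'   argument lists used by the `simulate` stage (seeds are overridden with
#'   values derived from `seed`).
#' @return A config list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, min_coverage = 10, min_gain = 0.20,
                            fdr = 0.05, beta_threshold = 0.3, day0_min = 0.5,
                            t_min = 3, t_max = 22, offset = 0.5, n_groups = 10,
                            wang_threshold = 0.7, min_background = 10,
                            meth_sim = NULL, kinetics_sim = NULL,
                            chip_sim = NULL, ontology_sim = NULL) {
  check_prob(c(min_gain, fdr, beta_threshold, day0_min), "thresholds")
  if (min_coverage < 1 || min_background < 0) stop_bad("invalid count threshold")
  if (t_min >= t_max) stop_bad("need t_min < t_max")
  # plain lists (e.g. from a JSON/YAML config file) are coerced to their
  # validated simulator configs
  if (is.list(meth_sim) && !inherits(meth_sim, "meth_sim_config"))
    meth_sim <- do.call(meth_sim_config, meth_sim)
  if (is.list(kinetics_sim) && !inherits(kinetics_sim, "kinetics_sim_config"))
    kinetics_sim <- do.call(kinetics_sim_config, kinetics_sim)
  if (is.list(chip_sim) && !inherits(chip_sim, "chip_sim_config"))
    chip_sim <- do.call(chip_sim_config, chip_sim)
  structure(list(seed = seed, min_coverage = min_coverage, min_gain = min_gain,
                 fdr = fdr, beta_threshold = beta_threshold,
                 day0_min = day0_min, t_min = t_min, t_max = t_max,
                 offset = offset, n_groups = n_groups,
                 wang_threshold = wang_threshold,
                 min_background = min_background,
                 meth_sim = meth_sim, kinetics_sim = kinetics_sim,
                 chip_sim = chip_sim, ontology_sim = ontology_sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON file whose keys are
#'   [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

pipeline_stages <- c("simulate", "methylation", "gain", "kinetics", "chip", "enrich")

derive_seed <- function(seed, stage) {
  # deterministic per-stage seeds, kept within 32-bit integer range
  (as.integer(seed) * 131L + match(stage, pipeline_stages) * 7919L) %% 2147483587L
}

strip_s3 <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_s3) else x
}

config_json <- function(config) {
  jsonlite::toJSON(strip_s3(config), auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order
#' (`simulate` -> `methylation` -> `gain`; `simulate` -> `kinetics`;
#' `simulate` -> `chip`; `simulate` + `gain` -> `enrich`), writing each stage's artifacts as TSV/JSON into `outdir` together with a run
#' manifest (`manifest.json`: config hash, input checksums, package
#' version, seed). Reruns with an identical config produce byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param stages Subset of `r paste(pipeline_stages, collapse = ", ")`.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, outdir,
                         stages = pipeline_stages) {
  stopifnot(inherits(config, "pipeline_config"))
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown))
    stop_bad("unknown stage(s): ", paste(unknown, collapse = ", "),
             "; valid stages are: ", paste(pipeline_stages, collapse = ", "))
  need <- list(methylation = "simulate", gain = "methylation",
               kinetics = "simulate", chip = "simulate", enrich = "gain")
  for (s in stages) {
    dep <- need[[s]]
    if (!is.null(dep) && !dep %in% stages)
      stop_bad("stage '", s, "' requires stage '", dep, "' in the same run")
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if ("simulate" %in% stages) {
    message("[simulate] generating synthetic inputs")
    ms <- config$meth_sim %||% meth_sim_config()
    ms$seed <- derive_seed(config$seed, "simulate")
    ks <- config$kinetics_sim %||% kinetics_sim_config()
    ks$seed <- derive_seed(config$seed, "kinetics")
    cs <- config$chip_sim %||% chip_sim_config()
    cs$seed <- derive_seed(config$seed, "chip")
    os <- config$ontology_sim %||% list(n_terms = 60, depth = 4, n_genes = 300)
    os$seed <- derive_seed(config$seed, "enrich")
    res$sim_meth <- simulate_cpg_counts(ms)
    res$sim_kin <- simulate_timecourse(ks)
    res$sim_chip <- simulate_chip_experiment(cs)
    res$sim_onto <- do.call(simulate_ontology, os)
    write_bismark_cov(res$sim_meth$table_a, file.path(outdir, "cpg_counts_A.cov"))
    write_bismark_cov(res$sim_meth$table_b, file.path(outdir, "cpg_counts_B.cov"))
    write_bed(res$sim_meth$cgis, file.path(outdir, "cgis.bed"))
    write_tsv(res$sim_meth$truth, file.path(outdir, "truth_gain.tsv"))
    write_tsv(res$sim_kin$truth, file.path(outdir, "truth_kinetics.tsv"))
    write_tsv(as.data.frame(res$sim_kin$tc), file.path(outdir, "timecourse.tsv"))
  }

  if ("methylation" %in% stages) {
    tab <- rbind(res$sim_meth$table_a, res$sim_meth$table_b)
    filt <- filter_cpgs(tab, min_coverage = config$min_coverage)
    message(sprintf("[methylation] coverage >= %d filter: %d of %d CpG rows retained",
                    config$min_coverage, nrow(filt), nrow(tab)))
    res$meth_a <- cgi_weighted_methylation(filt[filt$sample == "A", ], res$sim_meth$cgis)
    res$meth_b <- cgi_weighted_methylation(filt[filt$sample == "B", ], res$sim_meth$cgis)
    write_tsv(rbind(res$meth_a, res$meth_b), file.path(outdir, "cgi_methylation.tsv"))
  }

  if ("gain" %in% stages) {
    res$gain <- call_methylation_gain(res$meth_a, res$meth_b,
                                      min_gain = config$min_gain, fdr = config$fdr)
    message(sprintf("[gain] %d of %d CGIs called gainers", sum(res$gain$is_gainer),
                    nrow(res$gain)))
    write_tsv(as.data.frame(res$gain), file.path(outdir, "gain_calls.tsv"))
  }

  if ("kinetics" %in% stages) {
    ntc <- normalise_timecourse(res$sim_kin$tc, day0_min = config$day0_min)
    message(sprintf("[kinetics] %d CGIs pass the day-0 > %.0f%% filter (%d excluded)",
                    length(attr(ntc, "included")), 100 * config$day0_min,
                    length(attr(ntc, "excluded"))))
    res$heterogeneity <- test_rate_heterogeneity(ntc, config$t_min, config$t_max)
    res$rates <- fit_cgi_recovery_rates(ntc, config$t_min, config$t_max)
    write_tsv(res$rates, file.path(outdir, "recovery_rates.tsv"))
    ht <- res$heterogeneity
    jsonlite::write_json(
      list(loglik_null = ht$loglik_null, loglik_alt = ht$loglik_alt,
           lr_statistic = ht$lr_statistic, df_difference = ht$df_difference,
           p_value = ht$p_value, n_cgis = ht$n_cgis, timepoints = ht$timepoints),
      file.path(outdir, "heterogeneity_test.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("chip" %in% stages) {
    sc <- res$sim_chip
    regs <- covered_regions(list(sc$samples$ref$chip, sc$samples$ref$input,
                                 sc$samples$alt$chip, sc$samples$alt$input))
    message(sprintf("[chip] %d of %d regions covered in at least one sample",
                    length(regs), nrow(sc$cgis)))
    scaling <- rx_scaling_factor(sc$samples, reference = "ref")
    sig_ref <- normalised_signal(sc$samples$ref$chip, sc$samples$ref$input,
                                 offset = config$offset, regions = regs)
    sig_alt <- normalised_signal(sc$samples$alt$chip, sc$samples$alt$input,
                                 offset = config$offset, regions = regs)
    sig_alt <- apply_rx_scaling(sig_alt, scaling, "alt")
    res$chip <- list(scaling = scaling, signal_ref = sig_ref, signal_alt = sig_alt)
    res$decile <- decile_association(unclass(sig_ref),
                                     sc$truth$covariate[regs],
                                     n_groups = config$n_groups)
    write_tsv(data.frame(region = regs, signal_ref = unclass(sig_ref),
                         signal_alt_scaled = unclass(sig_alt)),
              file.path(outdir, "chip_signal.tsv"))
    jsonlite::write_json(list(reference = attr(scaling, "reference"),
                              factors = setNames(as.list(scaling$factor),
                                                 scaling$sample)),
                         file.path(outdir, "rx_scaling.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("enrich" %in% stages) {
    onto <- res$sim_onto
    # CGI -> gene: pair CGIs with simulated genes round-robin
    genes <- names(onto$gene_to_terms)
    cgi_ids <- res$sim_meth$truth$cgi
    cgi_to_genes <- setNames(as.list(genes[((seq_along(cgi_ids) - 1L) %% length(genes)) + 1L]),
                             cgi_ids)
    g2t <- propagate_ancestors(onto$gene_to_terms, onto$graph)
    target <- res$gain$cgi[res$gain$is_gainer]
    if (length(target) == 0L) {
      message("[enrich] no gainer CGIs; skipping enrichment test")
    } else {
      res$enrich <- enrich_terms(target, cgi_ids, cgi_to_genes, g2t,
                                 min_background = config$min_background,
                                 fdr = config$fdr)
      if (nrow(res$enrich) > 0)
        res$enrich <- collapse_similar_terms(res$enrich, onto$graph,
                                             threshold = config$wang_threshold)
      message(sprintf("[enrich] %d terms tested, %d significant, %d kept after collapse",
                      nrow(res$enrich), sum(res$enrich$significant),
                      sum(res$enrich$significant & res$enrich$kept_after_collapse)))
      write_tsv(as.data.frame(res$enrich), file.path(outdir, "term_enrichment.tsv"))
    }
  }

  # manifest: configuration hash and artifact checksums (no timestamps, so
  # identical runs are byte-identical)
  cfg_file <- file.path(outdir, "config.json")
  writeLines(as.character(config_json(config)), cfg_file)
  arts <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    stages = stages,
    package_version = as.character(utils::packageVersion("cgimeth")),
    artifacts = as.list(tools::md5sum(file.path(outdir, arts))))
  names(manifest$artifacts) <- arts
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
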