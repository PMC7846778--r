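# cgimeth

Tools for quantifying de novo DNA methyltransferase activity at CpG
islands (CGIs) from bisulfite sequencing, 5-aza-2'-deoxycytidine
(5-aza-dC) re-methylation time courses, and spike-in ChIP-seq, with
synthetic-data generators that make every stage testable against known
ground truth.

## Who it is for

Epigenomics analysts working with RRBS/WGBS count data, demethylation
re-methylation kinetics experiments, and quantitative (ChIP-Rx) ChIP-seq —
in settings such as DNMT3B re-introduction into hypomethylated cells,
where the questions are *which CGIs gain methylation*, *whether CGIs
recover methylation at different rates after demethylating drug treatment*,
and *how recovery relates to chromatin marks such as H3K36me3*.

## What it computes

**CGI methylation and gain calling.** CGI methylation is the
coverage-weighted mean over contained CpGs, β = Σm / Σ(m+u), using only
CpGs with coverage ≥ 10 in every sample. A CGI gains methylation when a
two-sided Fisher's exact test on pooled (methylated, unmethylated) counts
by condition has Benjamini–Hochberg adjusted p < 0.05 **and** Δβ ≥ 0.20.

**Re-methylation kinetics.** For CGIs with day-0 methylation > 50%,
trajectories are normalised to their day-0 value. On days 3–22 inclusive,
two nested linear mixed models are compared by a maximum-likelihood ratio
test:

    null (outgrowth only):  m ~ t + (1 | CGI)
    alternative:            m ~ t + (1 + t | CGI)

where the random slope s_CGI lets each CGI recover at its own rate.
Per-CGI OLS slopes over the same day range estimate the fraction of day-0
methylation recovered per day; groups (e.g. H3K36me3-marked vs other CGIs)
are compared with two-sided Wilcoxon rank-sum tests.

**Spike-in ChIP quantification.** Region counts get a 0.5 offset, are
scaled to counts per 10⁷ mapped reads and divided by the matched input.
Between-sample scaling uses spike-in reads per 10⁷ (dRPTM) with input
correction,

    S_n = (dRPTM_ChIP-n / dRPTM_ChIP-ref) / (dRPTM_IN-n / dRPTM_IN-ref),

with S_ref = 1 exactly; each sample's normalised signal is divided by its
S_n to place samples on a common quantitative scale. Rank-decile summaries
plus CGI-level Spearman correlation, a standardised-coefficient linear
model of per-CGI signal on histone marks, qPCR percent-input, and heatmap
matrices capped at the 90% quantile round out the module.

**Term enrichment.** CGIs inherit ontology terms through their assigned
genes (TSS overlap, then transcript, then closest TSS with ties kept);
ancestor-closed term sets are tested one-sided against the background CGI
universe (terms with < 10 background CGIs excluded; BH FDR 0.05), and
redundant significant terms are collapsed by Wang semantic similarity
(> 0.7 keeps only the lowest-q term per group).

## Worked example

```r
library(cgimeth)

# simulate a two-condition RRBS experiment: 500 CGIs, 30x coverage,
# 20% of CGIs gain 0.5 methylation in condition B
sim <- simulate_cpg_counts(meth_sim_config(
  n_cgis = 500, coverage_mean = 30, gain_size = 0.5,
  gainer_fraction = 0.2, seed = 2024))

counts <- rbind(sim$table_a, sim$table_b)
counts <- filter_cpgs(counts, min_coverage = 10)
meth_a <- cgi_weighted_methylation(counts[counts$sample == "A", ], sim$cgis)
meth_b <- cgi_weighted_methylation(counts[counts$sample == "B", ], sim$cgis)
calls  <- call_methylation_gain(meth_a, meth_b)
print(calls)
#> CGI methylation gain calls
#>   500 CGIs tested, 100 gainers (q < threshold and delta >= min gain)
table(called = calls$is_gainer, truth = sim$truth$gainer[match(calls$cgi, sim$truth$cgi)])
#>        truth
#> called  FALSE TRUE
#>   FALSE   400    0
#>   TRUE      0  100
```

All 100 simulated gainers are recovered with no false positives: at ~30x
coverage over ≥ 8 CpGs a 0.5 β difference is far outside binomial noise.

```r
# re-methylation kinetics: is recovery heterogeneous across CGIs?
kin <- simulate_timecourse(kinetics_sim_config(
  n_cgis = 200, regime = "heterogeneous", rate_sd = 0.01,
  mean_rate = 0.03, noise_sd = 0.02, seed = 42))
ntc <- normalise_timecourse(kin$tc)       # day-0 > 50% filter, /day0
print(test_rate_heterogeneity(ntc))
#> Test of heterogeneous re-methylation rates across CGIs
#>   null (outgrowth):  m ~ t + (1 | cgi),   logLik = 1178.532
#>   alt  (per-CGI):    m ~ t + (1 + t | cgi), logLik = 2082.204
#>   LR = 1807.344 on 2 df, p = 0  (200 CGIs, days 3,6,10,14,18,22)
```

(The likelihood-ratio statistic is so large that the chi-square tail
underflows double precision, hence `p = 0`.)

A rate SD of only 0.01/day among CGIs is overwhelming evidence against the
outgrowth-only null; the per-CGI slopes from `fit_cgi_recovery_rates(ntc)`
correlate with the generating rates at r ≈ 0.98.

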