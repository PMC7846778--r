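---
title: "Models and methods behind cgimeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cgimeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgimeth)
```

cgimeth implements the quantitative core of a CGI-centric analysis of de
novo DNA methyltransferase activity: calling CGIs that gain methylation
from bisulfite counts, deciding whether re-methylation after 5-aza-dC is
outgrowth-driven or rate-heterogeneous, quantitative spike-in ChIP
normalisation, and semantic-similarity-aware term enrichment. This
vignette explains the models, the defaults, the numerical choices, and
what the synthetic-data tests do and do not establish.

## CGI methylation and the gain caller

Per-CpG bisulfite data are methylated/unmethylated read counts. A CGI's
methylation in a sample is the coverage-weighted mean over its CpGs,

$$\beta_{\mathrm{CGI}} = \frac{\sum_i m_i}{\sum_i (m_i + u_i)},$$

identical to pooling the reads and taking the methylated fraction. Only
CpGs with total coverage ≥ 10 in *every* sample of an analysis enter
(boundary inclusive); CGIs with no usable CpG are reported as missing,
never as zero, because absence of evidence is not hypomethylation.

The gain call between conditions contrasts pooled (methylated,
unmethylated) counts in a 2×2 Fisher's exact test (two-sided), adjusts
p-values by Benjamini–Hochberg across all tested CGIs, and requires both
adjusted p < 0.05 and a gain Δβ ≥ 0.20. Pooling counts per condition is a
modelling choice the count data do not force: per-CpG tests could be
combined instead. Pooled counts were chosen because they make the tested
quantity exactly the weighted-mean β that is reported, and give one test
per CGI. Replicate libraries within a condition are likewise summed at
the count level before testing. Note that pooled-count exact tests treat
reads as independent draws; biological overdispersion across CpGs is not
modelled, so on real data the p-values are anti-conservative relative to
a beta-binomial treatment — the Δβ ≥ 0.20 effect-size gate is what keeps
calls biologically meaningful.

Threshold boundaries are read literally and inclusively throughout:
coverage "≥ 10", gain "≥ 20%", array beta "≥ 0.3" (methylated), clone
error "≥ 25%" (excluded). Day-0 filtering in kinetics is the one strict
inequality: "> 50%".

## Re-methylation kinetics

After 5-aza-dC, cells lose methylation passively and then recover. If
recovery were purely the outgrowth of cells that escaped demethylation,
every region's trajectory would be a fixed multiple of its starting
level: dividing each CGI's trajectory by its day-0 value collapses all
CGIs onto one common normalised curve. The alternative is genuine
enzymatic re-methylation at region-specific rates.

CGIs with day-0 methylation > 0.5 are normalised by their day-0 value
(values above 1 after division are retained — the raw means are divided,
not clipped). On timepoints in [3, 22] days inclusive, two nested linear
mixed models are fitted by maximum likelihood (not REML, so their
likelihoods are comparable):

- null: `m ~ t + (1 | cgi)` — common slope, per-CGI random intercept;
- alternative: `m ~ t + (1 + t | cgi)` — adds a per-CGI random slope.

The likelihood-ratio statistic is referred to χ² with the parameter-count
difference as degrees of freedom: 2 by default (slope variance +
intercept–slope covariance, the correlated-effects default of `lmer`), or
1 with `correlated = FALSE`. Because the null pins the slope variance to
its boundary, the χ² reference is conservative; the simulation studies in
the test suite measure the realised type-I rate at ~0.03 for nominal
0.05. We accept the conservatism rather than mixing chi-squares, because
the decision in practice is one-sided and overwhelming (the power study
rejects at p < 10⁻³ in 100/100 replicates for a rate SD of just
0.01/day).

Two numerical details. First, days 3–22 is a day-range filter, not a
count: any grid with at least three distinct days in range is accepted.
Second, the alternative model nests the null, so its ML log-likelihood
cannot be smaller; when the optimizer occasionally stalls at the boundary
and reports a lower likelihood, the fit is retried with `bobyqa` and
`Nelder-Mead`, and any residual deficit is clamped to a statistic of 0
with a warning — the mathematically correct boundary value, and
conservative.

Per-CGI recovery rates are plain OLS slopes of normalised methylation on
day over the same range, computed in closed form; the slope unit is
fraction of the day-0 methylation level recovered per day. Group
contrasts (e.g. H3K36me3-marked vs other CGIs) use two-sided Wilcoxon
rank-sum tests on these slopes.

## Spike-in ChIP quantification

Raw per-region counts receive an offset of 0.5 (so zero-input regions
cannot divide to infinity), are scaled to counts per 10⁷ mapped reads,
and divided by the matched input. Regions with zero coverage in every
sample are removed first (`covered_regions()`). The per-10⁷ denominator
is each run's total mapped reads including spike-in by default
(`denominator = "all"`); the choice is configurable because the counting
convention is not forced by the method.

Between-sample scaling uses the spike-in representation per run,
dRPTM = spike-in reads per 10⁷ mapped, input-corrected:

$$S_n = \frac{\mathrm{dRPTM}_{\mathrm{ChIP}\text{-}n} / \mathrm{dRPTM}_{\mathrm{ChIP}\text{-}ref}}
             {\mathrm{dRPTM}_{\mathrm{IN}\text{-}n} / \mathrm{dRPTM}_{\mathrm{IN}\text{-}ref}}.$$

$S_n$ measures how over-represented the spike-in is in sample *n*'s ChIP
relative to the reference after correcting for input composition. A
genuine global *gain* of target signal in sample *n* therefore yields
$S_n < 1$, and `apply_rx_scaling()` **divides** the CPM+input-normalised
signal by $S_n$. The direction matters: with fixed spike-in chromatin, a
true 2-fold global increase leaves per-million-normalised signals nearly
unchanged (composition effect), and division by the expected
$S = (T+s)/(2T+s)$ restores the factor of 2 exactly in expectation — the
closed-form identity the simulation-based tests verify to within counting
error. Replicates are scaled individually and averaged afterwards.

Decile association ranks CGIs by signal into equal groups (remainder
spread over the lowest groups) for display summaries; the reported
Spearman correlation is computed over individual CGIs, not group medians,
since group-level correlation would overstate certainty. The
histone-mark linear model z-scores its predictors so coefficients are
comparable across marks, and reports the design-matrix condition number
(flagging > 30 as collinear) rather than silently dropping columns.
Heatmap display ranges run from the minimum to the 90% quantile (type-7
linear interpolation, R's default); values themselves are never
truncated. qPCR enrichment adjusts the input Ct to 100% of chromatin by
subtracting $\log_2(1/\mathrm{input fraction})$ cycles and assumes primer
efficiency 2; the "adjust to 100%" step is an interpretation of standard
percent-input practice and is flagged as such.

## Term enrichment and Wang similarity

CGIs map to genes by TSS overlap, else containing transcript, else
closest TSS measured from the CGI edge, with distance ties keeping all
tied genes (hence "closest TSS(s)"). A CGI carries a term when any
assigned gene carries it after ancestor propagation (set semantics over
the is_a/part_of DAG). Enrichment contrasts a target CGI set against the
background CGI universe per term with one-sided Fisher tests; terms with
fewer than 10 background CGIs are excluded *before* testing (so they do
not dilute the BH correction), and BH runs across the tested terms.

Wang similarity scores each term's ancestor graph with S-values — 1 for
the term, and for each ancestor the maximum over paths of the product of
edge contribution factors (0.8 for is_a, 0.6 for part_of, the method's
original parameterisation, configurable) — and compares two terms by the
summed S-values of their common ancestors over their total semantic
values. Redundant significant terms are collapsed greedily in ascending
q-order: keep the best term, discard everything with similarity > 0.7 to
it, recurse on the rest; ties in q are broken by term id so reruns are
identical. Greedy-by-q is one of several defensible groupings
(single-linkage clustering is another); it matches the common
"simplify"-style behaviour and guarantees the kept term of every group
is its lowest-q member.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of (config, seed) and emit
machine-readable truth:

- **Bisulfite counts** — per-CGI baseline β from a two-mode Beta mixture
  (defaults: modes 0.1 and 0.8, 25% high, concentration 60 — the bimodal
  CGI landscape), truncated-Poisson coverage (mean 30; coverage is not
  modelled mechanistically), and Binomial(coverage, β) methylated counts.
  Gainers add Δβ to condition B, drawn only where the gain fits in [0, 1].
- **Time courses** — the default grid {0, 3, 6, 10, 14, 18, 22} days
  covers a day-0 anchor, early post-treatment days and a three-week
  endpoint; it is configurable. Normalised trajectories are linear from
  day 3 (level 0.2 at day 3, i.e. ~80% methylation loss) with per-CGI
  Gaussian slopes (SD 0 under the outgrowth null); raw trajectories are
  day0 × normalised with Gaussian observation noise on the beta scale,
  clipped to [0, 1]. Noise applies to post-day-0 points only: the day-0
  anchor is the ground state that defines proportional outgrowth, and
  noising it would itself induce spurious slope heterogeneity (the
  normalisation divides by it), confounding the type-I study.
- **ChIP-Rx** — log-normal per-CGI signal; reads multinomial over (CGIs,
  spike-in) with probabilities proportional to chromatin material; a
  global fold change multiplies target material with spike-in held
  fixed, so read reallocation between target and spike-in is exactly the
  mechanism the scaling factor corrects. Fragment intervals can be
  emitted for interval-counting tests; there is no sequence or alignment
  simulation.
- **Ontology** — a single-rooted random DAG with one planted term whose
  gene set is enriched by construction.

Passing tests on these simulations show the *computations* are correct
and well-calibrated under their own generative assumptions. They do not
show robustness to features real data have and the generators lack:
overdispersed counts, spatially correlated CpGs, coverage biases, copy
number, cell-population drift across a time course, or peak-level ChIP
artefacts.

## Pipeline determinism and problem sizes

`run_pipeline()` derives every stage seed from the single config seed,
writes only deterministic artifacts (TSV with fixed formatting, JSON
without timestamps), and records a manifest of config hash + artifact
checksums; two runs with the same config are byte-identical, which the
test suite asserts file-by-file. Stage logs report counts in and out of
every filter so each exclusion rule is auditable.

The validation studies use deliberately modest sizes — 500 CGIs for the
gain caller, 200 replicates × 200 CGIs for the type-I study, 100
replicates for power, 1000 CGIs for ChIP experiments — chosen so the full
suite runs in well under a minute while leaving all the tested
conclusions (complete separation for the gain caller, conservative size,
saturated power) far from their thresholds.

## Known limitations

- Exact tests on pooled counts ignore overdispersion (above).
- The boundary-conservative LRT sacrifices a little power by design.
- Wang-similarity collapse depends on the greedy order for borderline
  groups; only the guarantee "kept = lowest q within its group" is
  order-independent.
- Conversion efficiency is accepted as an input QC number; there is no
  λ-spike-in conversion model.
- No liftover, peak calling, alignment, or array preprocessing — inputs
  are counts and intervals, downstream of those tools.
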