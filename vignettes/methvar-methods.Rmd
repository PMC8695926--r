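---
title: "Variably methylated gene discovery: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variably methylated gene discovery: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methvar)
```

## The analysis problem

Invertebrate methylomes such as that of the marbled crayfish are mosaic:
most gene bodies are either stably methylated (ratio near 1) or stably
unmethylated (near 0), and only a minority of genes shows intermediate,
variable methylation across animals, tissues and sampling locations.
Because the species is clonal, methylation differences between
populations cannot be explained by genotype, which makes these variably
methylated genes candidates for purely epigenetic tissue and location
signatures. `methvar` implements the full desk-side machinery for that
programme: gene-body aggregation of per-CpG bisulfite methylation
calls, a selection cascade that isolates the variably methylated gene
set, rank-based differential methylation with false discovery rate
control, localized DMR detection, ordination of sample methylomes and
quantitative separation scoring, plus a seeded generator of synthetic
methylomes with ground truth so every stage is testable without any
sequencing data.

## Data model and units

The measurement unit is the CpG site: for each sample the input table
records the methylated read count and total coverage of every cytosine
(1-based plus-strand coordinate), with the methylation ratio
`meth/total` in [0, 1]. Symmetric CpG dyads are reported once per
strand by common callers; by default the minus-strand record at
position p+1 is folded into the plus-strand record at p by summing
counts, so each CpG yields one ratio. Whether the original toolchain
merged strands is not documented anywhere we could verify, so merging
is a flag (`merge_strands`, default `TRUE`); with high coverage the two
conventions give nearly identical ratios.

The analysis unit is the gene body: the unweighted mean ratio over the
gene's qualifying CpGs. Unweighted (rather than coverage-weighted)
averaging matches the per-CpG ratio framing of the aggregation rule and
keeps a deeply covered CpG from dominating the gene value. Gene
intervals are stored 1-based inclusive internally; BED input/output
converts at the boundary, and boundary CpGs belong to the gene.

## Coverage qualification and the selection cascade

Two rules guard against coverage artefacts, with defaults taken from
the published procedure:

* a CpG site qualifies only if it has **>= 5X coverage in every sample**
  of the current analysis set (`min_coverage = 5`);
* a gene obtains a value only if it has **>= 5 qualifying CpGs**
  (`min_sites = 5`); otherwise its value is missing, not zero.

"Every sample" is interpreted as every sample of the analysis set in
hand — e.g. all hepatopancreas samples for a location contrast — and the
pipeline recomputes qualification within each contrast's sample subset.
Whether the original analysis qualified jointly across tissues or per
tissue dataset is ambiguous; making the analysis set an explicit
argument renders the choice auditable.

Variable-gene discovery then proceeds in two stages
(`discover_variable_genes()`): keep genes with cross-sample variance
strictly above `var_cutoff`, then exclude the consistently methylated
or unmethylated genes, i.e. mean ratio strictly above 0.8 or strictly
below 0.2. The variance cutoff default is **0.006**; the source
procedure reports both 0.006 (methods text) and 0.06 (a figure legend)
and the contradiction cannot be resolved at desk scale, so the value is
a configurable parameter with the methods-text default.

The core-set filter (`core_set_filter()`) applies four further stages
in the order that carries the published intermediate counts
(697 → 623 → 463 → 361 in the original data): (a) drop genes whose
sequence is more than 50% Ns (poor assembly regions produce unreliable
mapping); (b) drop genes whose average is not computable in every
sample; (c) drop the bottom 10% of genes by methylation variance; (d)
drop genes with overall mean level below 0.1 or above 0.9. The
bottom-decile boundary uses the nearest-rank quantile
(`ceiling(q * n)`), and ties at the boundary variance are all removed —
a conservative rule that makes the stage deterministic and invariant to
gene input order. Every stage is recorded in a `filter_report` with
before/after counts and removed gene identities, so the cascade is
fully auditable. Those published counts derive from deposited
sequencing data and are not reproduced here; the package's fixtures
carry their own expected counts, verified against an independent
plain-loop implementation of the cascade.

## Differential methylation

Tissue contrasts use the Wilcoxon rank-sum test and location contrasts
the Kruskal-Wallis test, both implemented in the package: the gene
values are bounded ratios with heavy ties near 0 and 1, so rank tests
are the appropriate tool, and implementing them directly gives an exact
small-sample path and explicit tie handling. The Wilcoxon statistic is
the rank sum of the first group with midranks; p-values are exact by
full enumeration of the rank-sum distribution when the pooled sample is
tie-free and has at most 20 observations (configurable), and otherwise
use the normal approximation with tie-corrected variance and a
continuity correction. Kruskal-Wallis uses the tie-corrected H against
a chi-square with k − 1 degrees of freedom; for two groups H equals the
squared z of the uncorrected Wilcoxon approximation, an identity the
test suite checks to 1e-9. The standard library implementations
(`wilcox.test`, `kruskal.test`, `p.adjust`, `chisq.test`, `t.test`)
serve as independent oracles in the tests, never as the implementation.

Multiple testing is controlled by the Benjamini-Hochberg step-up
procedure across the genes actually tested: genes skipped because a
group drops below 2 non-missing values are excluded from the family and
reported. Significance is `q < alpha` (default 0.05); as a boundary
convention `alpha >= 1` flags every tested gene even when q equals 1
exactly. The two contrasts are deliberately stratified — tissue within
a single location, location within a single tissue — because tissue and
location are crossed factors and pooling would confound them.

## DMR detection

Because the published region caller relies on smoothed beta-binomial
inference, the package instead ships a deliberately simple, fully
deterministic run-based scanner (`scan_dmrs()`): a CpG discriminates
between groups when the largest pairwise difference of group-mean
ratios reaches `min_delta` (default 0.1); maximal runs of
discriminating CpGs, tolerating at most `max_gap = 2` interruptions,
are reported when they contain at least `min_sites = 5` such CpGs. The
scanner is not expected to reproduce the original caller's region
counts; it is the transparent primitive the validation logic needs
(localized windows of consistent group difference), and its outputs are
exactly reproducible. Capture-vs-amplicon concordance
(`amplicon_concordance()`) compares position-matched CpG ratios with
Pearson correlation and mean absolute difference.

## Ordination and separation

PCA (`pca_embed()`) runs on gene-centered, unscaled values — all
features share the [0, 1] scale, and the cited implementation's default
is unscaled; scaling is available by flag. Genes with any missing entry
are dropped (count logged) rather than imputed, since no imputation was
described for the original analysis. Classical metric MDS
(`mds_embed()`) on Euclidean distances is provided for the discovery
view; for Euclidean input it agrees with PCA scores up to rotation and
sign, which the tests verify by Procrustes residual. Separation that
the original study assessed visually is quantified with the mean
silhouette width over samples (`separation_score()`), which is bounded
in [−1, 1], needs no model fit, and is 0 in expectation for random
labels.

## The synthetic methylome generator

`simulate_dataset()` emulates the structure the analysis assumes, with
every default fixed in advance of any testing:

* **Baseline mixture** — weights (0.45, 0.20, 0.35) on
  beta(0.5, 5), beta(2, 2), beta(5, 0.5): a bimodal methylome with an
  intermediate minority. The exact shape is a modeling choice; only the
  bimodal-plus-intermediate form is empirically grounded.
* **Effects** — a fraction of genes (default 10% tissue, 10% location)
  carries a shift of `effect_delta = 1.0` on the logit scale over a
  contiguous window of `dmr_width = 10` CpGs (of ~30 per gene),
  reflecting that real tissue and location signatures are highly
  localized rather than gene-wide. Effect genes draw their baseline
  from the intermediate beta component: a log-odds shift applied at a
  near-0 or near-1 baseline is invisible at count level, and the
  empirically variable genes are the intermediate ones, so placing
  effects there is both realistic and the only way ground-truth
  recovery is meaningful. Non-effect genes follow the full mixture.
* **Counts** — coverage is negative binomial with mean 30 and size 30
  (variance ≈ 2× mean, mimicking overdispersed capture coverage);
  methylated counts are binomial with success probability
  `r + (1 − r) ε`, where `ε = 0.02` is the bisulfite non-conversion
  rate (failure to convert an unmethylated C inflates apparent
  methylation; sequencing miscalls are not separately modeled). A
  block of truly unmethylated CHH sites is emitted per sample so the
  pooled conversion-rate estimator can be exercised; at these defaults
  it recovers ≈ 98%.
* **Design** — 12 samples per tissue × location cell and 4 locations by
  default, matching the scale of the real capture experiment (48
  hepatopancreas samples across 4 locations).

What the generator does *not* emulate: linkage between neighbouring
CpGs beyond the shared gene baseline, capture-efficiency variation
between baits, read-level error profiles, between-animal random
effects, or genetic variation (the organism is clonal). Passing
recovery tests therefore demonstrates that the pipeline's statistics
behave correctly under the stated noise model, not that real data meet
that model.

## Numerical choices and degenerate inputs

* Conversion rate is pooled over counts, never a mean of per-site
  rates, so low-coverage sites cannot destabilise it; zero aggregate
  coverage is an error, not NaN.
* Variance uses the n − 1 denominator over non-missing values; genes
  with fewer than 2 observed values cannot enter the cascade.
* BH q-values are clamped to `max(q, p)`: the step-up minimum is
  mathematically ≥ p but can round one ulp below it in floating point.
* All-identical data yield p = 1 with an explicit degenerate flag in
  Kruskal-Wallis and Welch tests rather than a division-by-zero NaN.
* All randomness flows through one integer seed; the generator saves
  and restores the caller's RNG state, and identical seeds give
  byte-identical datasets and pipeline artifacts.

## Problem sizes used in the test suite

The packaged checks run the generator at 200 genes × 48 samples for
recovery and null-calibration studies (200 replicates for the false
discovery proportion under the null), 2 000 genes for the
mixture-weight goodness of fit, and ≥ 10^5 draws for coverage
calibration — sizes at which the Monte-Carlo error of each checked
quantity is well below its acceptance margin, and the full suite
completes in a few minutes on one core.

## Known limitations

* The cascade's published intermediate counts (846/697/623/463/361) are
  properties of the deposited sequencing dataset and are validated here
  only as arithmetic on constructed matrices, not re-derived from raw
  reads.
* The DMR scanner is a transparent stand-in with different operating
  characteristics from smoothing-based callers; its counts are not
  comparable to published DMR counts.
* Wilcoxon/Kruskal-Wallis treat samples as exchangeable within groups;
  paired designs (same animal contributing both tissues) are not
  modeled.
* The amplicon workflow is reduced to ratio concordance; primer design
  and amplicon-specific biases are out of scope.
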