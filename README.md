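# methvar

Discovery of variably methylated genes and of tissue- and
location-specific methylation signatures from per-CpG bisulfite
methylation calls.

In mosaically methylated invertebrate genomes — the motivating system is
the clonal marbled crayfish — most gene bodies are stably methylated
(ratio ≈ 1) or stably unmethylated (ratio ≈ 0), and only a minority of
genes varies between animals, tissues and sampling locations. Because
the organism is clonal, such differences are purely epigenetic, and the
variably methylated gene set can act as a panel of tissue and population
signatures. `methvar` is for epigenomics researchers who have per-CpG
methylation-call tables (methratio-style TSV from a bisulfite aligner)
and want a reproducible, fully audited path from those calls to
signature genes.

## What it computes

For gene *g* with qualifying CpG set *C(g)* in sample *s*, the gene-body
methylation level is the unweighted mean of per-CpG ratios
*m\_gs = mean( meth\_i / total\_i , i ∈ C(g) )*, where a CpG qualifies
only with coverage ≥ 5X in **every** sample of the analysis set, and a
gene only with ≥ 5 qualifying CpGs. On the resulting gene × sample
matrix the package provides:

- **Variable-gene discovery**: keep genes with cross-sample variance
  > 0.006, then drop the consistently (un)methylated ones (mean ratio
  > 0.8 or < 0.2); then the **core-set cascade**: N-content ≤ 50%,
  computable averages, not in the bottom variance decile, mean level in
  (0.1, 0.9) — each stage logged in a `filter_report`.
- **Differential methylation**: Wilcoxon rank-sum (tissue contrasts,
  exact by enumeration for small tie-free samples) and Kruskal-Wallis
  (location contrasts), with step-up Benjamini-Hochberg q-values
  (*q₍ᵢ₎ = min₍ⱼ≥ᵢ₎ p₍ⱼ₎·m/j*) and significance at q < 0.05.
- **Localized DMRs**: a deterministic run-based scanner over per-CpG
  group-mean profiles (runs of CpGs with max pairwise group difference
  ≥ 0.1, ≥ 5 sites, gaps ≤ 2), plus capture-vs-amplicon CpG concordance.
- **Ordination and separation**: PCA / classical MDS of sample
  methylomes and a mean-silhouette separation score for group labels.
- **A seeded synthetic methylome generator** with ground truth
  (beta-mixture baselines, negative-binomial coverage, binomial counts,
  bisulfite non-conversion, localized logit-scale effects) for
  end-to-end validation, and bisulfite conversion-rate QC from non-CpG
  cytosines.

## Worked example

Simulate a capture-style experiment — 200 genes, 4 locations × 12
hepatopancreas samples, 10% of genes carrying a localized location
effect — and recover the signature genes:

```r
library(methvar)

params <- simulation_params(tissues = "hepatopancreas", seed = 42)
sim <- simulate_dataset(params)
#> simulated_methylome: 200 genes, 48 samples, 20 tissue-effect and
#> 20 location-effect genes

mat <- build_matrix(sim$tables, sim$genes)
#> methylation_matrix: 200 genes x 48 samples; 200 genes fully observed

compute_conversion_rate(sim$tables[[1]])
#> 0.981   # pooled over non-CpG cytosines; > 0.98 indicates good conversion

labels <- setNames(sim$samples$location, sim$samples$sample_id)
res <- differential_genes(mat, labels, test = "kruskal_wallis", alpha = 0.05)
sum(res$significant)
#> 20      # of 200 tested genes, at q < 0.05

recovery_scores(res$gene_id[res$significant], sim, "location")
#> precision    recall
#>      0.95      0.95

emb <- pca_embed(mat, gene_ids = res$gene_id[res$significant])
separation_score(emb, labels)
#> 0.72    # mean silhouette by location: clear separation
```

19 of the 20 called genes are true location-effect genes and 19 of the
20 planted effects are found; ordinating the samples on the called
genes separates the four locations with a mean silhouette of 0.72
(random gene sets of the same size score ≈ 0). The same functions run
unchanged on real methylation-call tables via `read_methylation_table()`,
`read_gene_bed()` and `read_sample_sheet()`, or through the
config-driven `run_pipeline()` (a thin command-line wrapper is in
`inst/scripts/methvar-cli.R`).

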