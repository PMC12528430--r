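# ensid

Neurochemical identity and cross-dataset annotation concordance for
enteric neuron single-cell RNA-seq data.

## The problem

Published single-cell atlases of the enteric nervous system (ENS) annotate
their neuron clusters with functional labels — inhibitory/excitatory motor
neurons (IMN/EMN), intrinsic primary afferents (IPAN), interneurons (IN),
secretomotor and sensory classes — but each study uses its own marker
lists and vocabulary, and the labels transfer poorly between datasets.
`ensid` provides the computational toolkit for asking two questions about
such data:

1. **What neurotransmitters is each neuron predicted to synthesize?**
   A *two-step neurochemical classifier*: a cell is assigned a class
   (nitrergic, cholinergic, glutamatergic, catecholaminergic, GABAergic,
   serotonergic) only if it (i) expresses the hallmark rate-limiting
   synthesis enzyme — e.g. *NOS1* for nitric oxide, *CHAT* for
   acetylcholine — and (ii) scores highly for a curated support set of
   metabolism enzymes and transport proteins (for the nitrergic class:
   *NOS1AP, ARG1/2, ASL, ASS1*), scored against expression-matched
   control genes. Cells may carry several classes; the mono/multi-
   transmitter profile is a first-class result. Because synthesis-enzyme
   transcripts are low-abundance, classification runs in parallel on
   raw-normalized and dropout-imputed expression layers.

2. **Do two datasets agree on what their clusters are?** Four
   complementary concordance methods, each producing a clusters-by-
   clusters (or clusters-by-signatures/pathways) matrix:
   - *signature module scoring* — each cluster's top-100 differentially
     expressed genes scored across the other dataset;
   - *anchor-feature Spearman correlation* — rank correlation of
     pseudobulk profiles over 3000 (or 100) shared highly variable genes;
   - *supervised label transfer* — a random forest over rank-based
     gene-pair features with a `"random"` rejection class;
   - *pre-ranked GSEA* — per-cluster enrichment over a pathway catalog,
     followed by hierarchical clustering of clusters by normalized
     enrichment score (NES) and pathway averaging within the k = 4 main
     tree groups.

The core statistics, in standard notation: the module score of gene set
*S* in cell *c* is `mean(x[c, S]) − mean(x[c, ctrl(S)])` with controls
drawn from expression-matched bins; the GSEA enrichment score is the
signed maximal deviation of the weighted Kolmogorov–Smirnov running sum
(hits weighted by `|log2FC|`, misses penalized `1/(N − n_set)`), with NES
obtained by sign-stratified gene-set permutation.

Because the published atlases are large external downloads, the package
ships a **synthetic-data generator** (`sim_config()`, `simulate_dataset()`,
`simulate_dataset_pair()`) that emulates their salient structure —
negative-binomial counts, cluster archetypes, divergent annotation
vocabularies, batch effects, dropout, and cells carrying 0–3 planted
neurotransmitter programs — so every method can be validated against a
recoverable ground truth.

## Worked example

```r
library(ensid)

cfg <- sim_config(n_cells = 1000, n_genes = 1500, n_clusters = 6,
                  anchor_programs = TRUE, seed = 1)
sim <- simulate_dataset(cfg)
ds  <- sim$dataset |> normalize_counts() |> impute_knn()

calls <- classify_neurochem(ds, layer = "imputed", seed = 1)
multiplicity_profile(calls)
#> # A tibble: 4 × 4
#>   multiplicity_bin n_cells frac_all frac_assigned
#>   <chr>              <int>    <dbl>         <dbl>
#> 1 0                     34    0.034       NA
#> 2 1                    599    0.599        0.620
#> 3 2                    322    0.322        0.333
#> 4 3+                    45    0.045        0.0466

model <- train_transfer(ds, n_per_cluster = 80, seed = 1)
glance(model)
#> # A tibble: 1 × 5
#>   n_classes n_features n_trees heldout_accuracy min_class_accuracy
#>       <int>      <int>   <dbl>            <dbl>              <dbl>
#> 1         6       1500     500                1                  1
```

The multiplicity profile says that among cells assigned at least one
neurochemical class, 62% are mono-transmitter, 33% carry two classes and
5% three — close to the planted conditional proportions (0.556, 0.333,
0.111 at the default multiplicity probabilities) given the run's modest
size. The transfer summary reports perfect held-out accuracy on this
well-separated reference; `tidy(model)` breaks it down per class, and
`autoplot()` methods draw the standard heatmaps for every concordance
matrix.

`run_pipeline(run_config(...))` chains every stage — simulate (optional),
preprocess, classify, signatures, transfer, Spearman concordance, GSEA
clustering, method-agreement report — into a directory of TSV tables with
provenance headers and an MD5 manifest; rerunning with the same seed
reproduces the manifest checksum-for-checksum.

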