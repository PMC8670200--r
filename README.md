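# phosgo

GO over-representation analysis of a phosphoproteome sample is usually run
against the whole genome. That comparison cannot tell whether a term is
enriched because of the *condition under study* or simply because the term is
enriched in *any* phosphoproteome (kinase-related terms always light up).
`phosgo` implements a contrast strategy that separates the two: the sample is
tested not only against the genome but also against a phosphoproteome
reference set, and a term is called **sample-specific** only when it is
significant in *both* sample comparisons.

It is aimed at proteomics groups analysing phosphoprotein lists (the package
normalises AGI-style locus ids, so Arabidopsis data work out of the box, but
nothing is organism-specific).

## What it computes

**Reference sets.** An experimental reference (`ExpRS`, union of published
study lists), a predicted reference (`PredRS`, per-site predictor scores
max-collapsed to gene scores — gene score = max over isoforms of max over
sites — thresholded at a resampled Youden-optimal cutoff, then OR-ensembled
across predictors), their union (`UnRS`), and the sample-augmented union
(novel sample phosphoproteins added, so the sample is contained in the
reference universe).

**Classifier evaluation.** For a gene-score table *s* against experimental
labels: confusion counts, tpr/fpr/sensitivity/specificity/precision, the ROC
curve with trapezoidal AUC, the threshold maximising the Youden statistic
*J = tpr − fpr*, and its stabilised version — the mean of *J*-optimal
thresholds over repeated 30% subsamples (5000 by default).

**Enrichment.** For each namespace, every GO term *t* is tested by the
parent-child Fisher test: with *pa(t)* the genes annotated to the union of
*t*'s parents (true-path-propagated annotations), the p-value is the
upper-tail hypergeometric probability

> P(X ≥ k),  X ~ Hypergeom(N = |pa(t)|, K = |genes(t)|, n = |sample ∩ pa(t)|)

which removes the enrichment a term inherits from its parents.
Benjamini–Hochberg FDR is applied within each namespace; significance means
FDR < 0.01.

**Contrast.** The three comparisons (sample vs genome, sample vs reference,
reference vs genome) give each term a binary significance pattern; observed
patterns become contrast groups (`CG1`, `CG2`, … ordered by BP term count).
Specific terms = significant in both sample comparisons. Each specific term
gets a **GenRatio** (percentage of its annotated genes present in the
sample) and a 2-D Wang semantic-similarity layout (classical MDS of
1 − similarity) with GenRatio-sized nodes.

## Worked example

A fully synthetic run: a toy 35-term GO DAG over an 800-gene genome, two
phosphoproteome references sharing a default-enriched term, and a sample
carrying its own planted term.

```r
library(phosgo)

dag        <- make_toy_dag(c(biological_process = 35), seed = 21)
genome_ids <- agi_ids(800)
ann        <- propagate_annotations(dag, make_toy_annotations(dag, genome_ids, seed = 22))

idx   <- build_term_index(ann, genome_ids, dag, "biological_process")
sizes <- lengths(idx$index)
mid   <- names(sizes)[sizes >= 40 & sizes <= 300]

genome <- ref_set(genome_ids, "GenRS", normalize = FALSE)
exprs  <- make_enriched_sample(ann, genome_ids, mid[[1]], 0.85, 0.30, seed = 23)
predrs <- make_enriched_sample(ann, genome_ids, mid[[1]], 0.80, 0.28, seed = 24)
et     <- make_enriched_sample(ann, ensemble_or(exprs, predrs), mid[[length(mid)]],
                               0.90, 0.15, seed = 25)

run <- run_contrast_strategy(et, exprs, predrs, genome, dag, ann)
run
#> <phosgo_run>
#>   sample: 113 genes ( 0 novel, added to the reference )
#>   reference: 487 genes; genome: 800 genes
#>   biological_process: 3 terms in the matrix, 2 specific

run$groups$groups
#> # A tibble: 3 × 3
#>   label pattern n_biological_process
#>   <chr> <chr>                  <int>
#> 1 CG1   111                        1
#> 2 CG2   110                        1
#> 3 CG3   001                        1

run$gen_ratio$biological_process
#> # A tibble: 2 × 5
#>   term       n_sample n_term ratio gen_ratio
#>   <chr>         <int>  <int> <dbl>     <dbl>
#> 1 GO:0000003       70    196  35.7      35.7
#> 2 GO:0000035       49     55  89.1      89.1
```

Reading the output: three terms were significant somewhere. The pattern
columns are (sample vs genome, sample vs reference, reference vs genome).
`CG3` (`001`) is the term both references were built around — enriched in
the phosphoproteome *per se*, correctly *not* called specific. The planted
sample term `GO:0000035` is specific (pattern `110`: the reference is not
enriched for it) with a GenRatio of 89.1%, i.e. 49 of its 55 annotated
genes are in the sample. `autoplot(run$matrices$biological_process)` draws
the binary heatmap and `autoplot(run$embedding$biological_process)` the
semantic-similarity layout.

Real data enter the same way: `parse_obo()` for the ontology,
`read_gaf()`/`read_annotation_pairs()` for annotations, `read_gene_list()` /
`build_experimental_set()` for study lists, `read_site_scores()` +
`gene_scores_from_sites()` + `classify_genes()` for predictor output.

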