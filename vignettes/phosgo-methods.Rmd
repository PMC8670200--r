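---
title: "Methods: contrast-based GO enrichment for phosphoproteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrast-based GO enrichment for phosphoproteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosgo)
```

## The problem

A phosphoproteome is, by construction, a biased draw from the genome: terms
tied to kinase signalling are over-represented in *any* set of
phosphoproteins. An enrichment analysis of a condition-specific sample
against the genome therefore mixes two signals — what the condition does,
and what phosphorylation does. `phosgo` separates them by running three
comparisons per ontology namespace and classifying every term by its binary
significance pattern across them:

1. sample vs genome,
2. sample vs phosphoproteome reference,
3. reference vs genome.

A term is **specific** to the sample when it is significant in both sample
comparisons (1 and 2). A term significant only in (3) is a property of the
phosphoproteome itself; a term significant in (1) and (3) but not (2) is
phosphoproteome background that the sample merely inherits.

## Reference sets

The reference universe for comparison (2) matters. The package builds it in
layers:

* **ExpRS** — union of published experimentally observed phosphoprotein
  lists, after id normalisation (strip `.n` splice suffixes, uppercase).
  Union-before- or after-normalisation is immaterial under set semantics;
  per-study counts are logged anyway.
* **PredRS** — predictor output. Site-level scores in [0, 1] (missing
  predictions flagged −1) are collapsed by maximum to protein scores and
  then to gene scores, thresholded, and OR-ensembled across predictors.
  Max-aggregation encodes "a single confidently predicted site makes the
  protein a phosphoprotein"; the −1 flag survives aggregation only if every
  site of every isoform is missing, and a flagged gene is never called
  positive at any threshold.
* **UnRS = ExpRS ∪ PredRS**, and the sample-augmented reference: sample
  members absent from UnRS are added before comparison (2), because the
  enrichment machinery requires the tested set to be contained in its
  universe, and a phosphoproteome reference is by definition incomplete
  until updated with newly observed phosphoproteins.

### Threshold selection

The predictor threshold is the maximiser of the Youden statistic
J = tpr − fpr on the ROC curve, stabilised as the mean of the per-subsample
optima over `n_rep = 5000` draws of `frac = 0.30` of the universe without
replacement. Design choices here:

* "maximise tpr and minimise fpr" is operationalised as Youden's J — the
  standard single-criterion reading of that pair of objectives.
* At equal J the **largest** threshold wins: the stricter classifier, in
  keeping with the high-stringency stance of the whole reference
  construction.
* Boundary inclusion is `score >= threshold`, the usual ROC convention.
* Subsamples lacking one of the two classes are redrawn rather than
  skipped, keeping the replicate count fixed; the redraw count is reported.
* The ROC curve is bracketed by a sentinel above the maximum score (nothing
  predicted) and a terminal predict-everything point, so it always runs
  (0,0) → (1,1) even when −1-flagged genes exist; those genes are negative
  at every real threshold and enter only the terminal point.

## The enrichment test

Annotations are propagated up the DAG under the true path rule, following
`is_a` and `part_of` edges (the relations the standard GO tooling
traverses; `regulates` and friends are dropped at parse time). The universe
of a comparison is restricted to *feasible* genes — those with at least one
propagated annotation in the namespace — so unannotated genes never enter
the counts.

The test is the parent-child-union variant: term *t* is conditioned on the
gene pool of the union of its parents, which removes the significance a
term would inherit merely because its parent's genes are enriched. The
intersection variant is available (`variant = "intersection"`); union is
the default because it is the default of the field's reference
implementation. The namespace root has no parents and returns p = 1 by
convention; a term whose parents' pool covers the feasible universe reduces
exactly to the classic Fisher test. Direction is one-sided
over-representation throughout. BH-FDR is applied within each namespace and
comparison separately (the three ontologies are reported separately, so
their tests are not pooled), with significance at `alpha = 0.01`.

`min_node_size` (default 1) drops terms annotating fewer feasible genes
than the cutoff *from testing*, but parent pools are always computed from
the unfiltered annotation map — a filtered parent still conditions its
children. Terms untested in one comparison score 0 in that column of the
significance matrix, with a warning.

## Pattern groups, specific terms, GenRatio

Rows of the significance matrix are the terms significant in at least one
comparison. Each observed non-zero pattern is a group; labels are ordered
by descending biological-process term count, with ties broken by the
pattern read as a binary number (descending) — an arbitrary but
deterministic rule. Three comparisons admit at most 2³ − 1 = 7 groups.

GenRatio of a term = 100 · |sample ∩ genes(term)| / |genes(term)|, with the
denominator taken from the genome-wide feasible universe (the term's full
annotation complement, not the pool of whichever comparison flagged it).
The exact rational is kept; display rounds to one decimal.

## Wang similarity and layout

Specific terms are related to each other by Wang's graph-based semantic
similarity: S-values propagate from the focal term through its ancestor
subgraph by max-product with semantic contribution weights
`is_a = 0.8`, `part_of = 0.6` (the standard Wang constants; configurable),
and the similarity of two terms is the shared ancestors' S-mass over the
two semantic values. The 2-D layout is classical (Torgerson) metric MDS on
d = 1 − sim: double-centred Gram matrix, top-2 eigenpairs, coordinates
scaled by the square root of the eigenvalue. 1 − sim is used rather than
−log(sim) because it is bounded and conventional for Wang plots.
Determinism is enforced by orienting each axis so its largest-magnitude
coordinate is positive; fit is reported as Kruskal stress-1. With fewer
than two positive eigenvalues the missing axis is set to zero with a
warning. No claim is made that coordinates match any particular published
figure — only the distance-approximation property is guaranteed, since any
rigid motion of the plane is an equally valid layout.

## The synthetic generators

Every stage is testable offline through seeded generators:

* `make_toy_dag()` grows each namespace root-down, each new term attaching
  to one or two existing terms, so acyclicity holds by construction; edge
  labels mix `is_a`/`part_of`.
* `make_reference_scenario()` produces id sets with *exact* requested
  cardinalities and overlap, at the published scale
  (13,137 / 17,156 / 12,024 / 27,655 by default), so the overlap
  arithmetic is checked exactly, not stochastically.
* `make_score_sets()` draws positive-class scores from a high Beta
  component and negatives from a low one (defaults Beta(8, 2) and
  Beta(2, 8), modes near 0.88 and 0.12), with a configurable −1 missing
  rate. Only the [0, 1] range and the missing flag are constrained by the
  data format; the bimodal Beta shape is this package's choice of a
  realistic score model.
* `make_enriched_sample()` includes planted-term genes with probability
  `effect` and all others with `background_rate`, giving tunable true
  over-representation; `effect = background_rate` yields a null sample for
  type-I checks.

What the generators do **not** emulate: correlated annotations between
related genes, study-to-study heterogeneity of the experimental lists,
predictor score miscalibration, and the long-tailed term-size distribution
of the real GO. Passing tests therefore demonstrate correctness of the
machinery and its statistical behaviour under clean conditions, not
performance guarantees on any particular organism's annotation corpus.

## Problem sizes and numerical choices

The test suite exercises: exhaustive hypergeometric-sum agreement to a
relative 1e−12 on 1,000 random instances with N ≤ 200; parent-child
agreement with a naive independent implementation on 20 random toy DAGs;
a 500-simulation null control (uniform samples of 120 from a 400-gene
universe over a 40-term DAG) requiring ≥1 false FDR call in at most 5% of
simulations; and 50-seed planted-signal recovery on a 2,000-gene universe
(effect 0.8 vs background 0.1, reference baseline 0.35) requiring ≥90%
recovery of the planted term and ≥90% exclusion of the reference-default
term. The acceptance script reruns the same designs at 200 simulations and
25 seeds. These sizes were chosen to make the Monte-Carlo bounds sharp at
interactive runtimes.

Degenerate inputs are defined, not crashed on: zero-denominator metrics
return `NA`; a term annotating the whole universe has p = 1; `k = 0` gives
the exact tail complement; all-positive or all-negative label sets refuse
ROC construction; an empty sample after universe restriction is an error;
duplicate site records collapse under max-aggregation.

## Limitations

* Gene-level only: no phosphosite-level reference or site-level enrichment.
* Over-representation only; under-representation patterns are not
  classified.
* The parent-child correction reduces, but does not eliminate, dependence
  between tests; BH-FDR is applied as if tests were independent-ish, which
  in practice is conservative here (the null control verifies the
  direction).
* Obsolete terms are kept for id lookup but never tested, propagated
  through, or used in similarity.
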