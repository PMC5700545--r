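---
title: "Ontology-guided unsupervised gene selection and multi-objective sample clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-guided unsupervised gene selection and multi-objective sample clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goMedSel)
```

## The problem

Sample clustering of expression matrices (microarray or RNA-seq, bulk
or single-cell) is dominated by the dimensionality of the gene space:
thousands of mostly redundant or uninformative genes drown the signal
that separates biological sample classes. `goMedSel` implements an
*unsupervised* feature-selection strategy that never looks at the
expression values (or any class labels) when choosing genes. Instead
it exploits the structure of the Gene Ontology: genes that share
annotation patterns participate in the same processes, so a handful of
*representative* genes — one per annotation-coherent group — can stand
in for the whole space. Sample clustering then happens in that reduced
space with a multi-objective annealer.

The method has two stages.

### Stage 1: annotation-driven gene selection

1. **Term significance.** Every GO term annotated to the study genes
   is scored with a one-sided hypergeometric over-representation test
   against a background (genome) annotation set, and terms with raw
   p-value below a threshold (default 0.5) are kept, grouped BP, MF,
   CC. The permissive default mirrors the common practice of letting
   the downstream weighting — not the significance cut — carry the
   specificity information; `threshold` and a Benjamini–Hochberg
   switch are exposed for users who want a conventional cut.

2. **Structure-based information content.** Each selected term `t`
   gets

   `Struct_IC(t) = depth(t) * (1 - log(desc(t) + 1) / log(total_terms))`

   where `depth` is the *longest* is_a path from the namespace root
   (root = 0), `desc(t)` the number of distinct descendants, and
   `total_terms` the size of the term's namespace. Deep, specific
   terms score high; a root scores 0. Only the ontology topology is
   used, so the weight is free of annotation-corpus bias. The ratio
   of logarithms makes the value independent of the log base.

3. **Annotation matrix.** The genes × terms matrix holds
   `Struct_IC(term)` where the gene is annotated with the term, and 0
   otherwise; genes mapping to no selected term are dropped. Rows are
   weighted annotation fingerprints of genes.

4. **PAM gene clustering.** Partitioning Around Medoids is run on the
   rows under three interchangeable distances (Euclidean, city-block,
   cosine) over a grid of cluster counts `K`; the grid is capped by
   the `round(sqrt(n))` rule of thumb. Every (distance, K) solution
   is scored by the silhouette index *computed under the same
   distance*, and the argmax wins. The `K` medoid genes — actual data
   points, hence actual genes — form the reduced feature set.

### Stage 2: multi-objective sample clustering

Samples (rows of the d × n_m reduced expression matrix) are clustered
by archived multi-objective simulated annealing. Each solution is a
variable-length string of cluster centers; samples are assigned to
their Euclidean-nearest center. Three cluster-validity objectives are
optimised simultaneously — Xie–Beni (minimise), PBM (maximise) and the
fuzzy c-means objective J_2 (minimise) — under Pareto domination, and
the archive keeps mutually non-dominating solutions. After annealing,
the archive member with the highest Euclidean silhouette is reported;
ties prefer fewer clusters, then lower XB.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` (enrichment) | 0.5 | raw hypergeometric p-value cut for term selection |
| `k_grid` | 5, 10, 20, … capped near √n | candidate medoid counts |
| `restarts` (PAM) | 1 | independent initialisations; ≥5 recommended for tiny n |
| `t_max`, `t_min`, `alpha` | 100, 1e-4, 0.9 | geometric annealing schedule (~131 temperature levels) |
| `iter` | 100 | perturbations per temperature |
| `hl`, `sl` | 50, 100 | hard/soft archive limits |
| `kmin`, `kmax` | 2, round(√d) | encoded cluster-count bounds for samples |
| `laplace_scale` | 1% of per-gene range | scale of the Laplace center-move noise |
| `fuzzifier` | 2 | m in J_m; m=2 admits the closed form 1/Σ d⁻² per point |

The annealing defaults (`t_min = 1e-4`, `t_max = 100`, `alpha = 0.9`,
`hl = 50`, `sl = 100`, `iter = 100`) are the reference configuration
used throughout the test suite.

## Numerical and design choices

Several pieces of the procedure are under-determined by the general
method description and were fixed as follows.

* **Ontology edges.** Only `is_a` relations contribute to depth and
  descendant counts; `part_of` and other relation types are ignored as
  the minimal safe reading of "the GO tree". Obsolete terms are
  excluded at parse time. Depth counts *edges*, with the namespace
  root at 0, so the root's information content is exactly 0.
  `total_terms` counts the term's own namespace (each of BP/MF/CC is a
  complete ontology); a `total_scope = "ontology"` switch widens it.
* **Enrichment.** Annotations are *not* propagated to ancestor terms;
  the test is the standard one-sided hypergeometric with no
  multiple-testing correction by default, matching a raw p-value cut.
* **PAM.** Swaps are steepest-descent: all (medoid, non-medoid)
  exchanges are evaluated, the best strictly-improving one is applied,
  and equal-cost swaps keep the incumbent. Nearest-medoid ties go to
  the lowest medoid index. This buys exact reproducibility at fixed
  seed. A single random start can stall in a genuine single-swap
  local optimum (~6% of tiny random instances); `restarts` runs
  multiple seeded starts and keeps the lowest cost — 5 restarts
  sufficed for global optimality on every tiny instance we audited
  against exhaustive search.
* **Silhouette.** Singleton clusters contribute 0 (standard
  convention); the index is computed with the same distance that
  produced the clustering.
* **K-grid guard.** The default grids follow the √n rule rounded up
  to the next ten (e.g. n = 2260 → grid up to 50 although √n ≈ 48),
  because usable grids in practice sit on round numbers;
  `allow_large_k = TRUE` lifts the guard entirely.
* **AMOSA acceptance.** A perturbed solution dominated by the current
  solution or archive members is accepted as the new current point
  with probability `1/(1 + exp(Δdom_avg / T))`, where `Δdom_avg`
  averages the amount of domination (product of normalised objective
  gaps) over the dominating set. Acceptance therefore approaches 1/2
  at high temperature and 0 as T → 0. Non-dominated solutions are
  always accepted and archived, evicting members they dominate.
* **Archive overflow.** Above `sl` members the archive is clustered
  by single linkage in range-normalised objective space down to `hl`,
  keeping the member nearest each cluster mean.
* **Degenerate cases.** Coincident centers, or partitions where every
  sample sits exactly on a center, make XB/PBM ill-defined; such
  solutions are marked infeasible (XB = ∞) and can never enter the
  archive. An annealing move that empties a cluster re-seeds that
  center to the sample farthest from its nearest center.
* **%CoA.** Classification accuracy maps clusters to classes by exact
  enumeration of injective-where-possible assignments on the confusion
  matrix (surplus clusters fall back to their majority class), making
  the metric invariant under any relabelling of the prediction. The
  cluster and class counts this package produces (≤ ~10) keep the
  enumeration instantaneous.
* **FCM objective.** "FCM" is read as the fuzzy c-means objective
  J_m computed from the encoded centers; a partition-coefficient
  style validity index would be a defensible alternative reading, and
  a `crisp = TRUE` switch gives the hard-assignment SSE instead.

## What the synthetic data emulates

Because real studies hinge on a live GO snapshot and external
downloads, the package ships generators that reproduce the *structure*
the method relies on, as pure functions of a seed:

* `synth_ontology()` — three namespaces, each a random rooted DAG
  (every term attaches to 1–2 existing parents), emitted as OBO text.
* `synth_annotations()` — genes partitioned into groups, each group
  sharing a disjoint block of terms, plus Poisson(1) off-block noise
  per gene: annotation-coherent gene modules.
* `synth_background()` — the study table plus uniformly-annotated
  genome genes, so block terms come out over-represented.
* `synth_expression()` — samples drawn from `k` Gaussian clusters
  whose means differ *only* on the genes of informative groups, with
  spacing `separation × noise_sd` per informative gene; other genes
  are identical noise in every cluster.

The reference conditions are 60 genes in 5 groups (3 informative), 60
samples in 3 clusters, separation 6 at noise sd 1. Under these
conditions the suite verifies that (a) the annealer recovers the
planted partition (adjusted Rand ≥ 0.9 and k = 3 in at least 4 of 5
seeds), and (b) clustering in the medoid-reduced space is never worse
in %CoA than in the full space in at least 4 of 5 seeds, with the
reduced set covering every informative group.

These generators are deliberately idealised: Gaussian expression with
cluster-constant variance, disjoint annotation blocks, and a clean
DAG. Passing tests demonstrate the machinery is correct and that the
reduction preserves planted signal; they do not demonstrate
performance on real microarray noise, batch effects, or the heavily
shared annotations of a real GO slice.

## Worked example

```{r example, eval = FALSE}
spec <- synth_spec(seed = 7)
dag  <- parse_obo(synth_ontology(spec))
ann  <- synth_annotations(spec, dag)
bg   <- synth_background(spec, dag, ann)
sx   <- synth_expression(spec, attr(ann, "gene_groups"))

report <- run_pipeline(list(
  obo = synth_ontology(spec),
  annotations = as.data.frame(ann),
  background = as.data.frame(bg),
  expression = sx$expr,
  truth = sx$labels,
  k_grid = c(3, 4, 5, 6), kinds = "euclidean", seed = 7))
report
```

The report prints the annotation-matrix shape `n × (x + y + z)`, the
winning PAM configuration with its silhouette, the medoid gene ids,
and the sample-clustering quality (silhouette, Davies–Bouldin, Dunn,
and %CoA when truth is supplied). `compare_spaces()` reruns the
annealer with identical seed and configuration on the full and reduced
matrices for a controlled paired comparison.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated
data: tiny instances (n ≤ 8) are compared against exhaustive medoid
search; enrichment p-values against full combinatorial enumeration up
to population size 20; and the two recovery studies use the reference
conditions above (60 × 60 matrices, five seeds each, full annealing
schedule). These sizes were chosen so each stage's behaviour is
verifiable by brute force or by construction.

## Limitations

* Only `is_a` edges are honoured; regulatory and partonomy relations
  are out of scope, as are corpus-based IC variants and term-to-term
  semantic-similarity measures.
* The enrichment background must be supplied by the user; with the
  study set as its own background every p-value is 1 and selection
  degenerates (the package warns).
* The annealer is stochastic: archives are reproducible only at fixed
  seed, and recovery guarantees are statistical, not per-run.
* No evidence-code filtering of GAF input is performed.
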