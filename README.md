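# RectalSubtypes

Discovery and classification of transcriptional subtypes in rectal cancer.

Rectal and colon cancers differ in biology and outcome, yet the widely used
colorectal subtyping schemes were trained mostly on colon tumours — and
rectal resection specimens often carry the transcriptional footprint of
neoadjuvant chemoradiotherapy, which pushes tumours towards a
stromal/mesenchymal state. `RectalSubtypes` implements, as a tested and
reusable R package, the complete pipeline needed to derive and apply
rectal-specific subtypes from treatment-naive expression cohorts:

* **Preprocessing** — merging multi-study log2 expression matrices on their
  common genes, duplicate-sample detection (md5 checksum or correlation at
  r ≥ 0.999 with transitive closure), quantile normalisation, and a
  deterministic per-gene location–scale batch correction.
* **Consensus clustering** — Monti resampled hierarchical clustering on the
  1 − Spearman sample distance; the number of clusters k is chosen by the
  deltaK criterion, the relative increase of the area A(k) under the
  consensus CDF: Δ(2) = A(2), Δ(k) = (A(k) − A(k−1))/A(k−1), with an
  algorithmic elbow rule and silhouette/PCA diagnostics.
* **Gene-module discovery** — pairwise ANOVA selection of subtype-separating
  genes (BH-FDR over the union of comparisons), an unsigned power adjacency
  A = |ρ|^β on Spearman similarity with scale-free β selection, connectivity
  restriction, topological overlap dissimilarity
  TOM(i,j) = (Σ_u a_iu a_uj + a_ij)/(min(K_i, K_j) + 1 − a_ij),
  dendrogram cuts swept over k = 5..101, and optional hypergeometric
  gene-set pruning with a 5-gene module floor.
* **Subtype classifier** — gradient-boosted trees (multiclass softmax) on
  module-median scores of gene-wise z-scored expression: one robust feature
  per module, tolerant of partial gene coverage, with stratified 5-fold CV
  and per-class one-vs-rest AUC; models serialise to a portable JSON archive.
* **Survival and treatment shift** — Kaplan–Meier product-limit estimates,
  the k-group log-rank test, the stage-3 imputation rule for records with
  nodal involvement and no metastasis, and pre/post-treatment subtype
  transition tables.
* **Synthetic cohorts** — a generator planting correlated gene modules,
  subtype mean shifts, batch effects, per-subtype exponential survival and
  matched pre/post pairs with stromal activation, so every claim above is
  testable end-to-end without patient data.

## Worked example

A full discovery run on the default synthetic cohort (180 samples,
2000 genes, 12 planted modules, 3 subtypes, 4 batches):

```r
library(RectalSubtypes)

res <- runDiscovery(runConfig(outDir = "rss_run", seed = 1))
deltaKTable(res$consensus)
#>   k      area      delta
#> 1 2 0.4455246 0.44552465
#> 2 3 0.6722243 0.50883756
#> 3 4 0.6791992 0.01037588
#> 4 5 0.6860321 0.01006010
#> 5 6 0.6968994 0.01584085
#> 6 7 0.7108810 0.02006255
#> 7 8 0.7268728 0.02249582
kSelected(res$consensus)
#> [1] 3
```

The deltaK curve spikes at k = 3 (Δ = 0.51) and collapses at k = 4
(Δ = 0.01): three subtypes. Module discovery on the subtype-separating
genes and 5-fold CV of the boosted classifier on module medians:

```r
res$modules
#> GeneModuleSet: 5 modules, 426 genes assigned, 0 unassigned
#>   sizes: 120, 101, 98, 76, 31
cvMetrics(res$model)
#>   fold  accuracy
#> 1    1 0.9729730
#> 2    2 0.9444444
#> 3    3 0.9444444
#> 4    4 0.9722222
#> 5    5 0.9142857
```

Every fold classifies more than 91% of samples correctly. Applying the
trained model back to the cohort together with its follow-up data yields a
survival report by predicted subtype:

```r
out <- runClassification(res$model, res$corrected, clinical = clin,
                         outDir = "rss_classify")
out$logrank
#> log-rank chi-square = 18.21 on 2 df, p = 0.000111
```

The three predicted subtypes separate in disease-free survival, with the
planted good-prognosis group (hazard 0.02/month) observing 54 events against
34.4 expected — the prognostic ordering the generator planted (the group
labels RSS1/RSS2/RSS3 are arbitrary cluster names; the mapping to planted
subtypes varies with the seed).

Matched pre/post-treatment pairs are simulated with
`generateTreatmentPairs()` and tabulated with `subtypeShiftTable()`; with
the default stromal activation of 1.5 log2 units, more than half of the
post-treatment samples classify into the stromal subtype.

## Package layout

S4 classes follow Bioconductor conventions: `RectalCohort` (extends
`SummarizedExperiment`), `CohortConfig`, `ConsensusResult`,
`NetworkMatrices`, `GeneModuleSet`, `ModuleScoreMatrix`, `SubtypeModel`,
`TransitionTable`, each with validity checks, accessors and `show` methods.
The methods vignette (`vignettes/rectal-subtyping-methods.Rmd`) documents
the models, parameter choices, numerical conventions and limitations.
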