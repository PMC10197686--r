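# gcdecay

Multimodal mRNA regulation analysis for paired RNA-seq / Ribo-seq
time courses, SLAM-seq labeling and high-resolution coverage profiles —
built around the observation that when translation of an mRNA is acutely
suppressed (for example after depleting a translation-promoting RNA
helicase), a subset of those untranslated mRNAs is subsequently
*stabilized*, and that the GC content of the coding sequence (GCcds) is the
dominant transcript feature predicting which ones.

The package is aimed at computational biologists analysing degron/knockdown
time courses with paired expression and translation readouts. It provides:

* **`te_test()`** — translation-efficiency testing. Counts are modelled per
  gene as NB(μ, α) with log link and median-of-ratios size factors; the
  assay type (RNA-seq vs Ribo-seq) enters as a covariate and TE regulation
  is the likelihood-ratio test of the `condition:assay` interaction against
  a reduced model without it, at FDR 0.05 (BH). Dispersion: Cox–Reid
  adjusted ML per gene, MAP-moderated toward a mean–dispersion trend.
* **`classify_coordinate_groups()` / `vector_field()`** — the x / y / xy /
  −xy taxonomy on the (RNA log2FC, Ribo log2FC) plane and the 70×70 binned
  field of fold-change dynamics between consecutive timepoints.
* **`region_features()` / `partition_by_gc()`** — per-gene predictor table
  (GC content, log-length and read density per transcript region, 61
  sense-codon frequencies, codon-position GC, baseline TE, mature-RNA
  level) and equal-width GCcds partitions with Wilcoxon group tests.
* **`fit_rf_cv()` / `fit_lasso_cv()`** — Random Forest and Lasso under
  5-fold CV with held-out permutation importance (mean decrease in
  accuracy) and standardized-coefficient selection.
* **`count_tc_reads()` / `stability_test()`** — SLAM-seq T>C conversion
  counting (strand-aware, ≥1 conversion per read) and the NB-GLM stability
  LRT with labeling + degron covariates and log-total-read offsets.
* **`detect_start()` / `coverage_stats()` / `compare_classes()`** — the
  5′-end coverage-decay statistic: min/max-normalized coverage, start = the
  first position above 0.15, a 250 nt window around the pooled start, and
  per-transcript regression betas compared across stabilized / degraded /
  control classes by one-sided Wilcoxon tests (with a 3′-end negative
  control).
* **`sim_config()` + `simulate_*()`** — a synthetic-data generator that
  plants the whole structure (NB counts over a 4–48 h two-condition design,
  translation suppression preceding GC-dependent RNA stabilization,
  receding 5′ coverage boundaries, decaying T>C fractions), so the entire
  cascade is testable without sequencing data.
* **`run_pipeline()` / `report()`** — one-call orchestration with a
  reproducibility manifest (seed, config, per-stage counts, checksums).

## Worked example

```r
library(gcdecay)

cfg    <- sim_config(n_genes = 800, seed = 7)
ann    <- simulate_annotation(cfg)
truth  <- simulate_ground_truth(cfg, ann)
counts <- simulate_counts(cfg, ann, truth)

te <- te_test(counts, timepoint = 48)
table(te$class)
#>      NS TE_down   TE_up
#>     598     119      83
head(te[order(te$padj), ], 3)
#>     gene_id log2fc_rna log2fc_ribo log2fc_te       pvalue         padj class
#> 98   G00098 -1.1194550    1.335147  2.454602 4.507561e-16 1.803024e-13 TE_up
#> 386  G00386 -1.3110119    1.181963  2.492975 4.161843e-16 1.803024e-13 TE_up
#> 278  G00278 -0.8204673    1.512894  2.333361 8.870674e-15 2.365513e-12 TE_up
```

`log2fc_te` is the interaction term — the change in translation efficiency;
for these genes ribosome occupancy rises while mRNA falls, the classic
anticorrelated (−xy) pattern. Predicting the RNA response of the TE_down
class from transcript features recovers the planted GCcds dependence:

```r
rna  <- assay_test(counts, "RNA", 48)
feat <- region_features(ann, counts)
down <- te$gene_id[te$class == "TE_down"]
fd   <- feat[feat$gene_id %in% down, ]
rf   <- fit_rf_cv(fd, rna$log2fc[match(fd$gene_id, rna$gene_id)], seed = 7)
head(rf$importance, 3)
#>       feature  importance          sd rank
#> 1       GCcds 0.060114766 0.024126258    1
#> 2 codonfr_CGC 0.014206367 0.006316303    2
#> 3      GCpos2 0.008253123 0.006184944    3
rf$performance[is.na(rf$performance$fold), ]
#>   fold   pearson  spearman
#> 6   NA 0.8855379 0.8781107
```

GCcds ranks first by held-out permutation importance and the model explains
most of the held-out variation (Spearman r ≈ 0.88) — the feature-importance
signature of GC-dependent stabilization.

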