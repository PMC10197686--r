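---
title: "Models and methods behind gcdecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gcdecay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`gcdecay` implements an analysis cascade for multimodal mRNA regulation
observed when an RNA-binding protein is acutely depleted (e.g. by an
auxin-inducible degron) and the transcriptome is profiled by paired RNA-seq
and Ribo-seq along a time course, complemented by SLAM-seq metabolic
labeling. The cascade asks three questions: which genes change their
translation efficiency (TE); which transcript features predict the
accompanying mRNA-level changes; and whether the stabilized transcripts show
the coverage signature of suppressed 5'→3' exonucleolytic decay. Every stage
runs end-to-end on synthetic data with a planted GC-dependent stabilization
signal, so the whole pipeline is testable without sequencing data.

# The negative-binomial GLM core

Counts for gene $g$ in sample $j$ are modelled as
$K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g)$ with
$\mathrm{Var} = \mu + \alpha\mu^2$ and
$\log \mu_{gj} = x_j^\top \beta_g + \log s_j$, where $s_j$ are
median-of-ratios size factors. The TE test stacks both assays and fits

$$\sim \text{condition} + \text{assay} + \text{condition:assay}$$

against the reduced model without the interaction, i.e. assuming the two
assays respond identically; the likelihood-ratio statistic is referred to
$\chi^2_1$ and BH-adjusted, with TE_up/TE_down assigned by the sign of the
interaction term at FDR < 0.05. Per-assay condition effects
(`assay_test()`) use the same machinery with `~ condition` vs `~ 1`.

Dispersion estimation is the numerically delicate part at small sample
sizes. We use gene-wise maximum likelihood with the Cox–Reid adjustment
$-\tfrac12 \log\det(X^\top W X)$, then a second maximum-a-posteriori pass
with a log-normal prior centred on a fitted mean–dispersion trend
$\alpha(\bar\mu) = a_0 + a_1/\bar\mu$. The prior variance is the robust
(MAD-based) spread of the gene-wise estimates around the trend minus the
expected sampling variance $\psi'((n-p)/2)$ of a log-dispersion estimate at
the design's residual degrees of freedom, floored at 0.05. The MAP pass is
what keeps boundary estimates ($\hat\alpha \to 0$ whenever the within-group
variance falls below the Poisson expectation, which happens for a
substantial fraction of genes at $n = 8$) from collapsing and inflating the
LRT; type-I error and p-value uniformity under null simulations are asserted
by the test suite rather than assumed.

For the SLAM stability test the offsets are gene-specific
($\log$ total reads) and expected counts differ by more than an order of
magnitude between labeled and unlabeled samples, so a cross-gene
mean–dispersion trend is not meaningful. There, genes are rank-binned by
mean conversion fraction (the quantity that drives the effective
overdispersion) and each bin receives the dispersion maximizing its summed
Cox–Reid profile likelihood. Gene-wise ML would be slightly anticonservative
and a DESeq2-style trend prior markedly conservative on this design; the
binned common dispersion sits in between and calibrates best in our null
simulations. The residual type-I error of the $\chi^2_1$ approximation at
eight samples (a little under 0.06 for any member of this test family) is an
inherent small-sample property, not a tuning target.

# Regulation taxonomy and the binned vector field

Genes on the (RNA log2FC, Ribo log2FC) plane are labelled `x` (RNA-level
change only), `y` (ribosome-occupancy only), `xy` (both, concordant) or
`-xy` (both, anticorrelated — the stabilized-yet-suppressed class), with
"changing" defined as per-assay significance at FDR < 0.05 and an optional
|log2FC| margin (default 0). The membership rule is this package's
convention; the original figure conveys it graphically only.

The fold-change dynamics are summarized on a 70×70 grid (data-driven,
symmetric range): for each transition between consecutive timepoints, the
genes occupying a cell at the earlier timepoint contribute their mean change
in RNA and Ribo log2FC plus their mean GCcds. Only genes with a significant
TE change at the final timepoint enter the field.

# Transcript features

`region_features()` builds one row per gene: log2 TPM, baseline TE
(log2 Ribo/RNA control ratio), mature-RNA level (log2 length-normalized
exon:intron RNA density ratio), and per region — 5'UTR, ±25 nt windows
around the start and stop codons, CDS, non-coding internal exons, introns,
3'UTR — GC content, log10 length and RNA/Ribo read density, plus 61
sense-codon frequencies, GC at the three codon positions, and an optional
external codon-optimality score. The start/stop windows are ±25 nt on
either side of the codon (the source text is ambiguous between 25 nt total
and per side; the width is configurable). N bases are excluded from GC
denominators. Genes lacking a region receive defined sentinels (density 0,
GC 0, log-length −1) instead of NAs, so downstream models see a complete
matrix; zero-variance columns are dropped with a warning at fit time.

GC partitions (`partition_by_gc()`) cut the GCcds **range** into
equal-width groups by default, matching `cut()` semantics; an
equal-frequency option exists. Pairwise group differences use two-sided
Wilcoxon rank-sum tests, skipping groups of fewer than two genes.

# Feature importance

The Random Forest (500 trees, p/3 candidate split variables — the
regression defaults) and the Lasso run under an outer 5-fold
cross-validation. Importance is measured on the held-out fold: for the
forest, the increase in held-out MSE when one feature column is permuted
(the regression realization of mean decrease in accuracy), averaged over
folds; for the Lasso, coefficients on standardized predictors at the
regularization strength chosen by inner CV (`lambda.1se` by default — the
parsimonious conventional choice for feature selection; `lambda.min` is
available). Scaling parameters come from training folds only; the held-out
scaled column means are retained so leakage can be audited. Per-class models
are fitted independently (the source leaves this open; independent fits keep
the classes' error structures separate).

# SLAM-seq conversion counting

A read is converted when it carries at least one T-in-reference→C-in-read
mismatch on the transcript strand (genomic A→G for minus-strand genes); the
minimum-conversion count is configurable but defaults to 1, matching the
binary "reads harboring T>C mutations" notion. Reads without mismatch
information are excluded and counted. MAPQ/base-quality filtering and SNP
masking are upstream concerns of alignment processing; the package consumes
alignment records or precomputed conversion tables.

# The 5' coverage-decay statistic

Per-transcript coverage vectors are min/max-normalized (a `max_only` switch
reproduces the divide-by-maximum variant) and the coverage start is the
first 5'→3' position above 0.15. The pooled-sample start anchors a 250 nt
window (±125 nt, clipped to the transcript) in which normalized coverage is
averaged per sample and expressed as log2FC against the control mean; when
the control mean is zero the smallest positive normalized value of the
transcript guards the ratio while preserving ordering. Two summaries follow:
`beta_start`, the OLS slope of treated start positions over the timepoint
index (intercept included), and `beta_cov`, the slope of the windowed log2FC
series with the intercept omitted because the series starts at a structural
zero. Two-condition designs bypass regression and use plain
treated-minus-control differences. The ordinal timepoint index is the
default abscissa (hours are available) because the design's spacing is
uneven and the source fits a plain linear model. The identical machinery run
from the 3' end serves as negative control. Window width 250 nt follows the
methods text (300 nt appears once elsewhere and is available via
`cov_window`); start-detection thresholds 0.05–0.30 give the same
qualitative results in the test suite's robustness loop.

Classes for comparison are the 250 most stabilized and degraded genes by
RNA-seq p-value (stable sort by p, then decreasing |log2FC|) plus 1500
controls sampled from genes with p > 0.2 and TPM > 3, all scaled down
proportionally on smaller datasets; one-sided Wilcoxon tests compare betas
(stabilized > control and degraded < control for coverage betas; reversed
for start-position betas, since stabilized starts recede more slowly).

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions everywhere in the package.

* **Design**: two conditions (control, treated) × timepoints 4, 8, 16, 24,
  48 h × 2 replicates × two assays; 4000 genes by default (tests and the
  acceptance script state the sizes they use, chosen to keep stage runtimes
  in seconds-to-minutes on one CPU).
* **Annotation**: one transcript per gene — 5'UTR 50–300 nt, CDS of 100–500
  internal codons (ATG start, stop end, no internal stops), 3'UTR 100–500
  nt, 0–2 introns of 100–1000 nt. Target GCcds is uniform on 0.35–0.75;
  codon-position GC targets get independent jitter (±0.06 at positions 1–2,
  ±0.18 at the wobble position), emulating codon-usage-driven positional GC
  variation so positional GC correlates with, but does not duplicate,
  GCcds. Realized GCcds is recorded as ground truth.
* **Classes and effects**: 15% TE_down, 10% TE_up. The delta-TE magnitude
  is uniform on 1.2–2.0 log2 units from the first timepoint. The RNA
  response is delayed by a hard 12 h onset lag and its amplitude for
  TE_down genes is $\max(0.1,\ 1.25 + 5\,(\mathrm{GCcds} - 0.55))$ log2
  units — the planted monotone GC dependence (5 log2FC per GC unit is the
  default `gc_effect_size`; the source reports no effect magnitudes, so
  these are free simulation parameters, not calibrated values). TE_up genes
  lose RNA by a GC-independent 0.6–1.2 log2 units. Ribo-seq trajectories
  are RNA + delta-TE, so the assays anticorrelate for regulated genes.
* **Counts**: NB with shared dispersion α = 0.02 and log-normal baselines
  (median 300); library-size factors U(0.7, 1.3) exercise normalization.
  Control reads are also allocated multinomially across regions
  (length × assay-affinity weights; footprints concentrate in the CDS,
  intronic signal is RNA-only) so density features carry real sampling
  variation.
* **Coverage**: plateau (50×) with a 50 nt 5' ramp whose onset recedes by
  15 nt per timepoint step under control turnover, ×0.4 for stabilized and
  ×1.6 for degraded genes under treatment; fixed 3' end; Poisson noise.
  The linear ramp keeps the 0.15-threshold crossing analyzable in closed
  form.
* **SLAM**: saturating 24 h labeling (initial converted-read fraction 0.6,
  background 0.02), 8 h chase, half-lives log-normal (median 6 h), doubled
  under depletion for stabilized genes and ×0.6 for destabilized ones.
  Conversion fractions receive replicate-level log-normal noise (CV 0.15,
  the labeling/chase efficiency differences real cultures show) before the
  per-read Bernoulli conversion draw; without it the binomial counts would
  be under-dispersed relative to any count model with variance ≥ Poisson.

What the generator does **not** emulate: GC-dependent library bias, isoform
mixtures, positional coverage biases of real protocols, transcriptional
bursting, batch structure, or correlated gene modules. Passing tests
therefore demonstrate internal statistical correctness of the cascade —
calibration, parameter recovery, directional agreement — not robustness to
those real-data artifacts.

# Numerical choices and degenerate inputs

* All-zero genes are excluded from GLM fits and reported; non-converged
  IRLS fits restart from Poisson coefficients and are flagged.
* Flat coverage profiles have no defined start and exclude the transcript;
  windows falling entirely outside a transcript do the same.
* Isoform ties break by longer transcript, then lexicographic id.
* Constant regression targets yield the null Lasso model (all coefficients
  exactly zero) rather than an error.
* Determinism: every stochastic step derives from the `sim_config` seed
  (stage offsets keep streams independent); fitted pipelines with equal
  configs reproduce byte-identical outputs, which the manifest's checksums
  make auditable.

# Known limitations

The dispersion moderation is a deliberate simplification of full
empirical-Bayes machinery; its calibration is demonstrated on the
generator's conditions only. The χ²₁ LRT retains a small anticonservative
bias at eight samples. Region read densities for real data require a
region-level counter upstream; the package's own region counts come from
the generator. BAM/MD-tag traversal for conversion counting is out of
scope — alignment records or conversion tables are the entry point.
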