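---
title: "Signature scoring, stratification and auxiliary quantifications: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature scoring, stratification and auxiliary quantifications: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcosig)
```

## The analysis this package implements

Bulk expression cohorts of soft-tissue sarcomas (embryonal and alveolar
rhabdomyosarcoma, undifferentiated pleomorphic sarcoma, and normal muscle)
can be interrogated with *directional gene signatures*: named gene sets in
which each gene is tagged up (+1) or down (-1) for the biological state the
set summarizes — Met pathway activity, satellite-cell identity, fibroblast
identity. `sarcosig` implements the full desk-side workflow around such
signatures:

1. **Scoring.** The score of sample $s$ under signature $\Sigma$ is the
   signed algebraic sum
   $$S(s) \;=\; \sum_{g \in \Sigma} d_g\, x_{gs},$$
   where $x_{gs}$ is normalized log-scale expression and
   $d_g \in \{+1,-1\}$. Normalization itself (e.g. RMA) is out of scope:
   the matrix is assumed log-scale and normalized on input.
2. **Stratification.** Samples are ranked by score; the top fraction
   (default 25%) is selected and subtype enrichment inside the selection is
   tested with the one-sided hypergeometric upper tail
   $p = P(X \ge k)$, $X \sim \mathrm{Hyper}(N, K, n)$. The same test is
   applied to the overlap of two selections (Venn-style) and, per cluster,
   to subtype composition after hierarchical clustering of samples on the
   signature genes.
3. **Signature construction.** Signatures can be built by translating a
   mouse gene set into human identifiers through a homolog map, by
   intersecting two source signatures, or by differential expression
   between two groups with Benjamini–Hochberg selection at an adjusted-p
   cutoff (default 0.05), and can be restricted to the genes actually
   present on a platform.
4. **Auxiliary quantifications.** qPCR standard-curve relative copy number
   (target vs control locus, normalized to a non-amplified reference
   sample), FISH per-cell signal summaries (target/centromere ratio,
   percent of cells with more than 4 target signals, mean target signals
   per cell), and z-scores of a gene's expression against a normal-tissue
   panel.
5. **Synthetic data.** Generators for expression cohorts with planted
   additive signature shifts, qPCR plates with planted copy numbers, and
   FISH cell tables, all with explicit seeds and returned ground truth, so
   every downstream stage is testable without external data.

## Models, parameters and defaults

### Scoring

The default score is the raw signed sum of normalized log expression —
exactly the "algebraic sum" definition. Because cross-gene scale differences
can dominate a raw sum, `signature_score(..., standardize = TRUE)` first
standardizes each used gene row to mean 0 / sd 1 across samples (n−1
denominator everywhere in this package); whether the original box-plot
analyses used raw or standardized values is not knowable from the source, so
both modes are first-class and the default follows the stated wording.
Signature genes absent from the matrix are skipped and reported as a
coverage fraction, never silently. Ranks break ties by sample id in
C-locale order so stratification is reproducible across platforms.

### Top-fraction selection

"Top 25%" is read inclusively: the selection size is
$\lceil f\,n \rceil$ (e.g. 34 of 134), with `size_rule = "floor"`
available. Boundary ties are resolved by the deterministic rank order.

### Hypergeometric enrichment

The upper tail is accumulated in log space via `lchoose`, so cohorts of
hundreds of samples cannot overflow; the implementation is deliberately
independent of `stats::phyper` because the test suite checks it against an
exhaustive enumeration oracle over all $\binom{N}{n}$ draws for every
$N \le 12$. Enrichment is over-representation only (one-sided); depletion
is never tested. Across a clusters-by-labels annotation table no multiple
testing correction is applied by default (raw per-test p-values, as usually
starred on cluster heatmaps); BH across the table is available via
`annotate_clusters(..., adjust = TRUE)`.

### Clustering

`cluster_samples()` standardizes the signature-gene rows, computes
Euclidean distances between sample columns and applies complete-linkage
agglomeration (`stats::hclust`), cutting the tree to exactly `k` clusters
(default 5, the subdivision that separates normal muscle from tumors in the
cohorts this analysis style targets). The source analysis names the
clustering function but neither the metric nor the linkage; Euclidean /
complete / standardized rows is the common default for this style, and all
three choices are flags. Correctness is established against an
independently coded naive $O(n^3)$ agglomerative oracle (merge heights and
the partition after every merge).

### Differential-expression signatures

The in-package DE test is an ordinary two-sample t (pooled variance by
default, Welch selectable) followed by the BH step-up, selecting genes with
adjusted $p \le \alpha$ and assigning direction by the sign of the mean
difference, with no fold-change cutoff. This is an explicit substitute for
the moderated-t pipelines used on the original arrays: moderated variance
shrinkage is not reimplemented, so at very small group sizes this test is
less powerful than limma-style machinery — a documented, intentional
limitation. Zero-variance genes get $p = 1$ when the group means are equal
and are flagged (`degenerate`) otherwise.

### Homolog mapping and signature overlap

One-to-many homolog mappings default to `policy = "expand"` (union of all
targets), which preserves maximal overlap power; `"unique_only"` keeps only
1:1 sources and reports the ambiguous ones. Unmapped genes are always
reported, never dropped silently. When two signatures are intersected,
genes whose directions disagree cannot be assigned a sign and are dropped
with a warning (and returned in the `discordant` attribute); whether the
original satellite-signature overlap retained direction from one source or
required concordance is not stated in the source, so concordance is this
package's documented choice.

### qPCR relative copy number

Standard curves are least squares fits of $Ct = a + b\,\log_{10} q$;
efficiency is $10^{-1/b} - 1$. Quantities are
$q = 10^{(Ct - a)/b}$; the relative copy number of sample $s$ is
$$\frac{(q_T/q_C)_s}{(q_T/q_C)_{\mathrm{ref}}},$$
so the non-amplified reference sample is exactly 1 and no diploid ×2
scaling is applied. Technical replicates are collapsed by mean Ct *before*
the quantity transformation (replicate handling is not stated in the
source; averaging on the Ct scale is the conventional choice). A constant
Ct offset applied to all wells of one assay — standards included — is
absorbed by the refitted curve, which the suite asserts.

### FISH summaries

The target/centromere ratio is the ratio of means (population-level
convention); mean of per-cell ratios is available behind
`ratio_method = "mean_of_ratios"`. The "percent of cells with more than 4
target signals" is strict (`> 4`, asserted with boundary cells at exactly
4). Fewer than 100 scored cells triggers a warning, matching the scoring
convention of counting at least 100 tumor cells.

## The synthetic-data generator: what it emulates, and what not

`simulate_expression()` draws per-gene baselines
$\mathcal{N}(\mu_0, \sigma_0^2)$ (defaults $\mu_0 = 7$, $\sigma_0 = 1$,
typical mid-range normalized log2 array values), adds
$d_g\,\delta$ to the genes of a planted signature in the chosen subtype,
and adds i.i.d. Gaussian noise ($\sigma = 1$ by default). This emulates the
structure the pipeline consumes — multi-subtype cohorts, per-gene
baselines, additive subtype shifts on signature genes — and deliberately
not probe-level intensities, batch effects, gene–gene correlation, or
heavy-tailed noise. A green recovery test therefore establishes that the
pipeline detects additive shifts of the stated size under Gaussian noise;
it does not establish fidelity to any real cohort's effect sizes, which the
source does not report. Defaults were chosen once for realistic scale and
test power and are not tuned against outcomes. All randomness in one call
is drawn under a single seed in a fixed documented order (baselines, then
noise, column-major), making outputs byte-identical for identical
config+seed; signature genes missing from the configured universe are
appended so planted effects are always realizable.

## Numerical and statistical choices worth knowing

- **Discrete p-values and the null calibration check.** The top-quartile
  enrichment statistic is discrete: at $N = 120$, $K = 60$, $n = 30$ the
  p-value takes ~31 values with central gaps near 0.17. A
  Kolmogorov–Smirnov test of such p-values against the *continuous* uniform
  rejects with certainty at any usable replicate count — not a bug but a
  property of discrete tests. The calibration check in the acceptance suite
  therefore compares the empirical p-value distribution over 1000 null
  replicate cohorts with its *exact discrete null* (the p-value of
  $k \sim \mathrm{Hyper}(120, 60, 30)$), using a Monte-Carlo 1% critical
  value drawn from that null. Superuniformity (conservatism) of the
  discrete test is inherited, not removed: no mid-p correction is applied.
- **Noisy CNV recovery tolerance.** With 0.1-Ct Gaussian well noise the
  per-sample relative error of recovered copy number has spread around 10%,
  so the "within 15%" recovery contract is asserted on the mean and median
  absolute relative error over 100 simulated samples, not on the per-sample
  maximum (which would fail under any correct implementation).
- **Degenerate inputs.** Zero signature coverage, empty score tables,
  all-zero centromere counts, degenerate normal panels (sd 0), groups of
  fewer than 2 samples and non-finite curve parameters are errors; zero
  variance under standardization and sub-100-cell FISH tables are warnings
  with defined behavior.
- **Tie-breaking.** Everywhere a deterministic order is needed (ranking,
  top-fraction boundaries, dominant-label ties) the rule is lexicographic
  by id/label, stated in the function documentation.

## A worked example

```{r example}
sig <- gene_signature("met", sprintf("gene_%04d", 1:40), 1L)
cfg <- cohort_config(
  n_genes = 200,
  subtypes = c(ERMS = 30, ARMSp = 20, MUSCLE = 10),
  noise_sd = 1,
  planted_effects = data.frame(signature = "met", subtype = "ERMS",
                               delta = 0.8),
  seed = 42
)
sim <- simulate_expression(cfg, list(sig))

scores <- signature_score(sim$expr, sig)
top <- top_fraction(scores, 0.25)
erms <- sim$annotation$sample_id[sim$annotation$subtype == "ERMS"]
hypergeometric_enrichment(
  k = length(intersect(top, erms)), K = length(erms),
  n = length(top), N = nrow(scores), category = "ERMS"
)

v <- setNames(scores$score, scores$sample_id)
compare_scores(v[erms], v[setdiff(names(v), erms)], tails = 1)

ca <- cluster_samples(sim$expr, sig, k = 3)
head(annotate_clusters(ca, sim$annotation)[, c("cluster", "label", "k",
                                               "n", "p", "dominant")])
```

## Known limitations

- No moderated-variance DE, no GSEA/ssGSEA-style rank statistics, no
  survival association, no consensus clustering or data-driven choice of
  `k`.
- The simulator does not generate probe-level array data, batch structure,
  or read-level RNA-seq; conclusions from simulation transfer to real
  cohorts only insofar as the additive-shift Gaussian model does.
- Array-CGH segmentation and image-level FISH spot counting are upstream of
  this package: it consumes count and Ct tables, not images or raw arrays.
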