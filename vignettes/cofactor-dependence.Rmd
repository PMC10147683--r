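---
title: "Identifying cofactor-dependent transcription factor targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cofactor-dependent transcription factor targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

A transcription factor (TF) that drives a program such as the
epithelial–mesenchymal transition (EMT) rarely acts alone: chromatin
cofactors can be required for the TF to activate specific target genes.
`cobindep` implements the integrative analysis that identifies those
cofactor-dependent targets from three data modalities:

1. a **2×2 factorial expression experiment** — control versus cofactor
   knockdown genotype (`SCR`/`KD`), crossed with untreated versus induced
   state (`Con`/`Dox`, e.g. doxycycline-driven TF overexpression);
2. **ChIP-seq peak sets** for the TF and the cofactor, in the induced
   state and after cofactor knockdown;
3. a **multiplexed (TMT) interactome experiment** comparing bait
   pull-downs against IgG controls in both states.

The central statistic is the **knockdown impact score**. For each gene,
let $\mathrm{lfc}_{\mathrm{SCR}}$ be the induction log2 fold change in
the control genotype (induced vs untreated) and
$\mathrm{lfc}_{\mathrm{KD}}$ the same contrast in the knockdown. Then

$$\mathrm{IS} = \mathrm{lfc}_{\mathrm{KD}} - \mathrm{lfc}_{\mathrm{SCR}}.$$

A negative IS means the knockdown attenuates activation (or enhances
repression). A gene is called a direct cofactor-dependent TF target when
all three of the following hold:

* it is **UP** upon induction in the control genotype
  (adjusted $p \le \alpha$ and fold change $\ge$ the threshold);
* its activation is impaired: $\mathrm{IS} \le -\log_2(1.5)$, i.e. at
  least a 1.5-fold reduction in activation;
* a **co-bound peak** (TF and cofactor intervals sharing at least one
  base) lies within the annotation window of its TSS.

## Pipeline stages and their parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `alpha` | 0.05 | — | adjusted-p cutoff for UP/DOWN calls |
| `fc_threshold` | 1.5 | linear FC | induction fold-change cutoff |
| `is_cutoff` | $-\log_2(1.5) \approx -0.585$ | log2 | impaired-activation cutoff |
| `window` | 10000 | bp | nearest-TSS annotation window |
| `promoter_halfwidth` | 3000 | bp | promoter class around each TSS |
| `qplex_lfc_cut` | 0.5 | log2 | bait-vs-IgG enrichment cutoff |
| `qplex_alpha` | 0.05 | — | adjusted-p cutoff for interactome calls |
| `pseudocount` | 1 | counts | added before log2 in the DE surrogate |

Threshold conventions are applied **inclusively** (`>=`/`<=`) for fold
changes and impact scores, and the thresholds used are recorded in the
output attributes, so a run is always self-describing. The `alpha`
comparison for interactome calls is strict (`<`), matching the
convention the thresholds were defined with.

**Differential expression.** The built-in DE stage is a deliberate
surrogate, not a reimplementation of a negative-binomial GLM: counts are
normalized by median-of-ratios size factors (rescaled to geometric mean
1), log2-transformed with a pseudocount, and contrasted per gene with a
Welch two-sample t-test plus Benjamini–Hochberg adjustment. Externally
produced DE tables (e.g. from DESeq2) enter through
`read_contrast_table()` with an identical schema, and every downstream
stage is agnostic to the source. The surrogate reports unshrunken fold
changes; if a caller supplies shrunken estimates, the impact score
simply inherits them — no rescaling is applied.

**Peak logic.** All coordinates are 0-based half-open; two intervals
overlap iff they share at least one base. Co-occupancy uses
unique-report semantics (each query interval reported once with its
original coordinates), so it is asymmetric at the peak level; the
gene-level co-bound set is made symmetric by unioning both query
directions. Condition-specific peaks are presence/absence calls
(`a_only` / `b_only` / `common`), a deliberate simplification of
signal-based differential binding: signal tracks are out of scope, and
the interval-level comparison is what the target-selection logic
consumes. Peaks are annotated to the gene minimizing
|midpoint − TSS| when that distance is at most `window`; exact ties go
to the lexicographically smaller gene id; midpoints are used because
plain BED files carry no summits. The promoter context is
TSS ± 3 kb, the conventional promoter class; gene-body classification
is available when gene spans are supplied and otherwise everything
non-promoter is distal.

**Enrichment statistics.** The exact multi-set intersection test
computes the null distribution of the $m$-way intersection of
fixed-size uniform subsets of an $N$-element universe by iterated
pairwise hypergeometric convolution in log space: the running
intersection of $k$ sets, conditioned to have size $j$, meets the next
subset of size $n_{k+1}$ as $\mathrm{Hypergeom}(N, j, n_{k+1})$. For
$m = 2$ this reduces exactly to the hypergeometric upper tail; for
$m \ge 3$ the implementation is validated against a direct Monte-Carlo
oracle. The universe size $N$ is a required argument — results are only
meaningful relative to an explicitly chosen universe (e.g. all tested
genes). The observed/expected chi-square on 2×2 tables uses no
continuity correction (the regime of interest has large counts and
extreme p-values). Preranked GSEA uses the classic weighted running sum
(weight exponent 1, hit increments proportional to |score|, uniform
miss decrements), a gene-label permutation null, and the +1-corrected,
sign-matched permutation p-value; the desk default is 10,000
permutations (configurable up to the 10^6 used for publication-grade
p-values). Spearman correlation uses mid-ranks, a t-approximation for
$n \ge 10$ and exact permutation enumeration below.

**Interactome quantification.** Channels are normalized to equal total
intensity (idempotent; factors reported). Bait-vs-IgG and
induced-vs-untreated contrasts use a moderated two-sample t: per-protein
pooled variances are shrunk toward the across-protein trend with
`limma::squeezeVar` (method-of-moments prior df), falling back to a
fixed prior df of 4 when the estimate is unavailable — tiny designs
(3+3 bait, 2+2 IgG channels) need the stabilization. IgG channels are
compared per condition by default; pooling across conditions is a
switch (`pool_igg`), since published designs are ambiguous on this
point.

## What the synthetic generator emulates — and what it does not

`sim_config()` fixes the study conditions; `simulate_counts()`,
`simulate_gene_models()`, `simulate_peaks()` and `simulate_tmt()` draw
the three modalities from independent RNG streams derived from one
master seed, so any modality can be regenerated alone and a fixed seed
reproduces every byte.

* **Counts** are negative binomial with variance
  $\mu + \phi\mu^2$ (shared dispersion $\phi$), gene-specific baselines
  $\log_2\mu \sim \mathcal{N}(9, 1)$ (mean count ≈ 500, the
  moderately-expressed regime), and library-size factors log-uniform in
  [0.7, 1.4] to exercise normalization. Default $\phi = 0.02$, the
  clonal cell-line replicate regime. 10% of genes are planted up
  (+2 log2) and 10% down (−2) upon induction; 8% of the up genes are
  *dependent*: their induction is attenuated by 1.5 log2 units in the
  knockdown, giving a planted IS of −1.5. At the default 5000 genes
  this yields 40 dependent targets from 500 UP genes.
* **Peaks** are fixed-width (400 bp) and non-overlapping within a
  factor. Every dependent gene receives overlapping TF and cofactor
  peaks centered on its TSS; 1000 background peaks per factor are
  placed uniformly in slots at least 12 kb from every TSS, so
  background can never annotate into a 10 kb window. In the knockdown,
  TF peaks are lost with probability 0.44 at co-bound sites and 0.07
  elsewhere, emulating the strong promoter-biased loss reported for
  cofactor-dependent binding.
* **TMT intensities** are log-normal (reporter noise sd 0.3 on the
  log2 scale) over a 10-channel design (3+3 bait, 2+2 IgG); 30 of 500
  proteins are bait-enriched by +2 log2, 10 of those additionally
  rewired by +1.5 log2 in the induced state; channel totals carry known
  log-uniform scaling factors.

The generator is deliberately idealized: no GC or length bias, no
shared-variance outlier genes, no peak-width or summit-offset
variation, no overlapping gene models, no missing TMT values, and
planted effects are homogeneous rather than drawn from an effect-size
distribution. Passing the recovery tests therefore shows the pipeline's
logic is correct under its stated model — it does not certify
performance on real data, where normalization, annotation ambiguity and
variance heterogeneity are all harder.

Gene models are placed deterministically (even TSS spacing, alternating
strand, chromosomes `chrS1…chrSn`) rather than randomly: this keeps the
modality RNG-free, guarantees the TSS-free gaps used for background
placement, and avoids name collisions with real assemblies.

## Numerical and degenerate-input choices

* Welch tests with zero variance in both groups return $p = 1$ when
  means are equal and $p = 0$ otherwise.
* The multi-set tail is accumulated in log space; `p` is capped at 1.
* A GSEA set covering the entire ranked list has no miss increments;
  its ES is +1 by convention and flagged `degenerate`.
* Ties in the IS-sorted target list break by gene id, so output order
  is total and reproducible.
* `bh_adjust` delegates to `stats::p.adjust(method = "BH")`; the tests
  pin it against the step-function definition.
* Size-factor estimation requires at least one gene with nonzero counts
  in every sample and fails loudly otherwise.

## Problem sizes used by the test suite

The default simulated experiment (5000 genes, 3 replicates per cell, 40
planted dependent targets, 2 × 1040 TF peaks, 500 proteins) runs the
full pipeline in a few seconds. The property suites use 1000 fuzzed
peak-set pairs against the brute-force oracle, a 10^6-draw Monte-Carlo
check of the three-set exact tail, 200 random gene sets for GSEA null
calibration (2000 permutations each), and 2000-gene null simulations
for error-rate calibration — sizes chosen so each property is measured
with comfortable statistical margin while the whole suite stays quick
to iterate on.

## Known limitations

* Condition-specific peaks are presence/absence; quantitative
  differential binding from signal tracks is out of scope.
* The DE surrogate has no dispersion shrinkage and no GLM covariates;
  it exists to make the pipeline self-contained, not to replace a
  dedicated DE method on real data.
* Nearest-TSS annotation with identical TSS coordinates for distinct
  genes resolves the tie arbitrarily among the co-located genes (the
  documented lexicographic tie-break applies to distinct equidistant
  neighbors).
* The positive-IS class ("enhanced activation") is reported as a column
  but not pursued as a target class.
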