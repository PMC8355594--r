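---
title: "Bioenergetic profiling of thymocyte development: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioenergetic profiling of thymocyte development: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thymoflux)
library(dplyr)
```

## The problem

T-cell precursors pass through a stereotyped sequence of developmental
stages — double-negative (DN, subdivided DN1–3 in mouse and Thy1–3 in
human), immature single-positive (ISP), double-positive (DP, early then
late), and mature single-positive (SP8, SP4). Along this path their
metabolism is remodeled drastically: glycolytic and oxidative activity is
high in the proliferative DN/ISP stages, collapses at the quiescent DP
early stage, and partially recovers in SP cells. Two data types capture
this: extracellular-flux assays (a mito stress test measuring oxygen
consumption rate, OCR, and extracellular acidification rate, ECAR, per
well over time) and stage-resolved RNA-seq of metabolic gene panels.
`thymoflux` turns the raw well-level kinetic traces into standard
bioenergetic metrics, summarizes panel expression across the ordered
stages, and quantifies how well each gene's trajectory tracks a flux
metric.

## The mito stress test model

A plate measures each well repeatedly through four phases separated by
injections: baseline, oligomycin (ATP-synthase inhibitor), FCCP
(uncoupler; two sequential injections, treated as one phase), and
rotenone/antimycin A (Rot/AA; electron-transport-chain inhibitors leaving
only non-mitochondrial oxygen consumption). From a well's phase-resolved
trace the derived metrics are

- basal ECAR = baseline ECAR,
- basal OCR = baseline OCR − Rot/AA OCR,
- maximal OCR = maximum post-FCCP OCR − Rot/AA OCR,
- spare respiratory capacity (SRC) = maximal OCR − basal OCR,
- OCR/ECAR ratio = basal OCR / basal ECAR.

Rates are first normalized to cell number per well (per 1000 cells by
default): this is a pure rescaling, and the OCR/ECAR ratio is invariant
under it because numerator and denominator divide by the same count.

Aggregation choices the assay literature leaves open, and how this
package resolves them:

- **Baseline aggregation** defaults to the mean of all baseline-phase
  measurements; `baseline_mode = "last"` uses the final pre-injection
  point instead. Both are offered because instrument conventions differ
  and neither can be asserted as canonical.
- **Rot/AA floor** is the mean of all Rot/AA-phase measurements.
- **Maximum OCR** is the single largest FCCP-phase measurement (the term
  is "maximum OCR", not a phase mean), with both FCCP injections pooled.
- **Mixing transients**: `exclude_first_post_injection = TRUE` drops the
  first measurement of every post-injection phase; default off.
- **Negative derived metrics** (possible in barely-respiring wells) are
  flagged (`negative_basal_ocr`, `negative_maximal_ocr`) but never
  clipped, since silent clipping would bias group means upward.

Group comparison uses the two-tailed unpaired t test — Welch by default,
which is the robust choice at 2–4 wells per group, with the
pooled-variance Student variant selectable — and Benjamini–Hochberg
adjustment over exactly the family of comparisons passed to one
`compare_groups()` call, so the caller controls family scope. Sample
standard deviations use the n − 1 denominator throughout; single-well
groups report an undefined (NA) sd rather than zero.

## Expression panels over ordered stages

Expression input is a gene × population matrix of count-normalized,
variance-stabilized values (computed upstream; this package never
normalizes counts). Per-gene z-scoring (mean 0, sd 1 across populations,
n − 1 denominator) makes trajectories comparable; constant rows become
all-zero with a flag instead of NaN so pathway means stay defined.
Pathway trajectories are unweighted means of member-gene z-scores per
population. Panel symbols are matched case-insensitively, which bridges
mouse title-case and human upper-case symbol conventions.

Because flux assays measure the DN compartment as one sorted pool while
RNA-seq resolves DN1–3 (Thy1–3), the DN member columns are composited
into a single "DN" profile as a convex combination with the measured
subset proportions: mouse thymus 4/3/93%, mouse organoid 1/1/98%, human
thymus 0.1/59.9/40%, human organoid 0.1/79.9/20%. Compositing happens on
the expression scale *before* z-scoring of the correlation input: a
convex combination of separately standardized columns would not
correspond to any population's expression state, so the reverse order
would be incoherent.

The variable-gene filter consumes a precomputed differential-expression
table and keeps a gene iff some pairwise contrast has fold change beyond
the threshold in either direction (> 2 or < 1/2 by default) with
BH-adjusted Wald p < 0.01, the gene reaches 5 FPKM in at least one
sample, at least 0.5 CPM somewhere, 50 bp of mappable length, and is not
a flagged count outlier. The fold-change cutoff is two-sided because
variable-gene sets contain both up- and down-regulated genes; it is an
argument because a threshold of 4 is equally defensible for stricter
sets. Outlier status is an input flag: outlier detection belongs to the
DE tool, not here. The filter is monotone — relaxing any threshold can
only grow the set — and that property is tested.

PCA runs on standardized features (each gene scaled to mean 0, sd 1)
via `prcomp`; component signs are fixed deterministically by making the
largest-magnitude loading of each component positive, so results are
reproducible across platforms.

## Integrating flux and expression

For one flux metric (basal OCR by default) the per-population value is
the mean of well-level metrics across replicates, computed before any
transform. Flux values are then asinh-transformed with cofactor 5
(`x -> asinh(x/5)`, log-like but defined at and below zero); gene
z-scores are never transformed. Each panel gene's z-trajectory is
Pearson-correlated with the transformed flux vector across the shared
populations; two-sided p-values come from the t distribution with n − 2
degrees of freedom. Genes are classed `positive` (r > 0.5), `negative`
(r < −0.5), or `weak`, and BH adjustment runs within each pathway's gene
family by default (matching per-pathway scatter plots), with
`family = "all-pathways"` pooling one family.

Small-n handling is explicit: with only three populations (the organoid
systems) a correlation p-value would have one degree of freedom and is
not interpretable, so it is reported as undefined and such genes are
excluded from the BH family with reason `n_too_small`; their r values
and sign classes are still reported. Zero-variance gene rows are
excluded with reason `zero_variance`; a zero-variance flux vector aborts
with an error rather than emitting NaN. Thymus integrations default to
all five shared populations (DN, ISP, DP early, SP8, SP4); because it is
ambiguous whether DP early belongs in the thymus correlation set, the
`populations` argument lets either configuration be run explicitly.

## What the synthetic data emulate

The generators produce every input the pipeline consumes, with ground
truth attached, so the whole chain is testable without instrument data.

- `simulate_flux_plate()` builds piecewise-constant phase-level traces
  per well (baseline level, oligomycin residual, FCCP maximum, Rot/AA
  floor) plus i.i.d. Gaussian measurement noise, optionally proportional
  to the baseline level, and an optional exponential-style mixing
  transient on the first post-injection point (default off; it exists to
  exercise the exclusion option). Traces are scaled by a drawn per-well
  cell count so normalization is exercised on the way back in. The
  additive-Gaussian noise model was chosen for transparency; no
  instrument noise model is asserted. The default stage profile mirrors
  the qualitative biology — DN high, ISP high, DP early minimal, SP
  partially recovered — so trajectory-recovery tests are meaningful.
  With `fccp_fold >= 1` the generated true SRC is nonnegative by
  construction.
- `simulate_expression()` evaluates per-pathway trajectory templates
  built from narrow Gaussian bumps, so the programmed peak and nadir
  stages are exactly the template's argmax and argmin, plus per-gene
  offsets and noise. Linked genes instead track a designated flux
  profile (standardized) with a given slope; isoform-switch pairs get
  mirrored trajectories. Default noise sd 0.25–0.3 on the z-like scale
  reflects between-replicate variability typical of sorted-population
  bulk RNA-seq.
- `simulate_de_table()` draws genes that pass or fail each filter
  predicate with known labels, and returns the expected pass set
  computed by brute force from the filter's definition — an oracle
  independent of the filter implementation.

What the generators do **not** emulate: read-level counts, library-size
effects, gene–gene correlation structure, batch effects, or biological
network regulation. Passing tests therefore demonstrate that the
pipeline's arithmetic and statistics behave as specified under the
assumed noise model, not that the model captures every feature of real
instrument or sequencing data.

## Numerical choices and test scale

All tolerances for exact identities are 1e-9 or tighter; p-value
comparisons against reference distributions use 1e-9. The test suite
verifies, among others: metric formulas on 1,000 random
piecewise-constant traces; exact zero-noise recovery of simulator ground
truth; bias below 0.5% of truth and ≥ 90% coverage of truth by ±2
ground-truth standard errors for group-mean basal OCR over 500 plates at
5% noise with 4 wells/group; BH equality with an O(m²) brute-force
step-up oracle on 10,000 random vectors; linked-gene positive-class
recovery ≥ 90% over 500 expression draws at noise 0.3; ≥ 60% weak
classification of null genes (five-point correlations are noisy, so the
suite asserts rates, not certainties); and ≥ 95% recovery of the
DP-early minimum plus positive glycolysis–OCR correlation across 200
full pipeline runs. These problem sizes keep the whole suite around
three minutes on one CPU while leaving the Monte-Carlo margins wide.

## A worked example

```{r example}
flux_cfg <- flux_sim_config_thymus(noise_sd = 0.05, noise_relative = TRUE)
plate <- simulate_flux_plate(flux_cfg, seed = 1)
metrics <- plate$traces |>
  normalize_per_well() |>
  assign_phases() |>
  compute_well_metrics()
summarize_groups(metrics) |> filter(metric == "basal_ocr")
```

```{r integrate}
scheme <- scheme_mouse_thymus()
pops <- c("DN", "ISP8", "DP early", "SP8", "SP4")
truth <- setNames(
  flux_cfg$groups$ocr_baseline - flux_cfg$groups$ocr_nonmito, pops
)
expr_cfg <- expr_sim_config(
  populations = pops,
  pathways = tibble::tibble(pathway = "glycolysis", n_genes = 20,
                            peak = "ISP8", nadir = "DP early",
                            amplitude = 1.5),
  noise_sd = 0.3,
  linked = tibble::tibble(pathway = "glycolysis", n_genes = 20, slope = 1),
  flux_profile = truth
)
esim <- simulate_expression(expr_cfg, seed = 2)
# share the composited DN profile across the member columns
em <- tibble::tibble(gene_id = esim$expression$gene_id,
                     DN1 = esim$expression$DN,
                     DN2 = esim$expression$DN,
                     DN3 = esim$expression$DN) |>
  bind_cols(esim$expression[c("ISP8", "DP early", "SP8", "SP4")]) |>
  expression_matrix(scheme)

res <- run_integration(summarize_groups(metrics), em, esim$panel, scheme,
                       metric = "basal_ocr")
glance(res)
```

## Known limitations

- The flux parser reads only the long-format delimited dialect defined
  here, not proprietary instrument files.
- No ATP-production-rate or proton-efflux modeling; the only background
  correction is the Rot/AA subtraction.
- No partial correlations or regression of flux on expression; the
  integration is deliberately the simple per-gene Pearson screen.
- Count normalization, variance stabilization, differential testing, and
  outlier detection are consumed as inputs, never recomputed.
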