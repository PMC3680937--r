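---
title: "From cross-species signature to combination index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cross-species signature to combination index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The pipeline in one paragraph

tnbcsynergy models the computational chain behind a target-discovery
program for triple-negative breast cancer (TNBC): (1) project a
transgenic-mouse tumor gene signature across species and array platforms
and cluster cell lines and tumors on it, to pick a human cell line that
expresses the signature; (2) screen an siRNA library against that line and
a non-tumorigenic control, normalize plates, and call tumor-selective
dependency genes by z-score; (3) treat cells with drugs against those
targets, fit single-agent median-effect (IC50) models, and score drug
pairs with the Chou-Talalay combination index (CI). Because raw microarray
and screen data are not distributed with the package, a synthetic-data
module generates inputs with the statistical structure each stage assumes,
which also gives every stage an exact round-trip oracle.

# Stage 1: cross-species signature clustering

## Model

Each expression dataset is a probe-by-sample matrix of log2 normalized
intensities with species and platform tags. Integration proceeds:

1. **Probe collapsing.** Multiple probes per gene are reduced to the probe
   with the highest median signal across samples. Ties are broken by the
   lexicographically smallest probe id — an arbitrary but deterministic
   rule.
2. **Homology mapping.** Gene ids are translated across species through a
   homology table filtered to strictly one-to-one pairs; one-to-many and
   many-to-many pairs are dropped (with a logged count) because they would
   double-count expression. The analysis universe is the set of signature
   genes present in every dataset after translation.
3. **Standardization.** Within each dataset, every gene is z-scored to
   mean 0 and unit *sample* (n−1) standard deviation. Sample sd is the
   convention of mainstream statistics environments; with the sample sizes
   involved the n vs n−1 choice is immaterial to cluster topology.
   Zero-variance genes are dropped with a warning rather than set to 0:
   they carry no clustering information and corrupt the uncentered
   correlation norms.
4. **Clustering.** Samples are agglomerated under the
   uncentered-correlation distance `d = 1 − Σxy/√(Σx²Σy²)` (range [0, 2];
   no mean-centering, so the all-positive/all-negative structure of
   z-scored signature expression is preserved) with complete linkage.

Clustering runs on the signature genes only — the question the dendrogram
answers is "which samples express the signature", not "what is the global
expression topology". Only sample-side (column) clustering is computed;
the gene-side dendrogram of a two-way heatmap is presentational and can be
obtained by transposing the matrix into `cluster_complete()` if wanted.

## Numerical choices

The agglomeration is written out explicitly rather than delegated, so that
its tie rule is pinned: when several cluster pairs sit at the minimal
distance, the pair with the smallest creation-order indices merges first.
On continuous data ties have probability zero and the implementation is
checked against `stats::hclust(method = "complete")` on random instances;
on degenerate data (duplicate samples) the explicit rule keeps runs
bit-identical. Complete linkage guarantees monotone merge heights, so
`stats::cutree` applies directly; `co_cluster()` cuts at k clusters and
reports whether a query set (e.g. all tumor-like samples) lands in one
flat cluster — the quantitative reading of "these samples cluster
together".

One genuinely open point is whether per-gene standardization should be
computed within dataset or per array; the phrase "each gene expression was
standardized" supports per gene within dataset, which is what
`zscore_genes()` does.

# Stage 2: siRNA screen hit calling

## Model

Screens are 96-well plates using the interior 60 wells for library siRNA
pools (edge wells suffer evaporation artifacts); each plate carries three
non-targeting siRNA (NTS) wells, a cyclophilin-B transfection control, and
PLK1/cell-death positive controls. Analysis per plate:

1. **NTS normalization:** each gene's mean absorbance divided by the
   plate's mean NTS absorbance. This happens *before* z-scoring, so plates
   and screens are comparable; the order is ambiguous in common practice
   but normalization-first is the choice that makes cross-plate libraries
   coherent.
2. **Plate z-scores:** `(value − library mean)/library sample sd`,
   computed over library wells only. Controls are excluded because the
   strong positive controls would drag the mean down and shrink every
   z-score toward significance.
3. **Hit rule:** a gene is a hit for a cell line iff `z ≤ tau` in *every*
   replicate screen of that line. The default `tau = −1.4` is the unique
   round threshold that reproduces the published selective/nonselective
   split of the bundled six-gene z-matrix (`tnbc_screen_zscores()`); it is
   a configurable parameter, not a constant of nature. Notably, one gene
   in that matrix is called significant in the control line at z = −1.452,
   suggesting the original control-line calls may have used percent
   change rather than z — the package documents the discrepancy and keeps
   tau configurable rather than resolving it.
4. **Selectivity:** hits in all tumor lines but not the control line are
   `selective` (candidate tumor dependencies); hits everywhere are
   `nonselective` (generic proliferation machinery); anything else is
   `non_hit`.
5. **Deconvolution:** a pooled hit is confirmed when ≥3 of its 4
   individual oligos suppress growth to at or below the activity threshold
   (default 70% of the non-targeting reference) — the usual community
   convention for pool confirmation.

Genes split across plates are scored on their own plate; no cross-plate
re-centering is applied beyond NTS normalization.

# Stage 3: median-effect potency and Chou-Talalay synergy

## Model

Viability signals are converted to fraction affected
`fa = 1 − mean(treated)/mean(vehicle)` (replicates averaged first, the
CompuSyn convention), clipped into `[ε, 1−ε]` with `ε = 1e−4` so the logit
stays finite; clipped points are flagged and excluded from fitting but
kept in reports. The median-effect equation `fa/fu = (D/Dm)^m` is linear
in log-log, so ordinary least squares of `log10(fa/fu)` on `log10(D)`
yields the slope `m` and `Dm = 10^(−intercept/m)`; `Dm` (the dose of
half-maximal effect) is reported as the IC50, with the plot's linear
correlation `r` as goodness of fit. No separate 4-parameter logistic IC50
is fitted.

**Effect-level window.** The logit transform amplifies viability noise
without bound as fa approaches 0 or 1: at fa = 0.01 a 3% viability error
moves `log10(fa/fu)` by a factor-of-several, while at fa = 0.5 it barely
moves it. Points outside `fa ∈ [0.1, 0.9]` are therefore excluded from the
regression by default (`fa_range` argument), falling back to all unclipped
points if fewer than two distinct doses remain. This mirrors the working
rule that the median-effect plot is reliable in its middle effect range,
and it is what makes IC50 estimates stable on wide (4-decade) dose designs
at realistic assay noise.

The combination index at an observed combination effect fa is the
mutually-exclusive two-term form
`CI = D1/Dx1(fa) + D2/Dx2(fa)`, `Dx(fa) = Dm·(fa/(1−fa))^(1/m)` — the
CompuSyn default; the non-exclusive third term is out of scope. CI < 1 is
synergy, = 1 additivity, > 1 antagonism; classification uses a band
`|CI − 1| ≤ δ` with `δ = 0.05` (configurable) because exact equality is
measure-zero on noisy data. `fa_ci_profile()` evaluates all dose pairs of
a combination experiment and flags overall synergy when every CI is
below 1. Repeated-experiment "average IC50" is the arithmetic mean of
per-experiment Dm.

Auxiliary statistics match the surrounding analysis conventions: classical
unpaired two-tailed (pooled-variance) t-tests and Pearson correlation for
expression/group association; lettered significance tiers A ≤ 0.01,
B ≤ 0.005, C ≤ 0.001, D ≤ 0.0005 (most stringent satisfied tier wins);
caliper tumor volume `length × width² / 2`.

# The synthetic-data module

The generators define the study conditions and double as oracles:

- **Expression collections** (`gen_expression_collection()`): four
  datasets by default, alternating human/mouse namespaces with distinct
  probe ids, four tumor-like and four normal-like samples each, gene
  baselines ~N(8, 1.5) log2 units shared across datasets,
  dataset-specific scale (0.8–1.3×) and offset so per-dataset
  standardization is actually necessary, every fourth gene carrying a
  dimmer sibling probe so collapsing is decidable, and an 80-gene
  signature shifted up by `effect` (default 2 log2 units) in tumor-like
  samples only. The within-group noise default of 0.5 log2 units is a
  realistic microarray spread; with an 80-gene signature at 2 log-units
  the tumor/normal separation on the signature axis is then ~4 sd per
  gene, and planted-signature recovery holds in ≥95% of seeds.
- **Screens** (`gen_screen()`): interior-60 layout, `ceiling(n/60)` plates
  per replicate, controls on row A edge wells, planted hits at
  `(1 − inhibition)` of the NTS level, multiplicative log-normal well
  noise with CV 5% by default (absorbance noise scales with signal),
  positive-control inhibition never below the planted inhibition.
- **Dose response** (`gen_dose_response()`): exact median-effect truth,
  additive Gaussian viability noise clipped to [0, 1.2] (treated wells can
  read above vehicle in real MTS assays — this exercises the fa clipping
  path), explicit vehicle wells so the pipeline's own normalization runs.
- **Combinations** (`gen_combination()`): a constant-CI deformation of
  Loewe additivity — the true fa at `(D1, D2)` solves
  `D1/Dx1(fa) + D2/Dx2(fa) = κ`, found by bisection to `|Δfa| < 1e−10`
  (the left side is strictly decreasing in fa from ∞ to 0, so a unique
  root always exists for valid parameters). This makes the Chou-Talalay
  CI *exactly* recoverable: analyzed noise-free, every dose pair returns
  CI = κ to 1e−6, and a drug sham-combined with itself at κ = 1
  reproduces its own single-agent curve. With both slopes equal to 1 the
  closed form `fa = R/(R + κ)`, `R = D1/Dm1 + D2/Dm2`, cross-checks the
  bisection.

All generators are driven by a single `sim_config()` seed; identical
configurations give bit-identical output.

## What the generators do not emulate

Probe-level array preprocessing (the pipeline starts from normalized log
intensities), spatial plate artifacts and edge effects, siRNA off-target
(seed-match) activity, systematic transfection-efficiency drift between
replicate screens, non-median-effect dose-response shapes (biphasic
curves, partial maximal effect), and inter-experiment IC50 drift. Passing
tests therefore demonstrate that the analysis chain is a faithful,
self-consistent implementation of its models — not that those models
capture every pathology of real data.

# Problem sizes and reproducibility

The test suite exercises: 200-gene, 4-dataset, 32-sample expression
collections (100 seeds for planted-signature recovery); 108-gene, 2-plate,
2-replicate screens (100 seeds for exact hit recovery and false-positive
rate); 8-dose × 3-replicate viability designs (100 seeds for Dm recovery,
median relative error under 10% at 3% viability noise); and exhaustive
agreement of the explicit agglomeration with library clustering on 100
random ≤8-sample instances. These sizes were chosen as the smallest
designs at which each statistical property is comfortably identified.
Every analysis stage writes a JSON manifest (config, seed, package
version) sufficient to re-run it bit-identically.

# Known limitations

- The hit threshold tau is under-determined by the available numbers; the
  default reproduces the published split but other thresholds are
  defensible (see the control-line discrepancy above).
- The CI is computed at each combination point's *observed* fa; no
  smoothing across effect levels is applied, so single noisy combination
  points propagate directly into single CI values (the Fa-CI summary
  exists for exactly this reason).
- IC50s from designs whose doses all fall outside the [0.1, 0.9] effect
  window fall back to extreme-point fitting and inherit its noise.
- The in-vivo arm of such a program is represented only by the caliper
  volume formula; growth-curve modelling is out of scope.
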