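---
title: "Methods: same-cell respirometry and expression heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: same-cell respirometry and expression heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picoresp)
```

This vignette is the package's account of its models and the design
decisions behind them: what is assumed, what is tunable, what the
simulator does and does not emulate, and where the genuinely open choices
were made.

## 1. The measurement model

A single cell sits in a hermetically sealed glass microwell of volume
$V = 140$ pL together with a luminescent oxygen sensor. As the cell
respires, dissolved oxygen falls and the sensor, whose emission is
quenched by oxygen, brightens. Two channels are recorded: the
oxygen-sensitive sensor channel and an oxygen-insensitive rhodamine-123
reference channel. Dividing the first by the second removes the deposited
sensor volume — uncontrollable at picoliter scale — from the readout.

The forward model in `simulate_sensor_trace()` is ideal Stern–Volmer
quenching of that ratio,

$$\rho(C) = \frac{I_0}{1 + K_{sv} C},$$

with oxygen amount $A(t) = \max(0,\; V C_0 k_u - r\,t)$ for a cell of true
OCR $r$, concentration $C(t) = A(t)/(V k_u)$, and unit constant
$k_u = 10^{-3}$ fmol per µM·pL. Multiplicative Gaussian noise is applied
per channel; an optional linear drift affects the reference channel only,
and an optional first-order leak term relaxes the well toward an external
oxygen level (used to emulate failed seals).

Parameters and defaults, with reasoning:

* `volume = 140` pL — the chamber the hardware defines.
* `initial_o2 = 200` µM — air-saturated culture medium near 37 °C. At
  140 pL this is 28 fmol of O2, so a cell respiring 0.5–5 fmol/min
  produces a measurable decline within the 30–80 min windows typical of
  these drawdowns. This value is not part of the study's printed record
  and is exposed in configuration.
* `ksv = 0.005`/µM, `i0 = 2` — a dynamic range of 2× between anoxia and
  200 µM, typical of optical O2 sensors; the true calibration lives in
  instrument-specific material, so the package models the simplest
  photophysics consistent with a self-referencing ratiometric quencher and
  lets `two_point_calibrate()` fit both constants from an anoxic and one
  known-concentration anchor.
* `noise_sd = 0.01` — 1% multiplicative intensity noise, a conservative
  figure for shading-corrected epifluorescence time series.

## 2. OCR extraction

`extract_ocr()` inverts the pipeline: ratio → Stern–Volmer inverse →
concentration → optional 5-point centered sliding average → OLS fit →
$\mathrm{OCR} = |dC/dt| \cdot V \cdot k_u$, with class `non-respiring`
below a `detection_floor` of 0.1 fmol/min (the zero-OCR class is treated
as real biology, not instrument failure: observed non-respirer fractions
far exceed dead-cell fractions).

Numerical choices worth recording:

* **Smoothing operates on the calibrated concentration series**, not on
  the raw ratio. Pre-depletion, $C(t)$ is linear in $t$, so a centered
  moving average leaves the OLS slope unbiased; the ratio is convex in
  $t$ and smoothing it would curve the recovered concentration and bias
  fast cells by up to ~1%.
* **Pre-depletion truncation.** The depletion floor clamps $C$ at zero;
  regressing across it biases slopes toward zero. The fit stops at the
  first sample below 2% of the initial concentration, and when smoothing
  is on the cut moves earlier by the half-window so that no fitted point
  has a window overlapping the floor.
* **Volume convention.** A concentration slope (µM/min) must be
  *multiplied* by well volume to give an amount rate; the package
  implements $\mathrm{OCR} = |dC/dt|\,V k_u$, which makes
  $-1$ µM/min at 140 pL exactly 0.14 fmol/min.
* **The regression is unweighted OLS on concentration**, matching the
  published description of a linear regression on the drawdown curve.
* **Seal QC.** `qc_seal()` flags a well unsealed when the normalized ratio
  changes beyond a tolerance over a window in which it should be constant
  (e.g. a nitrogen-purge test, or any non-respiring well). Inside
  `extract_ocr()` the flag is only computed for non-respiring results: a
  well that draws down demonstrates its own seal, since ambient resupply
  would prevent depletion.

Under the study conditions (140 pL, 200 µM, 60 min at 0.5 min sampling)
the extractor recovers true OCRs of 0.1–5 fmol/min to well under 1%
noiselessly, and to a median relative error of a few percent at 1%
intensity noise; the acceptance suite asserts both.

## 3. Expression normalization and the enrichment statistics

`normalize_expression()` mirrors a qPCR-panel convention: non-detects are
imputed at the gene's minimum detected value (a limit-of-detection
surrogate) and kept flagged; the global mean of detected entries is
subtracted; each gene is Z-scored by the mean and *sample* SD of its
detected entries; genes detected in fewer than 3 cells are dropped and
reported. Per-cell or global Z-scoring were the alternatives; per-gene
scoring is the one that makes genes comparable in the clustering metric,
and the choice is recorded in the output metadata.

All cells are pooled and cut into $k = 10$ clusters by Ward linkage on
Euclidean distance (`hierarchical_cluster()`, both configurable); pooled
occupancies give $p_i = N_i/N_\mathrm{total}$. For a strain $g$ occupying
the clusters with fractions $f_{gi}$, the enrichment ratio is
$ES_{gi} = f_{gi}/p_i$ — the probability of landing where the strain
landed relative to chance — and the total enrichment score is its
occupancy-weighted mean:

$$TES_g = \sum_i f_{gi}\,ES_{gi} = \sum_i \frac{f_{gi}^2}{p_i}.$$

This aggregation was a genuinely open design choice: only $p_i$ and the
ratio idea are fixed by the published description. The quadratic form was
adopted because it is the natural occupancy-weighted mean of the ratio and
because it is exactly bounded, $1 \le TES_g \le N_\mathrm{total}/n_g$
(lower bound by Cauchy–Schwarz, attained iff the strain's occupancy equals
the pooled occupancy; upper bound attained iff the strain exclusively owns
one cluster) — a range consistent with published per-strain values around
2.4–5.5 for $n_g \approx 21$ of 170 cells. The test suite asserts both
bounds, both equality cases, and agreement with a brute-force cell-by-cell
oracle.

Relative variability is $RV = TES_\mathrm{control}/TES_\mathrm{hypoxia}$;
the direction was fixed by verifying all four published strain pairs.
`compare_groups()` accompanies the heterogeneity statistics with Welch and
Mann–Whitney tests of OCR means per cell type (the published analysis
reports "no significant difference" without naming the test, so both are
reported) under Benjamini–Hochberg adjustment.

## 4. Integration and aberrant-cell flags

`pca_embed()` is column-centered PCA with a deterministic sign convention
(largest-magnitude score positive). `tsne_embed()` wraps Rtsne with an
explicit seed. `augment_with_ocr()` replaces the third axis by the robust
Z of OCR — median/MAD over respiring cells, because the OCR distributions
are zero-inflated and right-skewed, so mean/SD scaling would let the
non-respirers define the scale. Non-respirers are pinned below the lowest
respiring cell. (The published phrasing "replacing the third principal
component's loading with OCR" is read as replacing the per-cell
*coordinate*: loadings are gene-wise and cannot carry a per-cell
quantity.)

`flag_aberrant_cells()` operationalizes "well differentiated" — for which
no quantitative criterion was published — as:

* `high-OCR-outlier`: $|Z_\mathrm{OCR}| > 2.5$ *and* distance to the
  cell's own expression-cluster centroid at or below the 0.75 quantile of
  within-cluster centroid distances, pooled across clusters (pooling keeps
  the quantile stable at ~17-cell clusters). Extreme function, ordinary
  transcriptome.
* `non-respirer-cluster`: non-respiring with mean pairwise expression
  correlation against the other non-respirers above 0.5. Fewer than two
  non-respirers skips the flag with a note.

All three thresholds are exposed in configuration. Flags are invariant to
relabeling cell types and to common positive rescaling of OCR (MAD scaling
cancels), asserted as properties. Note that a MAD-scaled threshold of 2.5
on a lognormal population legitimately flags on the order of 2% of
respiring cells; the flags are geometric statements, not biological
identifications.

## 5. The simulator and the selection model

`generate_study()` emulates the study design: 8 strains × 20–24 cells,
one drawdown trace per cell, a 96-gene panel (six housekeepers with
near-zero dropout, ninety target genes in seven hypoxia-relevant
functional groups, 15% dropout) with four latent expression clusters
(each cell type's modal cluster holds 70% of its cells), and per-strain
non-respirer fractions fixed inside the observed 18–35% band — except
control CP-A, which has none, mirroring the one strain in which no
non-respirer was seen. Everything is deterministic given one seed, and
outputs are byte-stable.

The bottleneck protocol (`simulate_hypoxia_selection()`): six rounds, each
keeping `round(N · 0.10)` cells and re-expanding to the original size.
Selection acts on a latent survival trait decomposed as $t = g + e$ with
heritable variance $\mathrm{var}(g) = h\,\sigma^2$. A fraction $h$ of the
survivor quota is taken by trait rank, the rest uniformly; re-expansion is
clonal — offspring inherit $g$ exactly and redraw $e$ — so offspring
regress toward the mean by factor $h$ ($E[g\,|\,t] = h\,t$). The two
limits make the recapitulation claim falsifiable: at $h = 0$ the trait
distribution is invariant under any number of rounds (each expansion
redraws from the base distribution; there is no compounding drift), and at
$h = 1$ six rounds of 10% survival shift the mean strictly. Cluster
*labels*, being clonally inherited and trait-independent, keep their base
proportions in expectation, though each bottleneck adds resampling
variance of order $p(1-p)(1/N_\mathrm{surv} + 1/N)$ per round — the
relevant null when checking proportions after selection.

By default the hypoxia strains are generated with $h = 0$, i.e. under the
conditions in which selection recapitulates the control phenotype
distribution — the study's own conclusion. Consequently the simulated RV
values scatter around 1 (the suite checks the median over 25 studies lies
in [0.85, 1.18]); the generator is not tuned to reproduce the published
per-type RV pattern (0.59 for CP-A vs 1.25 for CP-D), which would require
the per-cell cluster table of the original supplementary material.

What the simulator does *not* emulate: raw images and ROI extraction
(simulation starts at per-well intensities), qPCR chemistry and
amplification noise structure, gene–gene correlation beyond the latent
cluster structure, cell-cycle or culture-adaptation drift between
measurement and harvesting, and any coupling between OCR and expression
(none is imposed, so integration tests plant their own). Passing tests
therefore demonstrate the statistical machinery, not instrument fidelity.

## 6. Problem sizes and determinism

The test and acceptance workloads use the study's own scale — ~180 cells,
96 genes, 61–121 samples per trace — and complete in seconds; the
RV-stability property uses 25 full simulated studies and the OCR-recovery
check 50 traces of 121 samples at 60 min. Every stochastic entry point
takes an explicit seed (`withr::with_seed`; the caller's RNG state is
never touched), hierarchical clustering and PCA are deterministic given
input order, and `run_pipeline()` re-run on identical inputs reproduces
its numeric outputs byte for byte.

## 7. Known limitations

* The Stern–Volmer model is ideal (no sensor photobleaching, no
  temperature dependence, no heterogeneous quenching); real calibrations
  may need the two-point fit per array.
* TES depends on $k$ and the linkage; published values are only
  comparable under the published clustering, which is not recoverable
  from the printed record.
* The aberrance thresholds are an operationalization, not a
  reconstruction of the original selection of "well differentiated"
  cells.
* t-SNE coordinates are seed-reproducible but not stable across
  perplexities; they are used for visualization-level claims only
  (silhouette of planted structure), never for flagging.
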