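# picoresp

Same-cell analysis of respiration and gene expression: single-cell oxygen
consumption rates (OCR) from sealed-picoliter-well sensor kinetics,
cluster-enrichment statistics for transcriptional heterogeneity under
hypoxia selection, and OCR-augmented embeddings that identify cells with
aberrant combined phenotypes.

## The problem

Measuring a functional phenotype (how fast a cell respires) and a molecular
phenotype (what it expresses) *in the same single cell* makes it possible
to ask questions neither readout answers alone: does repeated selective
pressure change a population's phenotypic heterogeneity, and are there
cells that look ordinary in expression space but behave aberrantly in
function? The experimental setting this package models is an array of
hermetically sealed 140 pL glass microwells, each holding one live cell and
a luminescent oxygen sensor; after the drawdown measurement each cell is
harvested for a 96-gene expression panel. The biological study design is a
premalignant progression model (metaplastic CP-A and dysplastic CP-B/C/D
esophageal lines), each line carried as a control strain and a
hypoxia-resistant strain derived by six rounds of ~10%-survival acute
hypoxia with re-expansion.

The package is organized as an analysis workflow (`analysis/01...04`) over
a fully tested R package, with a forward simulator standing in for the
instrument so that every stage is testable end to end.

## The methods

**OCR extraction.** The sensor is a self-referencing ratiometric
chemosensor: the oxygen-sensitive channel is divided by a rhodamine-123
reference channel, and the ratio follows Stern–Volmer quenching,

    ratio(C) = I0 / (1 + Ksv · C),

with `C` the dissolved O2 concentration (µM). Inverting the calibration
gives `C(t)`; a 5-point sliding average is applied; and the pre-depletion
decline is fit by ordinary least squares. The rate is

    OCR = |dC/dt| · V · ku   (fmol/min),

with `V = 140 pL` and `ku = 10⁻³` fmol·pL⁻¹·µM⁻¹. Cells below a
0.1 fmol/min detection floor are classified non-respiring.

**Heterogeneity via cluster enrichment.** Cells are pooled, their
normalized expression matrix is cut into `k = 10` Ward clusters with
occupancy probabilities `p_i = N_i / N_total`, and each strain `g` with
per-cluster occupancy fractions `f_gi` gets an enrichment ratio
`ES_gi = f_gi / p_i` and a total enrichment score

    TES_g = Σ_i f_gi · ES_gi = Σ_i f_gi² / p_i,   1 ≤ TES_g ≤ N_total / n_g.

Higher TES = more concentrated = less variable. The relative variability
of a (control, hypoxia-resistant) strain pair is `RV = TES_c / TES_h`;
RV < 1 means selection reduced transcriptional variability.

**Integration.** PCA and t-SNE embed cells in expression space; the third
PCA axis is then replaced by the robust Z-score (median/MAD over respiring
cells) of OCR. Cells are flagged `high-OCR-outlier` when their respiration
is extreme (|Z| > 2.5) while their transcriptome sits inside an ordinary
cluster, and `non-respirer-cluster` when they are non-respiring with
mutually coherent expression profiles — the two aberrant-phenotype classes
that neither readout detects alone.

**Simulator.** `generate_study()` forward-simulates the whole study:
zero-inflated lognormal OCR populations (18–35% non-respirers in every
strain except control CP-A), Stern–Volmer drawdown traces with
multiplicative noise, a 96-gene panel with latent-cluster structure and
dropout, and the six-round bottleneck-selection protocol with a
heritability knob coupling a latent survival trait to survival and
inheritance.

## Worked example

```r
library(picoresp)

study <- generate_study(study_config(), seed = 20260919, out_dir = "results/study")
cfg <- pipeline_config(
  traces_dir = "results/study",
  manifest   = "results/study/manifest.json",
  matrix     = "results/study/expression_matrix.tsv",
  out_dir    = "results/pipeline",
  seed       = 20260919)
run_pipeline(cfg)
```

Running the numbered drivers (`Rscript analysis/01_simulate_study.R` … `04_integrate.R`)
on this study prints, among other things:

```
median relative OCR error over 138 respiring cells: 1.30%
respirer classification agreement with truth: 100.0%

RV (control TES / hypoxia TES) per cell type:
CP-A CP-B CP-C CP-D
1.13 0.99 0.68 1.07

aberrant-phenotype flags:
high-OCR-outlier             none
               4              176
```

Read: the extractor recovers the simulator's true OCRs to ~1% at 1%
sensor noise and classifies every non-respirer correctly; with both
strains of each pair simulated from identical settings the RV values
scatter around 1 (a strain made genuinely less variable would pull its
pair below 1); and four cells with ordinary transcriptomes but extreme
respiration are flagged — cells that expression-only clustering leaves
inside normal clusters.

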