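# fociscreen

High-content screening pipeline for quantitative, single-cell detection of
DNA damage in immunofluorescence plate images.

DNA double-strand breaks recruit repair factors that are visible as discrete
nuclear foci: 53BP1 relocalises from a diffuse nuclear pool into foci, while
γ-H2AX (H2AX phosphorylated at Ser139) is generated de novo at damage sites.
High-throughput imaging of 384-well plates — for example immune cells
challenged ex vivo with etoposide — produces thousands of per-channel TIFF
fields that need to be turned into per-cell damage measurements and
condition-level statistics. `fociscreen` implements that full analysis
chain in R, together with a synthetic-microscopy simulator that provides
ground truth, so every stage of the pipeline is testable without
instrument data.

## What the pipeline computes

For each field (DAPI / 53BP1 / γ-H2AX channels at 216 nm/pixel):

1. **Nucleus segmentation** — Gaussian smoothing, global Otsu threshold,
   hole filling, optional watershed split of touching nuclei on the
   distance transform, area gating and border exclusion.
2. **Focus detection** — permissive multi-scale Laplacian-of-Gaussian
   detection inside nuclei; local maxima of the scale-normalised response
   `σ²·|∇²(G_σ ∗ I)|` become spot candidates with intensity, shape and
   context features.
3. **Focus classification** — a trainable Fisher linear discriminant
   `w = S_W⁻¹(μ₁ − μ₀)` separates true foci from background detections,
   with the decision threshold at the projected-means midpoint and exact
   fine-tuning via additive per-class sufficient statistics.
4. **Per-cell features** — 53BP1 *sum spot intensity* (sum of accepted
   focus integrated intensities) and γ-H2AX *mean nuclear intensity*
   (mean over the nucleus mask), following each marker's staining biology.
5. **Positivity calling** — a cell is damage-positive when its feature
   strictly exceeds the negative control's mean + 1 sample SD.
6. **Statistics** — Mann–Whitney–Wilcoxon rank-sum tests per marker,
   Yates-corrected 2×2 χ² on positive-cell counts, one-way ANOVA of
   single-cell values across technical replicates, and dual-marker 2D
   Gaussian kernel densities (the "diagonal shift" view of a treatment
   response).

## Worked example

Simulate a two-well plate (vehicle vs 30 µM etoposide analog), train the
focus classifiers on separate simulated fields, quantify, and compare:

```r
library(fociscreen)

cfg    <- simulation_config(field_shape_px = c(512L, 512L), n_cells = 30L)
models <- train_spot_models(cfg, n_fields = 2, seed = 42)

dir <- file.path(tempdir(), "demo")
layout <- plate_layout(list(
  A01 = sample_meta("D1", "JURKAT", "DMSO"),
  A02 = sample_meta("D1", "JURKAT", "ETP", 30)))
run_simulate(cfg, layout, dir, fields_per_well = 3L, seed = 7)

cells  <- run_quantify(dir, layout, models)
report <- run_stats(cells, control = "DMSO")
print(report)
```

```
<stats_report> 180 cells, control = DMSO
 ETP vs DMSO:
<condition_comparison> control n = 90, treated n = 90
  53BP1 [sum_spot_53BP1]: Wilcoxon U = 8083, p < 2.2e-16 | positive 10.0% -> 100.0% (X2 = 143.7, p < 2.2e-16) | delta median = +2.382e+05
  gH2AX [mean_nuclear_gH2AX]: Wilcoxon U = 8100, p < 2.2e-16 | positive 17.8% -> 100.0% (X2 = 122.3, p < 2.2e-16) | delta median = +532
```

Reading the output: the treated well shifts both markers — nearly every
treated cell exceeds the vehicle-derived mean + 1 SD threshold
(10% → 100% positive for 53BP1; the ~10–18% baseline positivity of the
control against its own threshold is expected for a roughly normal
feature, Φ(−1) ≈ 0.159), the rank-sum tests reject at the display floor,
and both median differences are positive: the dual-marker "diagonal
shift" of a genuine damage response.

A thin command-line front end over the same functions is installed at
`inst/cli/fociscreen.R` (subcommands `simulate`, `train-spots`,
`quantify`, `stats`).

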