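---
title: "Methods: models, parameters and design choices in fociscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in fociscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fociscreen` quantifies DNA double-strand-break markers (53BP1 and
γ-H2AX) in multiwell immunofluorescence images at single-cell
resolution. This vignette documents the underlying models, the
parameters that matter, the numerical conventions the results depend
on, and the choices made where the design was genuinely open. The
companion README shows the user-facing workflow.

## The measurement model

Each field of view contributes three grayscale channels: DAPI
(chromatin), 53BP1 and γ-H2AX, at a default 0.216 µm/pixel (a 60×
objective with 2×2 camera binning) and a default field of 1080×1280
pixels. All intensities are raw arbitrary units (A.U.); the package
applies no normalisation or background subtraction at I/O time, because
downstream thresholds are defined on raw control distributions.

The two markers are quantified differently, on purpose:

* **53BP1** exists as a diffuse nuclear pool before damage and
  *redistributes* into foci. Total nuclear intensity is therefore
  nearly uninformative; the per-cell feature is the **sum of accepted
  focus integrated intensities** ("sum spot intensity").
* **γ-H2AX** is *created* by phosphorylation after damage, so the bulk
  nuclear level carries the signal; the per-cell feature is the **mean
  nuclear intensity** over the segmented nucleus mask. Focus-level
  γ-H2AX features are still computed and stored, but the mean nuclear
  intensity drives positivity calls by default.

A cell is called **damage-positive** when its marker feature strictly
exceeds the negative control's mean plus one sample SD (n−1
denominator). Strictness matters: values exactly at the threshold are
negative, so calls are deterministic under ties. For a control whose
feature is approximately normal, classifying the control against its
own threshold flags Φ(−1) ≈ 15.9% of control cells; this baseline is a
property of the rule, not a defect, and is verified by the test suite
on 10⁶ normal draws. The negative control is the vehicle (DMSO)
condition when present, else the untreated condition, pooled across
replicate wells of the same sample — pooling maximises the control n
on which the threshold estimate rests.

## Nucleus segmentation

Pipeline: Gaussian smoothing (σ = 2 px) → global Otsu threshold →
hole filling → optional watershed split → area gate → border
exclusion → consecutive relabeling.

Numerical conventions worth knowing:

* The Otsu threshold is computed on the range-normalised smoothed
  image, which makes the segmentation exactly invariant to
  multiplying the input by any positive constant (verified as a
  property test). A constant image yields an empty label map, not an
  error.
* Touching nuclei are split by a watershed on the distance transform
  of the foreground mask; the single knob is the h-minima tolerance
  (default 2 px of distance), which suppresses shallow maxima so mild
  shape waviness does not fragment a nucleus.
* Labels are 4-connected (the labeling convention of the underlying
  EBImage primitives); pixel coordinates are 0-based (row, col) with
  row 0 the top image row.
* The area gate defaults to π·(2 µm)²–π·(7 µm)² converted by the
  pixel size — immune-cell nuclei of roughly 8–10 µm diameter pass
  comfortably, debris and merged clumps do not.
* Border-touching nuclei are excluded by default because their area
  and intensity features are truncated.

## Focus detection and classification

Detection is deliberately **permissive** ("low stringency"), with the
pruning pushed into a trained classifier. Candidates are strict local
maxima of the scale-normalised Laplacian-of-Gaussian response
(σ² times the negated Laplacian of the σ-smoothed image, positive for
bright blobs) over a log-spaced filter bank (default σ = 1–3 px in 4
steps, bracketing a diffraction-limited focus at 216 nm pixels), kept
when the response exceeds a low threshold (default 15 A.U.) and the
pixel lies inside a segmented nucleus. Duplicate maxima across scales
are merged by distance: a weaker candidate within one detection scale
of a stronger one is dropped.

Each candidate is featurised against its local background, estimated
as the median over an annulus at 3–5 detection scales from the peak
(restricted to the parent nucleus). At those radii a Gaussian focus
contributes ≲ 0.1% of its peak, so the integrated intensity above
background over a disc of 3 scales captures the focus flux essentially
unbiased; the noise-free flux of a simulated focus equals
amplitude × 2πσ² to within 1% (a conservation test).

Classification is a two-class Fisher linear discriminant:
`w = (S_W + εI)⁻¹(μ₁ − μ₀)`, threshold at the projected-means midpoint
`t = (w·μ₁ + w·μ₀)/2`, accept iff `w·x > t`. The ridge ε defaults to
10⁻⁶·trace(S_W)/d and is recorded in the model. The model stores
per-class sufficient statistics (count, mean, scatter), which are
additive — fine-tuning on new labelled examples is therefore *exactly*
equivalent to retraining on the pooled data, a property the suite
checks numerically. The closed form is also cross-checked against a
brute-force maximisation of the Fisher criterion over a 0.1° grid of
directions.

The default feature set is {log integrated intensity, log amplitude
(peak − local background), log contrast, area above half-max,
roundness, detection scale}. The intensity features enter on a log
scale because focus amplitudes in fluorescence data are heavy-tailed
(approximately log-normal): on a raw scale the focus-class mean is
dominated by the bright tail and the midpoint threshold rejects dim
but real foci. Measured on synthetic ground truth at default
conditions, the log-scale features raise post-classification recall
from ~83% to ~96% at unchanged (≈100%) precision. `fld_train()` and
`fld_classify()` are agnostic to the feature set; any numeric columns
can be supplied.

## The statistical layer

All condition-level tests are thin wrappers that fix the contract
around the standard R implementations (and are validated against
independent brute-force oracles in the test suite):

* **Wilcoxon rank-sum**: U from midranks; exact permutation p-value
  when n₁·n₂ ≤ 400 and there are no ties, otherwise the normal
  approximation with tie and continuity corrections. Two-sided
  everywhere.
* **2×2 χ²** on positive/negative counts: Pearson statistic with the
  Yates correction `(|O−E| − min(0.5, |O−E|))²/E` on by default — with
  published positive fractions and cell counts, the corrected
  statistic reproduces reported χ² values slightly better than the
  uncorrected one, consistent with R's default behaviour in the
  typical analysis environment.
* **One-way ANOVA** across technical replicates, run separately per
  treatment group on single-cell feature values (replicate as the
  grouping factor). Per-replicate means would leave too few degrees of
  freedom to be informative. A table in which every value is identical
  is flagged degenerate rather than producing a spurious F.
* **2D kernel density** for the dual-marker view: product-Gaussian
  kernel, Scott's rule per axis (σ̂·n^(−1/6)) by default, grid padded
  by 4 bandwidths so the trapezoidal integral over the grid is 1
  within 1%. A zero-variance axis is an error that asks for a manual
  bandwidth.
* p-values are kept exact in code; only display applies the
  conventional 2.2e-16 floor.

The treatment-vs-control report summarises the dual-marker response as
the signed pair of median differences (Δ median 53BP1 sum spot
intensity, Δ median γ-H2AX mean nuclear intensity) — the "diagonal
shift" when both are positive.

## The simulator

The simulator emulates what the pipeline needs to be tested against,
with ground truth:

* **Nuclei**: ellipses with semi-axes uniform in 3.0–4.5 µm, random
  orientation, centres at least twice the maximum radius apart
  (non-overlapping by construction; placement failure after a retry
  budget is an explicit error). DAPI = background + constant nuclear
  level.
* **Foci**: isotropic 2D Gaussians (σ = 0.35 µm, the standard PSF
  approximation) with log-normal amplitudes (median 1500 A.U.,
  geometric SD 1.6), centres uniform inside the (slightly shrunk)
  nucleus, counts Poisson per cell.
* **Condition contrast**: focus rate λ = 1 → 8 foci/cell for both
  markers and pan-nuclear γ-H2AX 200 → 500 A.U. (×2.5) from control
  to treated. These defaults reproduce the direction and approximate
  magnitude of a strong etoposide response; they are simulator
  settings, not estimates of any real dataset. DMSO is simulated
  identically to untreated.
* **Noise**: Poisson shot noise on the clean signal, then additive
  Gaussian read noise (SD 10 A.U.), in that order (camera physics);
  background 100 A.U.
* **Determinism**: every (well, field) gets its own RNG stream derived
  by hashing the master seed with the well id and field index, so
  adding wells to a layout never changes existing wells' images, and
  identical (config, seed) gives byte-identical TIFFs.

`simulate_cell_features()` draws per-cell features directly from the
same generative model without rendering images. It exists for
statistically calibrated experiments — e.g. the inter-replicate ANOVA
type-I-error study, which needs thousands of repetitions where image
rendering would add nothing but runtime.

What the simulator does **not** emulate: spatially varying background
and vignetting, optical aberrations and defocus, nucleus texture and
chromatin heterogeneity, overlapping or deformed nuclei, anisotropic
or clustered foci, pan-nuclear 53BP1 pool variation, bleed-through
between channels, and plate-position effects. Passing the recovery
tests therefore demonstrates correctness of the algorithms under the
stated signal model, not performance on real instrument data — on
real plates the classifier is expected to need fine-tuning per cell
type, which is what `fld_finetune()` is for.

## Validation problem sizes

The test suite and the acceptance script validate on scaled problem
sizes chosen to exercise the same densities, rates, optics and noise
as the full-size defaults: recovery runs use 512×512 px fields with 30
nuclei (the default nucleus density) over 12 fields; the end-to-end
treatment comparison uses 960×960 px fields with 167 nuclei, three
replicate wells × two fields per condition (~1,000 analysed cells per
condition); the ANOVA calibration uses 1,000 repetitions of three
50-cell replicates from the feature-level sampler. Focus-recovery
rates are evaluated on control-condition fields: at the treated rate
(λ = 8) a substantial fraction of true foci lie within about two
detection scales of a neighbour and merge into a single intensity
maximum — an optics limit, not a detector property — whereas the
sparse condition measures single-focus detectability, which is the
quantity of interest.

## File formats and conventions

* Images: single-plane grayscale TIFF, one file per well/field/channel
  named `<WELL>_f<FF>_<CHANNEL>.tif` (e.g. `B03_f04_DAPI.tif`);
  whole-valued images in [0, 65535] are stored as 16-bit integers
  (bit-exact round trip), anything else as 32-bit float with an exact
  power-of-two scaling (valid A.U. range [0, 65536)).
* Tables: CSV, UTF-8, header row, `.` decimal separator; one row per
  cell with a documented mandatory column set.
* Layouts and configs: YAML; classifier models, manifests and reports:
  JSON. Models serialise their sufficient statistics, so a reloaded
  model can be fine-tuned exactly.
* Quantile convention: type-7 (linear interpolation) for IQRs; medians
  are the standard order statistic.

## Known limitations

* The spot detector is 2D; genuinely 3D focus stacks must be projected
  first (acquisition here is single-plane).
* The midpoint decision threshold encodes no class priors; severely
  imbalanced candidate populations may warrant a prior-shifted
  threshold, which the stored class statistics make easy to derive.
* The watershed split handles moderately touching nuclei (the
  dumbbell regime); heavily clumped cell monolayers are out of scope
  of both the simulator and the recovery guarantees.
* The χ² on positive fractions treats cells as independent; within-
  well correlation is not modelled (no mixed-effects layer).
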