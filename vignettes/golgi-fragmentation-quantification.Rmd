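---
title: "Quantifying Golgi fragmentation from imaging flow cytometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Golgi fragmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

The Golgi apparatus is a perinuclear ribbon that fragments — first into
discrete stacks ("partial" fragmentation), then into vesicles dispersed
through the cytoplasm ("full" fragmentation, the mitotic haze) — during
mitosis, apoptosis, trafficking blocks and disease. The classical readout is
manual: stain a Golgi marker (GM130, GRASP65, Giantin), look at 100–500
cells, and assign each to a morphology class by eye. That is slow,
low-throughput and user-biased.

Imaging flow cytometry (IFC) captures a multichannel image of every cell in
flow, which makes an automated, population-scale version of the same
classification possible. `golgifc` implements that pipeline end to end on
three channels per cell — brightfield (BF), a Golgi marker, and a DNA stain —
and validates every stage against a built-in synthetic image generator with
known ground truth.

## Masks and features

All features are computed over a *mask*, a boolean region aligned with the
cell image.

* **Object mask** — pixels above the global Otsu threshold of a channel,
  reduced to the largest 8-connected component, holes filled. For channels
  where several objects are legitimate (a late-anaphase nucleus is two
  objects; a fragmented Golgi is many), the union of all components is used
  instead (`keep = "all"`). The Golgi-channel parent mask uses the union:
  reducing a dispersed Golgi to its largest fragment would erase exactly the
  signal the assay measures.
* **Threshold mask** — the central mask of the assay: the *p*% highest
  intensity pixels of a parent mask (`Threshold_60` on the Golgi stain,
  `Threshold_50` on the DNA stain). "p% highest pixels" is read as a
  pixel-count fraction, `k = ceiling(p/100 * |parent|)`; an
  intensity-fraction variant is available via `threshold_mode =
  "intensity"`. Ties at the cutoff are broken in row-major scan order so
  masks are bit-reproducible.
* **Minor axis intensity** (µm) — with in-mask intensities as weights,
  compute the weighted centroid and the 2×2 weighted second-central-moment
  matrix; with eigenvalues λ₁ ≥ λ₂ the axes of the equivalent-moment ellipse
  are reported as 4√λ (the ±2σ extent). The constant is a convention; any
  fixed positive constant only rescales the gate axis, so it is frozen and
  documented rather than tuned.
* **Area** (µm²) — mask pixel count × pixel area.
* **Gradient RMS** (au) — RMS of the 3×3 Sobel gradient magnitude over the
  mask; an absolute sharpness (focus) metric.
* **BF contrast** (dimensionless) — gradient RMS divided by mean in-mask
  intensity; a brightness-invariant texture metric. Keeping the focus metric
  absolute and the texture metric normalized matches their different uses
  (focus gating vs apoptosis detection).
* **Bright detail intensity** (au) — the in-mask sum of the image minus its
  grayscale opening (disc radius 3 px): intensity of small bright features
  after local-background removal. High for speckled prophase and condensed
  apoptotic nuclei.
* **Total DNA intensity** (au) — summed DNA signal over the object mask
  dilated by 3 px. The dilation matters: condensed mitotic nuclei are
  compact Gaussians whose tails fall outside the raw Otsu mask, and without
  dilation their measured DNA content drops to ~1.65× the G1 mode —
  below the G2/M window — while the true ratio is 2.
* **PulSA triplet** — the in-mask Golgi signal projected onto the x axis
  emulates a cytometer pulse: height = profile maximum, area = profile sum,
  width = span of columns at ≥50% of maximum (FWHM) × pixel size. FWHM is
  the most robust single-threshold pulse-width convention; it is
  config-overridable in spirit (the profile is exposed) but fixed here.

No per-cell background subtraction is applied before moment computation: the
generator adds a constant camera offset, and because moments are computed on
the Threshold-60 mask (bright pixels only) the offset contributes only in
second order. This is a documented limitation for strongly vignetted or
gradient-illuminated real data.

## Feature selection: Fisher's discriminant (RD)

For two labeled populations the separation score of a feature is

RD = (μ₂ − μ₁) / (σ₁ + σ₂)

with sample SDs. `rank_features()` computes RD for every panel feature and
orders by |RD|. On balanced synthetic exemplars the two headline features —
Threshold-60 area and Threshold-60 minor axis intensity — rank at the top of
the panel, which is the selection the assay is built on.

## The gating hierarchy

1. **Singlets**: BF object area inside a calibrated range and aspect ratio
   above a calibrated minimum. Doublets are about twice as large and clearly
   elongated.
2. **Focused**: BF gradient RMS above a calibrated minimum.
3. **DNA content**: the G1 (2N) mode of total DNA intensity is located as
   the lowest-intensity peak of a kernel density estimate whose height is at
   least 25% of the tallest peak. Taking the *lowest prominent* peak rather
   than simply the tallest makes the anchor robust in G2/M-arrested samples,
   where the 4N peak dominates; for resting populations the two rules agree.
   Windows: G1 = 0.75–1.25×, G2/M = 1.7–2.3× the mode (conventional
   flow-cytometry choices, overridable); above 2.3× is excluded as
   aggregates; the remainder is S/indeterminate.
4. **Mitotic sub-phase** (within G2/M): bright detail intensity below its
   threshold → interphase G2; two DNA objects → anaphase if the
   intensity-weighted centroid separation exceeds its threshold, else
   telophase; one compact object (Threshold-50 DNA area below threshold) →
   metaphase; remainder → prophase. Prometaphase (the microtubule-poison
   arrest state) is folded into metaphase: distinguishing it requires visual
   nuclear morphology outside this pipeline's scope.
5. **Apoptosis**: BF contrast above threshold *and* Threshold-50 DNA area
   below threshold — high-contrast cells with condensed DNA.
6. **Golgi morphology** (eligible = singlet ∧ focused cells): on
   x = Threshold-60 minor axis intensity, y = Threshold-60 area,
   *intact* is x ≤ t₁ₓ ∧ y ≤ t₁ᵧ, *full* is x > t₂ₓ ∧ y > t₂ᵧ, *partial*
   is everything else. The four boundaries partition the quadrant; the
   boundary itself belongs to the lower region (closed below, open above),
   a convention frozen for reproducibility and stable under ±1 ulp.

## Gate calibration

Real deployments of this assay draw gates by hand around treatment centers
after visual inspection. Since hand-drawn coordinates are not transferable,
`calibrate_gate_config()` reconstructs every threshold from *labeled
exemplars*: balanced synthetic exemplars (100 cells per Golgi class by
default) for the morphology gates, and dedicated labeled groups (clean vs
doublet vs defocused; healthy vs apoptotic; interphase G2 vs each mitotic
sub-phase) for the scalar thresholds. Between two adjacent classes the
boundary sits at the variance-weighted midpoint

t = (μ₁σ₂ + μ₂σ₁) / (σ₁ + σ₂),

the equal-z-score point of the two class distributions. Class means must be
ordered (intact < partial < full on both gate axes) or fitting aborts with
an error naming the offending axis.

```{r calibrate}
library(golgifc)
config <- calibrate_gate_config(seed = 2)
glance(attr(config, "golgi_fit"))
```

## The synthetic generator

Every downstream stage is validated on populations from `render_cell()` /
`sample_population()`, which emulate:

* **Geometry**: 64×64 px tiles at 0.5 µm/px (no instrument magnification is
  assumed; the tile is sized so a 15 µm cell fits with margin), cell radius
  7.5 µm and nucleus radius 4 µm, each jittered ±8% per cell.
* **Golgi morphologies**: intact = 2–4 overlapping blobs (σ 1.3 px) along a
  60° perinuclear arc — a compact, elongated footprint; partial = 4–8
  puncta (σ 1.5 px) within 1.5× the nucleus radius; full = 20–60 small
  vesicles (σ 0.9 px) across 0.9× the cell radius. Total Golgi intensity is
  class-independent (20 000 au ± 10%), so the gates must work from geometry,
  not brightness.
* **Nuclei**: smooth interphase disks (2N total 40 000 au; G2 exactly
  twice); prophase adds bright speckle; metaphase is an elongated bar;
  anaphase/telophase are two blobs (22 px apart, σ 2.0 / 14 px apart,
  σ 2.6); apoptotic nuclei are 2–4 small very bright fragments plus a
  speckled BF texture.
* **Artifacts**: 5% doublets (second cell at ~1.5 cell radii, 0.8–1.2×
  size) and 5% out-of-focus cells (extra Gaussian blur, σ 2.5–3.5 px) in
  every non-exemplar preset.
* **Noise**: signal = Poisson(clean × gain)/gain + N(0, σ_read) + offset,
  with gain 0.25, σ_read 2 au, offset 5 au, then quantization to 16-bit
  integers (so written TIFFs round-trip exactly).

Preset mixtures encode the studied conditions at the level of their
published population claims (untreated ≈ 80/17/3 intact/partial/full with 2%
apoptotic; nocodazole time courses shifting to partial then full; BFA mostly
partial; TNFα/CHX 6 h with 75% apoptotic nuclei; WI-38 fibroblasts 82/15/3).
Exact per-condition percentages were never published as numbers, only as
bar charts and text bounds, so the mixtures are design constants chosen to
satisfy the text claims — they are the conditions under which the package
validates itself, not measurements.

What the generator does **not** emulate: real GM130 texture statistics,
point-spread functions and spectral bleed-through, illumination gradients,
debris, or cell-to-cell staining variability beyond the ±10% intensity
jitter. Passing tests therefore demonstrate that the *pipeline* is correct
and self-consistent under realistic geometry and noise, not that any
particular biological sample will reproduce the preset percentages.

## Numerical choices

* 8-connectivity for foreground components everywhere (with 4-connected
  background during hole filling); connected components and grayscale
  morphology are compiled code.
* Otsu's threshold on a 256-bin histogram of the min-max-scaled channel.
* Row-major tie-breaking in threshold masks; closed-below gate boundaries;
  deterministic tie-break by feature name in RD rankings.
* Welch's unequal-variance t-test is the default for replicate comparisons
  (safer than the pooled test at n = 3 replicates); the pooled variant is
  available via `var_equal = TRUE`. SEM = sd/√n.
* All randomness is seeded: `render_cell(spec, seed)` is a pure function,
  and `sample_population()` derives one sub-seed per cell.

## Known limitations

* **Gradual morphology, rectangular gates.** The morphology classes are not
  cleanly separated — fragmentation is a continuum — and the *full* gate
  requires exceeding both boundaries while *partial* is the catch-all.
  In populations dominated by full fragmentation (long nocodazole arrest,
  synchronized mitotic peaks) this undercounts the full class by roughly
  10 percentage points, moving it into partial; in populations at or below
  ~15% full the recovered percentages track the generative mixtures within
  ±5 points at n = 5000. Symmetric decision rules (nearest class in
  z-score) remove that bias for full-heavy samples but introduce a
  comparable one for partial-heavy samples; the rectangular convention is
  kept because it matches how such gates are drawn in practice.
* **Mode-anchored DNA gating** assumes a detectable 2N population; a sample
  with no G1 cells needs a manually supplied `g1_mode`.
* **Feature formulas** for gradient RMS, contrast and bright detail
  intensity follow their published verbal definitions; commercial
  implementations may scale differently, so calibrated thresholds are not
  transferable between this package and vendor software.
* **Problem sizes.** The package's own validation uses 100 exemplars per
  class for calibration, 120 cells per auxiliary calibration group, and
  5000-cell populations for end-to-end checks; smaller sizes are used in
  unit tests of individual operators.
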