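# golgifc

Automated, non-subjective quantification of **Golgi apparatus fragmentation**
from imaging-flow-cytometry-style single-cell images.

The Golgi fragments in mitosis, apoptosis, trafficking blocks and disease:
the intact perinuclear ribbon breaks first into discrete stacks (*partial*
fragmentation) and then into vesicles dispersed through the cell (*full*
fragmentation). The classical readout — manually classifying ~100 stained
cells under a microscope — is slow and user-biased. `golgifc` reimplements
the imaging-flow-cytometry alternative as an open, scriptable R pipeline for
cell biologists and cytometrists: thousands of cells per sample, objective
gates, ground-truth validation.

## What it computes

For each cell (brightfield + Golgi marker + DNA stain rasters), features are
computed on masks; the central mask is **Threshold_60**, the 60% highest
intensity pixels of the Golgi staining. The two headline features are

* **Area** — µm² inside the Threshold_60 mask, and
* **Minor Axis Intensity** — the intensity-weighted narrowest dimension of
  the equal-second-moment ("best fit") ellipse of the masked signal:
  with weighted covariance eigenvalues λ₁ ≥ λ₂, minor axis = 4√λ₂ · pixel
  size.

These were selected by **Fisher's discriminant** (the RD value),
RD = (μ₂ − μ₁)/(σ₁ + σ₂), computed between manually labeled morphology
exemplars for every mask × feature combination (`rank_features()`).

Cells then pass a gate hierarchy: singlets (BF area + aspect ratio) →
focused (BF gradient RMS) → DNA content (G1/S/G2M by total DNA intensity
relative to the G1 mode) → mitotic sub-phase (DNA bright-detail intensity,
Threshold_50 DNA area, nuclear component count) and apoptosis (BF contrast
high ∧ Threshold_50 DNA area low) → the three **Golgi morphology gates** on
the (minor axis intensity, area) plane. A **PulSA** (pulse-shape analysis)
baseline — area/width/height of the projected Golgi signal — is included for
comparison.

A built-in synthetic single-cell generator (`sample_population()`) renders
all three morphologies, interphase/mitotic/apoptotic nuclei, doublets and
out-of-focus cells with known ground truth, so the whole pipeline is
testable without any data download.

## Worked example

```r
library(golgifc)

# calibrate every gate from labeled synthetic exemplars
config <- calibrate_gate_config(seed = 2)
glance(attr(config, "golgi_fit"))
#> # A tibble: 1 × 6
#>   x_intact_max y_intact_max x_full_min y_full_min     n resubstitution_accuracy
#>          <dbl>        <dbl>      <dbl>      <dbl> <int>                   <dbl>
#> 1         2.22         8.32       9.57       18.0   300                   0.933

# simulate an untreated-like culture and run the pipeline
pop      <- sample_population(get_preset("untreated"), n = 2000, seed = 1)
features <- compute_features(pop$cells)
result   <- gate_cells(features, config)
summarize_population(result, "untreated")[, c("pct_intact", "pct_partial",
                                              "pct_full", "pct_apoptotic")]
#> # A tibble: 1 × 4
#>   pct_intact pct_partial pct_full pct_apoptotic
#>        <dbl>       <dbl>    <dbl>         <dbl>
#> 1       76.9        19.8     3.31          2.47
```

The fitted gates separate the three morphology exemplars with 93%
resubstitution accuracy, and on the untreated-like population ~77% of
eligible (single, focused) cells carry an intact Golgi, ~3% a fully
fragmented one, and ~2.5% are flagged apoptotic — the profile expected of a
resting transformed culture. `autoplot(attr(config, "golgi_fit"))`,
`plot_density_map()` and `plot_population_summary()` draw the corresponding
gate, density and stacked-bar figures; `compare_replicates()` adds
mean ± SEM and two-tailed Welch t-tests across replicates.

A thin command-line interface over the same functions ships in
`inst/cli/golgifc` (`simulate`, `features`, `rank-features`, `fit-gates`,
`calibrate`, `gate`, `pulsa`, `summarize`).

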