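# mandmap

Surface-based 3D morphometry of the rodent mandible from micro-CT, for
detecting *where* on the bone surface two groups of specimens differ —
the kind of question raised by soft-diet versus hard-diet feeding
experiments in mice, where loading changes remodel the mandible locally
(angular process, condyle, coronoid process, alveolar bone) in ways that
linear 2D measurements cannot localize.

The package implements the full pipeline:

1. **Segmentation** — seeded GrowCut cellular-automaton region growing on
   the CT volume (synchronous updates, 26-neighbourhood, attack strength
   attenuated by `g(x) = 1 - x` on range-normalised intensities),
   morphological cleanup, and watertight isosurface extraction to a
   triangulated surface in mm.
2. **Standardization** — a landmark frame with origin at the mental
   foramen, y-axis normal to the least-squares occlusal (molar-cusp)
   plane, z-axis toward the condyle centre (posterior positive),
   x = y × z (+x lateral, +y superior, +z posterior).
3. **Homogeneous modelling** — a fixed-topology template mesh
   (12,186 nodes, 69 named landmarks) fitted to each specimen by 3D
   thin-plate-spline landmark warping (kernel U(r) = r) followed by
   iterated exact closest-point projection with pinned umbrella smoothing,
   so node *i* corresponds anatomically across all specimens.
4. **Group morphometry** — per-node averaged shapes
   (x̄ per node and axis, sample SD), displacement maps
   Δ = x̄_A − x̄_B (mm), per-node per-axis two-sided two-sample *t*-tests
   (pooled variance; Welch optional) banded at
   p ≤ 0.05 / 0.01 / 0.001 / 0.0001, accentuated averages
   `ref + k (grp − ref)`, and per-region summary tables with anatomical
   direction words (Inward/Outward, Upward/Downward, Forward/Backward).
5. **Synthetic data** — a parametric hemimandible generator (template,
   region atlas, effect fields with known ground truth, shape-mode noise,
   rasterized phantom volumes) so that every stage is testable without
   scan data.

## Worked example

Simulate the study design — 7 control (HD) against 9 soft-diet (SD)
specimens — with a known 0.2 mm inward (−x) displacement of the angular
process in the SD group and 0.02 mm smooth shape noise, then map it:

```r
library(mandmap)

template <- make_template()          # 12,186 nodes, 69 landmarks
effect   <- effect_field("angular_process", dx = -0.2)
study    <- simulate_groups(template, effect, noise_sd = 0.02,
                            landmark_jitter_sd = 0, n_a = 7, n_b = 9,
                            seed = 1)

hd <- lapply(study$group_a, `[[`, "mesh")
sd <- lapply(study$group_b, `[[`, "mesh")

sig <- significance_map(hd, sd)
sig
#> <significance_map> 12186 nodes, student t-test (n = 7 vs 9)
#>   x: 42.4% of nodes p <= 0.05
#>   y: 23.7% of nodes p <= 0.05
#>   z: 0.0% of nodes p <= 0.05

avg_hd <- average_model(hd, "HD"); avg_sd <- average_model(sd, "SD")
difference_map(avg_hd, avg_sd)       # figure convention: HD minus SD
#> <difference_map> HD - SD, 12186 nodes
#>   max |delta| per axis (mm): x 0.175, y 0.048, z 0.011

tbl <- region_summary(difference_map(avg_sd, avg_hd), sig, template)
tbl[tbl$region == "angular_process" & tbl$axis == "x", 1:5]
#>   region          surface   axis  direction significance
#> 1 angular_process lateral   x     Inward    ****
#> 2 angular_process medial    x     Inward    ****
#> 3 angular_process posterior x     Inward    ****
#> 4 angular_process inferior  x     Inward    ****
```

The injected transverse effect is recovered as a strongly significant
inward displacement of the angular-process cells (the effect field's
smooth falloff also displaces adjacent regions, which is why 42% of all
x tests flag); the y flags illustrate that a *single* study's flag
fraction is noisy, because the smooth shape modes correlate nodes — the
null calibration below averages 200 replicates for exactly that reason.
`run_study()` drives the same pipeline from a config (or YAML file),
including per-specimen frame standardization and template fitting, and
writes six per-axis map PLYs, the accentuated model, the summary CSV and
a manifest.

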