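# afmtopo

Quantification of neutrophil activation and NETosis from atomic force
microscopy (AFM) topography.

## The scientific problem

When neutrophils are activated (e.g. by the calcium ionophore A23187 or the
PKC activator PMA) they progress through characteristic morphological
stages: a tall spherical cell with a segmented nucleus (type 1, ~1.2 µm high,
~9.8 µm across) spreads and flattens (type 2, ~0.64 µm, with distinct
nuclear-lobe summits), loses nuclear segmentation (type 3, ~0.3 µm), and
finally disintegrates, shedding a "halo" of sub-micron membrane fragments
and releasing neutrophil extracellular traps (NETs) — chromatin meshworks
whose filaments are beaded with 30–50 nm granules (type 4). AFM height maps
resolve this progression at the nanometre scale, including the *spongiform*
roughness of the membrane itself.

`afmtopo` turns raw AFM height maps into the quantitative readouts of this
process:

- **Spatial roughness spectra.** Height profiles are detrended and Fourier
  transformed into a one-sided, amplitude-squared spectral intensity
  S(ν) [nm²] versus spatial frequency ν = 1/L [nm⁻¹]: a sinusoidal
  corrugation of amplitude A contributes S = A² at its spatial period L.
  Roughness is analysed in two windows — **first order** 600–1200 nm (large
  sponge-like formations) and **second order** 50–300 nm (fine structure) —
  and summarised per window by the peak intensity S_max, its frequency
  ν_max, and the corresponding period L_max = 1/ν_max. Band-pass "order
  surfaces" reconstruct each scale in real space.
- **Morphometrics and staging.** Background estimation, cell segmentation,
  maximum height h_max, equivalent-circle diameter, nuclear-lobe counting by
  topographic prominence, and rule-based classification into types 1–4.
- **Particle statistics.** Detection of halo fragments (6 × 5 µm sections)
  and NET granules, size/height statistics, relative-frequency histograms,
  and a Gaussian-mixture BIC decision between unimodal and bimodal size
  distributions (the halo's distribution shifts from normal to bimodal with
  modes near 0.25 and 0.81 µm late in activation).
- **The statistical layer.** Pearson correlation and ordinary least-squares
  regression of S_max on h_max (slope b in nm), activator-arm slope ratios,
  spectral fold-changes, and exact/approximate Mann–Whitney comparisons.
- **A seeded synthetic scene generator** with full ground truth (cell body,
  band-limited roughness, fragment halo, NET granule chains, substrate
  noise), so every estimator is validated by parameter recovery.

All user-facing functions take and return tibbles (or a small `heightmap`
S3 object for the grids themselves), chain with the pipe, and have
`autoplot()`/`plot_*()` companions and broom-style `tidy()`/`glance()`
methods.

## Worked example

```r
library(afmtopo)

# a synthetic 30 x 30 um scene of a spread (type 2) neutrophil
scene <- make_scene(scene_preset("spread", seed = 42))
scene$map
#> <heightmap> 256 x 256 px, 117.2 nm/px (30 x 30 um), heights -4.23..638 nm

cells <- measure_cell(scene$map)
cells[, c("h_max_nm", "diameter_um", "n_lobes", "type_label")]
#>   h_max_nm diameter_um n_lobes type_label
#> 1  638.158      16.378       3          2
```

The measured cell is 0.638 µm high and 16.4 µm across with three
nuclear-lobe summits — a type 2 cell, matching the scene's ground truth.

```r
# 5 x 5 um membrane nanosurface patch: roughness spectra per window
patch <- make_scene(scene_params(seed = 42))
cell_patch_spectrum(patch$map)$summary
#>     window  S_max_nm2 nu_max_per_nm  L_max_nm
#> 1  order_I 1600.71781        0.0010 1000.0000
#> 2 order_II    5.41169        0.0068  147.0588
```

The patch was generated with first-order roughness of amplitude 40 nm and
period 1000 nm, plus a second-order band of amplitude 2.3 nm: the spectrum
reads back S_max ≈ 40² = 1600 nm² at L_max = 1000 nm and ≈ 5.4 nm² in the
second-order window.

```r
# fragment halo on a 6 x 6 um section (30-min conditions)
sec <- make_scene(scene_preset("fragment_section", seed = 42))
det <- detect_particles(sec$map, estimate_background(sec$map),
                        scale_class = "fragment")
particle_stats(det)
#>    n mean_diameter_nm sd_diameter_nm mean_height_nm sd_height_nm
#> 1 26            214.6           79.7           19.3          2.7

modality_test(sec$truth$fragments$diameter_nm)
#> <modality_result> 1 mode(s) at 335 nm (BIC diff -3.19)
```

All 26 planted fragments are recovered; their early-activation size
distribution is (correctly) declared unimodal. Note the measured
`mean_diameter_nm` is the above-threshold cross-section; the
threshold-cut-corrected `est_basal_diameter_nm` column tracks the true
basal sizes.

```r
# height-spectrum coupling: S_max falls with h_max as the membrane smooths
reg <- correlate_height_spectrum(simulate_height_spectrum_cohort(seed = 42))
tidy(reg)
#>       r  b_nm b_se_nm intercept_nm2     n
#> 1 0.948 0.877  0.0480         -32.4    40
```

A cohort simulated with true slope b = 0.86 nm is recovered at
b̂ = 0.88 ± 0.05 nm with r = 0.95.

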