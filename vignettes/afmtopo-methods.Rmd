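---
title: "Methods: quantifying neutrophil activation from AFM topography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying neutrophil activation from AFM topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmtopo)
```

## Scope and data model

`afmtopo` analyses AFM height maps of neutrophils fixed at successive times
after activation. The raw object is a `heightmap`: a rectangular grid of
heights in nm with an isotropic lateral pixel size, pixel-center
coordinates, and a plain-text native format (whitespace matrix + JSON
sidecar) chosen so data round-trip bit-exactly without vendor software.
Generic AFM ASCII grid exports with `#`-comment headers are imported with
unit normalisation to nm.

Because the original scan data are not publicly deposited, the package
ships a first-class synthetic scene generator that emulates every analysed
morphology with known ground truth. All tests and the acceptance script are
parameter-recovery studies against that truth.

## Roughness spectra

A height profile h(x) sampled at N points with step Δx is detrended
(least-squares line; plane for 2-D maps) and transformed into the
one-sided, amplitude-squared spectral intensity

S_k = |(2/N) Σ_n h_n exp(−2πi k n/N)|²,  ν_k = k/(N·Δx),  k = 1, …

so that a cosine corrugation of amplitude A at an on-grid frequency gives
S = A² at that frequency: S is the squared roughness amplitude per spatial
period. The zero-frequency term and, for even N, the Nyquist term are
excluded; with that convention Σ_k S_k/2 equals the detrended profile
variance exactly for signals with no Nyquist content (the Parseval
property tests use odd N or trend-free band-limited signals). No taper
window is applied before the transform: the synthetic validation places
roughness at on-grid frequencies where leakage is nil, and a taper would
bias the amplitude calibration; for real maps with strong off-grid
components a taper could be added ahead of the transform without changing
any downstream convention.

Two spectral windows are analysed, first order 600–1200 nm and second
order 50–300 nm. Per window we report S_max (the maximum in-window S_k,
window edges inclusive, ties broken toward the lowest frequency, i.e. the
largest period), ν_max and L_max = 1/ν_max. Band-pass "order surfaces"
retain 2-D Fourier coefficients whose radial (isotropic) frequency falls
inside the window band — no orientation is privileged in the measured
membranes — and are real and zero-mean by construction, with variance equal
to the in-band power.

Cell-level spectra use a 5 × 5 µm patch centered on the cell apex. Each
patch row yields a profile spectrum and the spectra are averaged across
rows; averaging stabilises S_max substantially compared to a single
cross-section, and a single-row mode (`rows = "apex"`) is kept for
figure-style output.

## The synthetic generator as a study design

The generator's defaults encode the measured study conditions rather than
convenient values:

- **Scan geometry.** 512 points per line; 5 × 5 µm membrane patches
  (≈9.8 nm/pixel, within the ≤10 nm/pixel nanostructure requirement);
  30 × 30 µm whole-cell scenes at 256 points; 1.5 × 1.5 µm NET mesh patches
  at ≈2.9 nm/pixel.
- **Stage presets.** Control cells 1.2 µm high and 9.8 µm across; spread
  cells 0.638 µm high and 1.7× wider with 2–4 nuclear lobes; flattened
  cells ≈0.3 µm; disintegrated scenes with no intact body and a dense
  halo. Per-stage first-order roughness amplitudes (40, 21, 4 nm) are the
  square roots of the reported stage intensities (≈1600, ≈450, ≈15 nm²);
  the second-order default amplitude 2.3 nm reproduces the ≈5.3 nm²
  control intensity. When stage cohorts are sampled, the drawn roughness
  amplitude scales with the drawn height, reflecting the strong S_max–h_max
  coupling the statistics module quantifies.
- **Fragments and granules.** 26 fragments of 0.33 ± 0.15 µm and height
  16 ± 4 nm at 30 min; a bimodal 0.25/0.81 µm mixture late in activation;
  granule sizes 50 ± 20 nm (A23187-like) on random-walk chains.
- **Substrate noise.** 1 nm SD Gaussian noise — no instrument figure is
  reported, and 1 nm is a typical tapping-mode height-noise scale for
  fixed-cell scans in air.

Design choices worth recording:

- **Cell body.** A super-Gaussian cap h(r) = H·exp(−c·(2r/D)^(2p)) with
  p = 3 (control) to 4 (spread): smooth, with one tunable spreading
  exponent covering the tall-dome to flat-pancake range. The edge constant
  c is set so the cap falls just below the 20 nm segmentation floor at
  r = D/2, making the thresholded footprint diameter match the nominal
  diameter to a fraction of a pixel. Nuclear lobes are Gaussian bumps on a
  ring at 0.22·D (a single lobe sits at the apex); with ≥2 lobes a shallow
  central depression is carved so each lobe is a distinct summit. The body
  plus membrane roughness is rescaled so the scene apex equals the nominal
  height: the advertised h_max is the height of the *rough* membrane
  surface, which is what a real map's maximum measures.
- **Roughness synthesis.** Seeded white noise shaped in the frequency
  domain. Modes are kept when their dominant wavevector component lies
  within 20% of 1/period (hard cut) under a Gaussian envelope of 8% width,
  applied symmetrically around both lattice axes. An isotropic radial
  annulus — the more obvious choice — provably smears 1-D row spectra
  toward lower frequencies (a wavevector at angle θ projects onto the
  profile axis at ν·cosθ), which both biases L_max and inflates the field
  variance; component-wise shaping keeps the row spectra peaked at the
  target period. The field is then rescaled so the in-band peak of the
  row-averaged profile spectrum equals amplitude², making generation and
  measurement mutually consistent by construction.
- **Fragments.** Paraboloid bumps with mixture-drawn equivalent diameters,
  placed by rejection sampling with a 3-pixel margin so they overlap
  neither each other nor the cell footprint; exceeding 10·n placement
  attempts is an error reporting the placed count (ground-truth counts must
  be exact, never silently truncated). Size–height pairs whose
  above-threshold cross-section would cover fewer than ~8 pixels at the
  scene's resolution are redrawn (capped at 50 tries so coarse whole-cell
  scenes still plant scenery fragments): planted fragments at
  fragment-section resolution are recoverable by construction, at the cost
  of a small (<1 SE) upward bias in the realised size mean. Bump heights
  are floored 4 nm above the 10 nm detection threshold for the same reason.
- **NET mesh.** Chains of Gaussian beads (σ = size/4, height = size/2)
  along direction-persistent random walks with steps of 0.75·size, so beads
  overlap in sequence; overlaps take the envelope (max), not the sum.
  Granules must exceed 2 pixels (mesh scenes are generated at ≤3 nm/pixel).
- **Reproducibility.** One integer seed per scene; each component (noise,
  cell, bands, fragments, mesh) derives a named sub-stream, so scenes are
  bit-identical across runs and components are individually reproducible.

What the generator does *not* emulate: scan-line artefacts, tip-sample
convolution, drift, piezo creep, or touching/fused fragments. Passing
recovery tests therefore demonstrate estimator correctness under clean,
non-interacting geometry — not robustness to instrument artefacts, which
real data would add on top.

## Morphometry

- **Background.** The candidate substrate is seeded from the
  lowest-quartile heights; their median and MAD give a crude level and
  noise scale, and the final level/noise are the median and scaled MAD of
  all pixels below crude level + 6 MAD. The second pass removes the
  ≈−1.15σ bias a plain lowest-quartile median would have on a cell-free
  map, while cell pixels stay excluded whenever ≥~25% of the field is
  substrate.
- **Segmentation.** Threshold level + max(3σ, 20 nm) — the 20 nm floor
  prevents noise-driven masks on clean substrates — then the largest
  connected component, holes filled. Secondary components and the fraction
  of above-threshold pixels outside the mask ("particle cover") are
  reported alongside.
- **h_max and diameter.** Maximum in-mask height above the background
  level; equivalent-circle diameter 2·√(area/π) (rotation-stable; the
  profile width through the apex is kept as a secondary output).
- **Lobe counting.** The map is smoothed with a Gaussian kernel
  (FWHM 1200 nm by default) and in-mask summits are counted when their
  topographic prominence (computed by descending flood with union-find)
  exceeds max(5σ_noise, 10% of h_max). The smoothing width sits at the top
  of the first-order roughness window: spongiform roughness at 600–1200 nm
  periods is attenuated by ~e⁻⁵ and cannot out-prominence the floor, while
  nuclear lobes — micrometres wide and several micrometres apart — lose
  little height and are never merged. A narrower kernel (e.g. 250 nm)
  leaves the 1000 nm roughness essentially untouched and produces spurious
  lobes on mid-height cells; the width remains a configurable knob.
- **Typing rules**, applied in order: type 4 if the mask is fragmented
  (solidity < 0.5), a mesh is flagged, or the object is flat (<150 nm)
  amid high off-mask particle cover (>0.3); type 1 if h_max ≥ 900 nm and
  diameter ≤ 12 µm; then types 2/3 by lobe count (≥2 vs ≤1); anything
  else is "other". The 900 nm and 12 µm cuts bisect the reported
  control vs spread morphometrics; scene ground truth uses the same rule
  table on the *true* parameters, so classification accuracy measures
  estimator error, not rule disagreement. AFM cannot see the nucleus
  directly: lobe counting treats apex topography as a proxy for nuclear
  segmentation.

## Particles and modality

Particles are connected components above level + max(3σ, floor) outside
the cell mask, with floor 10 nm (fragments) or 2 nm (granules) and a
4-pixel minimum area. Two robustness steps precede labelling: a 3 × 3
median despeckle (single-pixel noise excursions at the threshold contour
otherwise split low particles or seed false ones) and a 1-pixel
morphological closing (re-attaching rim slivers that noise detaches from
particles whose peak sits only a few nm above the floor). Touching
particles merge — there is no watershed splitting — and a fixture
exercises that documented limitation; NET granule chains therefore merge
into filament-scale components, so granule *size statistics* come from the
generator truth or fine-pitch isolated-bead scenes, and mesh detection is
used for coverage only.

The measured equivalent diameter 2·√(area/π) describes the
above-threshold cross-section, which understates basal size; for a
paraboloid cap cut at height c the basal diameter is the measured one
divided by √(1 − c/h), reported as `est_basal_diameter_nm`.

Modality of a size sample (n ≥ 8) is decided by fitting one- and
two-component Gaussian mixtures with unequal variances (mclust's
deterministic model-based hierarchical initialisation, so no random
restarts are needed) and declaring bimodality when the two-component BIC
improves by more than 2 — the conventional "positive evidence" threshold.
The decision is invariant to unit rescaling, since a change of units
shifts both models' log-likelihoods equally. Mixtures are fitted
untruncated with a positivity check; at the observed size/SD ratios the
truncation mass is negligible.

## Statistics

The regression of S_max [nm²] on h_max [nm] is ordinary least squares
(slope b in nm, which fixes the direction: nm²/nm), pooled across time
points within one activator arm and order, with Pearson r alongside;
activator-arm slope ratios are rounded to 2 decimals and fold-changes to 2
significant figures, matching the conventions in which 0.86/1.12 → 0.77
and 1800/10 → 180. Mann–Whitney comparisons are two-sided; the exact null
distribution is used when the smaller sample has ≤8 observations and no
ties (the tests verify it against full enumeration for all n ≤ 6), and the
normal approximation with tie and continuity corrections otherwise. No
multiple-testing correction is applied to the panel comparisons, matching
the source analyses; stars are \*, \*\*, \*\*\* at 0.05, 0.01, 0.001.
`build_report()` assembles the per-time tables (types, morphometrics,
spectra, fragments, granules, regression) and `write_report()` writes
them as CSV/JSON plus a timestamp-free run log, so identical inputs yield
byte-identical output.

## Problem sizes and numerical choices

The validation studies use 20 seeds for membrane-patch roughness recovery
(512² patches), 10 seeds per stage preset for morphometric recovery, 200
cells for classification (256² scenes), 50 sections for fragment-count
exactness (512² sections), 20 seeds for each modality arm (n = 58 sizes,
the late-activation section count), and 50 cohorts of n = 40 for
regression recovery — sizes at which the binomial uncertainty on the ≥90%
recovery criteria is well below the margin actually observed. Degenerate
inputs (empty masks, constant heights, zero denominators, out-of-Nyquist
periods, sub-resolution granules, impossible packings) raise classed
errors rather than returning sentinel values; spectral window edges are
inclusive with a 1e-12 frequency tolerance; S_max ties break to the
largest period.

## Known limitations

- Touching particles are counted as one; fragment crowding late in
  activation will undercount unless sections are chosen sparse.
- Raw particle sizes are threshold-cut cross-sections; use the corrected
  basal estimate (or the planted truth, in synthetic studies) when
  comparing to profile-based size readings.
- The classifier's mesh flag must be supplied (or inferred from
  fragmentation/cover rules) on whole-cell scans, whose pixel size cannot
  resolve 30–50 nm granules.
- No tip-deconvolution or scan-line flattening beyond detrending: heavily
  bowed or streaked real scans need preprocessing before import.
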