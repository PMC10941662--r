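---
title: "Methods: spectral unmixing and quantitation in specmix"
author: "specmix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral unmixing and quantitation in specmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specmix)
```

## The measurement model

Highly multiplexed fluorescence imaging in autofluorescent tissue (whole-mount
embryos, thick brain sections) cannot rely on one bandpass filter per
fluorophore: ten dyes packed across the visible/near-IR spectrum overlap
heavily, and tissue autofluorescence (AF) contaminates every band. Spectral
imaging instead acquires, for every pixel, an M-dimensional measurement
vector across multiple excitation lines and multiple detector emission bands
per line. `specmix` models this axis with an `acquisition_scheme()`: ordered
excitation wavelengths, each with 1–4 emission bands, the bundled fixture
(`hcr10_scheme()`) using 11 excitations and 26 detectors in total.

Each channel — every fluorophore, and AF treated as an additional channel —
contributes a characteristic *reference spectrum*: its M-vector of responses,
measured in a 1-plex sample (or an unlabeled sample for AF). A pixel's
spectrum \(b \in \mathbb{R}^M\) is modelled as a linear superposition of the
reference spectra with unknown non-negative coefficients:

\[
b \approx R\,x,\qquad x \ge 0,
\]

where \(R\) is the \(M \times C\) reference matrix (`reference_matrix()`,
fluorophore columns first, AF columns last). Per-pixel unmixing solves the
non-negative least-squares (NNLS) problem

\[
\hat x = \arg\min_{x \ge 0} \lVert R x - b \rVert_2,
\]

and the unmixed image is one coefficient map per channel plus the per-pixel
residual norm. Assumptions worth stating explicitly:

* **Linearity.** Signals superpose additively; no quenching, FRET, or
  detector saturation. Amplified HCR signal is approximately linear in
  target count, which is what makes the downstream quantitation meaningful.
* **Spatially constant references.** One spectrum per channel for the whole
  image. Samples with spectrally distinct AF sources can add AF columns
  (`add_af_channels()`), one reference per source.
* **Unweighted least squares.** The objective is plain Euclidean; no
  Poisson variance weighting or background pre-subtraction is applied. A
  weighting hook would change the statistical efficiency at low counts but
  not the model, and is deliberately left out of the default contract.

## Reference spectra: extraction and conventions

`extract_reference_spectrum()` averages the M-vectors of the brightest
pixels — by default the top 0.1% by summed spectral intensity — as an
anatomy-free, reproducible proxy for a "region of maximum expression", then
normalizes. An explicit mask can override the quantile rule when an
anatomical region is preferable.

Two conventions were genuinely open and are fixed as follows:

* **Normalization: per-spectrum maximum = 1.** (The alternative, per-detector
  normalization, couples columns to each other.) With max-1 columns the
  unmixed coefficient of a channel is on the same intensity scale as the raw
  image, which keeps signal-to-background ratios and voxel statistics
  interpretable.
* **Selection fraction 0.001.** Small enough to sit inside the expression
  maximum of a typical 1-plex stain, large enough (hundreds of pixels on a
  realistic frame) to average down shot noise. It is exposed as
  `top_fraction`.

Extraction is invariant to positive rescaling of the input image, so gain
differences between reference acquisitions do not matter.

Because near-collinear reference columns make coefficients unstable,
`condition_report()` reports the condition number, all pairwise cosine
similarities, and the minimum pairwise angle, warning (never failing) below
a configurable 5° threshold.

## Placing the autofluorescence channel

AF has no "right" excitation a priori; it is sample dependent. From an
excitation–emission matrix scan (`eem_scan()`), `optimize_af_channel()`
scores each excitation by its total emission red of the line plus a guard
offset and picks the maximum (ties toward the shortest wavelength, for
determinism). Detector bands are then laid out as `n_detectors` contiguous
equal-width bands from the guard edge to the red end of the scanned range.
The 10 nm guard offset keeps the first band clear of the excitation line's
scatter; the equal-width contiguous banding is the package's own rule —
nothing in the problem pins down a banding, and this one is parameter-free
and covers the emission range without gaps.

## The NNLS solver

`solve_nnls()` is a Lawson–Hanson active-set solver written for this
package's regime: \(C \le\) ~12 channels, \(M \le\) ~26 measurements,
millions of independent pixels. Design points:

* It runs on the normal equations (`G = R'R`, `h = R'b`), so the per-pixel
  cost is independent of M after one `crossprod`. At condition numbers
  typical of usable reference matrices (the bundled fixture's is ≈3) the
  squared conditioning is harmless at double precision.
* The KKT tolerance defaults to `1e-10 * max(|h|, 1)`, making the solution
  scale-equivariant: unmixing \(\alpha b\) gives \(\alpha \hat x\).
* The active set terminates at the exact constrained minimum (it is a
  finite algorithm for a strictly convex problem when R has full column
  rank); the test suite verifies agreement with an exhaustive
  support-enumeration oracle to 1e-9 on hundreds of random instances.
* Degenerate inputs: `b = 0` returns `x = 0` with zero residual; negative
  raw intensities (detector offset artifacts) are clamped to zero at image
  construction with a warning; non-finite values are errors.
* `unmix_image()` chunks pixels purely for memory locality — every pixel is
  an independent solve, so chunked and per-pixel evaluation are
  bit-identical (and tested to be).

The residual map is the unnormalized Euclidean misfit per pixel; a relative
residual (`residual / ||b||`, zero for empty pixels) is carried alongside
for QC, since the absolute norm scales with brightness.

## The simulator

Every quantitative claim in the test suite is validated against
`render_spectral_image()`, a forward model with known ground truth:

* **Fluorophores** are Gaussian in excitation and emission
  (`fluorophore_model()`). Real dye spectra are asymmetric with vibronic
  shoulders; Gaussians are used because band integrals are analytic (normal
  CDF) and overlap between neighbours is directly controllable. The bundled
  10-plex set (`hcr10_fluorophores()`) places excitation peaks on the
  fixture's laser lines with emission peaks spanning 425–795 nm and ~41 nm
  spacing against ~20 nm emission widths — heavily overlapping by
  construction, so separation genuinely exercises the unmixing.
* **Scenes** (`scene_spec()`) define per-channel abundance fields from
  geometric domains and/or Gaussian point sources, an AF field (smooth
  low-frequency map), and a noise model. Redundant two-channel detection of
  one target is modelled by two channels sharing one field up to gains
  (`make_redundant_detection_scene()`); single-molecule fields of view by
  shared dot positions with a minimum separation
  (`make_single_molecule_scene()`).
* **Noise** is Poisson on a photon scale — expected intensity times a
  `photon_budget`, drawn, rescaled — plus optional Gaussian read noise,
  clamped at zero. With noise off the render equals the linear model
  exactly, which anchors the machine-precision round-trip tests. All
  randomness derives from one master seed with per-stage substreams, so
  stages can be re-run independently and runs are bit-reproducible.
* **Not modelled:** optical sectioning and defocus, bleaching, chromatic
  aberration, detector crosstalk beyond band integration, and real dyes'
  asymmetric spectra. Passing tests therefore demonstrate the correctness
  of the *computational* pipeline under its stated model, not robustness to
  those instrument effects; on real data the residual map and condition
  diagnostics are the intended guardrails.

Photon budgets are expressed per intensity unit; raw-count calibrations are
instrument specific, so the validation scenes use budgets \(10^2\)–\(10^4\)
photons per unit, spanning visibly noisy to near-noiseless imaging.

## Quantitation layers

**Signal-to-background** (`signal_to_background()`): mean over a
high-expression mask minus mean over a no/low-expression mask, divided by
the latter. Any residual expression in the "background" mask inflates the
denominator, so the estimate is a lower bound on true S/B — a property the
tests check directly by contaminating the background mask and verifying the
estimate can only drop. Means (not medians) are used for both regions.

**qHCR voxel statistics**: `bin_voxels()` partitions the grid into blocks
of physical size `voxel_size` (pixels per voxel = `round(voxel/pixel)`,
minimum 1 — e.g. 0.18 µm pixels and 2.0 µm voxels give 11 pixels per axis),
sums intensities within blocks, and drops trailing partial blocks. Sum
rather than mean: a voxel's amplified signal models the molecule count it
contains, and the sum scales linearly with content.
`normalize_voxels()` divides by the channel's 99.9th-percentile voxel
(robust to single hot voxels, unlike the max; values above it simply exceed
1). `qhcr_scatter_stats()` then reports the Pearson correlation, the
least-squares slope through the origin \( \sum ab / \sum a^2 \), and a
free-intercept OLS fit — the intercept is reported precisely so that the
zero-intercept expectation of redundant detection is checkable rather than
assumed. Note that per-channel quantile normalization maps both channels to
a common scale, so gain ratios should be read from the *unnormalized* slope
(`normalize = FALSE`); the correlation is scale-invariant either way. No
background subtraction is applied before voxel statistics by default.

**Display scaling** (`display_scale()`): replicate images are pooled, the
`1 - saturation_fraction` order statistic becomes the clip value (default
0.1% of pixels saturated; 0 means no saturated pixels), and `[0, clip]`
maps linearly to 8-bit.

## Dot detection and colocalization

`detect_dots()` uses the scale-normalized Laplacian of Gaussian — the
standard, parameter-light blob detector — with anisotropy handled by
per-axis sigma in pixel units (`sigma_um / pixel_size`); axial sigma below
one pixel is clamped to one pixel with a warning, which is the honest thing
to do on coarse z-sampling. Detections are local maxima over space and
adjacent scales above a threshold; maxima closer than `min_separation_um`
(default twice the mean scale) keep the stronger response. No sub-pixel
Gaussian refinement is attempted; accuracy is pixel-level by design.

`colocalize()` matches dots one-to-one by greedy ascending-distance
assignment among pairs within a radius (default twice the mean detection
scale; ties broken by dot index for determinism). Greedy was chosen over
optimal assignment because at single-molecule densities dots are far apart
relative to the radius, where greedy *is* optimal — the suite verifies this
against a brute-force minimum-cost oracle on such instances. The
colocalization fraction of a channel is the matched fraction of its dots;
as detection errors vanish it approaches one from below, which the tests
exercise by sweeping the photon budget. `coloc_summary()` reports
mean ± s.e.m. over replicate specimens (s.e.m. 0 with a warning for n = 1).

## Numerical and I/O choices

* Arrays are (Z, Y, X[, channel]), 1-based in R; physical coordinates in µm
  with the origin at the outer corner of voxel (1,1,1) and voxel centers at
  `(i - 0.5) * pixel_size`. All CSVs use µm.
* Stacks are exchanged as multi-page 32-bit TIFF plus a JSON sidecar (axes,
  pixel sizes, scheme, channel names). Samples are quantized to 32 bits
  against a power-of-two full scale recorded in the sidecar — precision
  2^-33 of full scale — and the writer is quantization-aware, so write/read
  cycles are bit-stable.
* Coefficients stay floating point end to end; 8-bit conversion happens
  only in `display_scale()`.
* `run_workflow()` validates its YAML/list config strictly (unknown keys are
  errors), derives all randomness from one master seed, collects warnings
  into a JSON run report, and is bit-reproducible for fixed config and
  inputs.

## Validation problem sizes

The shipped validation uses deliberately small grids chosen to exercise
every code path at comfortable runtimes: 64×64×3 for the noise-free
round trip (max relative abundance error at machine precision), 48×48×3
across photon budgets \(10^2, 10^3, 10^4\) for noisy recovery (median
relative error under 5% at \(10^4\), improving monotonically with budget),
redundant-detection scenes binned to 2.0×2.0×1.2 µm voxels for qHCR
linearity (r ≥ 0.95, slope within 5% of the simulated gain ratio, free
intercept within 0.02 normalized units), and 25-dot single-molecule scenes
in triplicate for colocalization (both fractions ≥ 0.9 at high SNR).
`scripts/acceptance.R` recomputes all of these from scratch for any seed.

## Known limitations

* The solver is exact but pure R; per-pixel cost is microseconds, fine for
  the stack sizes here, but a compiled inner loop would be the next step
  for full-frame tiled acquisitions.
* One reference spectrum per channel per image; spatially varying spectra
  (depth-dependent attenuation, fixative gradients) appear as structured
  residual, not as corrected coefficients.
* Dot detection reports pixel-resolution positions and makes no attempt at
  absolute intensity calibration.
* The simulator's idealizations listed above mean real-data performance
  must be judged with the residual and conditioning diagnostics, not
  extrapolated from synthetic tests.
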