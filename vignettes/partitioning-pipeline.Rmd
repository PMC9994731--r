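---
title: "Quantifying cryoprotectant partitioning from Raman image cubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cryoprotectant partitioning from Raman image cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement

When a cell suspension freezes, ice excludes solutes, so the remaining
liquid collects in *unfrozen channels* between extracellular ice crystals.
A penetrating cryoprotectant such as DMSO distributes between these
channels and the cell interior, and where it sits at low temperature is
believed to drive survival. Confocal Raman microspectroscopy measures this
label-free: each pixel of a small raster (typically 45 × 45 or 60 × 60
pixels at ~200–333 nm pitch, one spectrum per pixel at ~4.83 cm⁻¹ per
step) carries a full vibrational spectrum, and the area under a marker
band is proportional to the local concentration of its carrier:

| band     | search range (cm⁻¹) | start (cm⁻¹) | assignment                  | marks        |
|----------|--------------------:|-------------:|-----------------------------|--------------|
| ice      | 3087–3162           | 3125         | OH stretching               | ice          |
| protein  | 1610–1710           | 1660         | Amide I / alkyl C=C         | the cell     |
| dmso     | 650–740             | 673          | symmetric CS stretching     | DMSO         |
| dna      | 760–810             | 785          | O–P–O backbone              | the nucleus  |

The headline statistic is the partitioning ratio

$$P \;=\; \frac{C_o}{C_i},$$

where $C_o$ is the mean background-subtracted integrated DMSO intensity
over unfrozen-channel pixels and $C_i$ the mean over cell pixels. $P
\approx 1$ means the cryoprotectant equilibrated across the membrane; $P
\ll 1$ means it is trapped inside; $P > 1$ indicates incomplete
dehydration at faster cooling. Only relative intensities within one image
are meaningful, so $P$, the intracellular coefficient of variation
(CV = sd/mean over cell pixels, the heterogeneity measure) and the
intracellular ice area fraction (AIC = ice area / cell area) are all
ratios.

The protein-band search range is taken as 1610–1710 cm⁻¹, symmetric
about the 1660 cm⁻¹ starting wavenumber and consistent with the
75–95 cm⁻¹ spans of the other bands.

## Peak quantification

For every pixel and band, `find_peak_window()` locates the local maximum
nearest the band's starting wavenumber within the search range, then walks
outward along each flank. A side's boundary is the first sample whose
outward first difference has flattened to at most `derivative_sensitivity`
(default 0.1) times the first difference one step inward. Derivative
thresholding of this kind can be formulated in several ways; the outward
walk from the maximum is the reading adopted here because it produces the
expected operating behavior — window widths consistently between 4 and 8
axis steps — and is well defined for asymmetric peaks. The width is
finally clamped into
`[min_peak_steps, max_peak_steps]` (default 4–8) by trimming the longer
flank first, or extending the shorter one, about the maximum; ties prefer
the upper side. All step-denominated rules count samples on the axis
actually supplied, whose nominal step is derived from the axis rather than
assumed.

`integrate_peak()` subtracts the minimum value within the window (the
background estimate — deliberately not a fitted baseline) and integrates
by the trapezoidal rule on the true wavenumber spacing. This makes the
integral exactly linear in amplitude, invariant to constant offsets, and
exact for piecewise-linear peaks, all of which the test suite asserts.
Flat spectra are flagged and integrate to zero. No smoothing is applied
before differentiation; the slopes are raw first differences.

A consequence worth knowing: with minimum-value (chord) subtraction the
integral is sensitive to the window edges, so the procedure only yields
per-pixel-comparable intensities when the derivative rule lands
consistent windows — which is precisely the regime this class of
instrument's signal-to-noise supports.

## Cosmic-ray despiking and image QC

Cosmic rays hit the detector as single-sample, single-pixel spikes, so a
spiked pixel is always a strict local maximum of the intensity map.
`detect_spikes()` flags a pixel when its value exceeds the **maximum** of
its 8 neighbors by more than `spike_k = 5` times a robust scale. Two
design points, both reached by measurement on phantoms:

* comparing against the neighborhood *median* mislabels compartment
  boundaries — at an even class split the 8-sample median sits midway
  between the two intensity levels, so ordinary boundary pixels look like
  outliers; the max-based comparison is strictly stronger and immune to
  this;
* the scale is 1.4826 × MAD over the surrounding 5 × 5 ring (24 samples):
  an 8-sample MAD is so unstable that k = 5 rules based on it flag ~1% of
  pixels of plain Gaussian noise. The scale is floored by a global robust
  scale (map-wide median of |value − neighborhood median|, which sparse
  spikes cannot inflate) and by 10⁻¹² of the map maximum.

`despike_map()` replaces each flagged pixel by the mean of its 8
neighbors, re-detects, and repeats up to `max_despike_passes = 3`
replacement rounds. If the first pass flags more than
`scatter_reject_threshold = 10` pixels the image is marked rejected and
returned untouched: that much scattered signal is not repairable. In the
end-to-end `analyze_cube()` the rejection rule is evaluated on the union
of the DMSO and ice spike masks by default (`spike_scope = "union"`),
since cosmic rays are band-agnostic.

## Compartment segmentation

The cell is found on the Amide I map by a classical morphology chain:
Sobel gradient-magnitude edge detection thresholded at `edge_sensitivity`
(0.5–0.9, default 0.65) times an automatic level (4 × the mean gradient
magnitude — the classical auto-threshold convention; raising the
sensitivity strictly cannot add edge pixels); dilation of the edge image
with perpendicular line elements of length 3 (0° and 90°); hole filling;
clearing of border-touching components; one smoothing erosion; and
selection of the largest 4-connected component, which must be off-border
and at least 50 pixels.

The structuring-element sizes are exposed in the configuration. The default smoothing erosion is a 5 × 5 box rather than
the radius-1 diamond one might first try, and the reason is geometric: a
step edge excites the 3 × 3 Sobel operator on *both* sides, giving a
2-pixel edge ring, and the two line dilations add one more Chebyshev
unit. An erosion matched to that accumulated dilation (Chebyshev radius
2) recovers a convex cell exactly — on noise-free disk phantoms the mask
equals the true disk — while the diamond leaves a systematic one-ring
bias that alone would push the recovered $C_i$ off by the boundary-ring
fraction. Sobel gradients are computed by exact matrix shifts with
replicated borders, avoiding FFT-based convolution wrap-around.

Ice pixels are those at or above an automatic bimodal (Otsu) threshold of
the OH map (a manual threshold can be substituted), split by the cell
mask into extracellular and intracellular parts; intracellular
single-pixel components are discarded as shot noise. The unfrozen channel
is the extracellular complement, so cell, extracellular ice and channel
partition the raster — an invariant asserted on every segmentation
output. Cells with extensive intracellular ice (AIC ≥ `iif_reject_aic`,
default 0.05) are rejected by `analyze_cube()` unless `allow_iif = TRUE`,
mirroring how such cells are screened in practice while still allowing
their dedicated analysis.

## Derived statistics

* `partitioning_ratio()` — $C_o$ averages channel pixels only, never
  extracellular ice (the solute is excluded from the ice phase). $C_i$
  averages all cell pixels *including* intracellular ice by default,
  because the ice-bearing analyses report $P$ without stating an
  exclusion; `exclude_iif_from_ci` flips this, making the alternative
  testable. Results with fewer than 50 cell pixels are flagged
  low-confidence.
* `coefficient_of_variation()` — sample (n−1) standard deviation over the
  mean; the sample form is the conservative default.
* `line_scan()` / `line_scan_ratio()` — the cross-validation estimator
  pools a horizontal and a vertical scan band through the cell centroid,
  three pixels wide (`half_width = 1`): a drawn line has finite
  thickness, and averaging across it suppresses single-row sampling
  noise. On phantoms this estimator agrees with the mask-based $P$ to
  within a few percent.
* `manual_region_ratio()` — the hand-validation estimator: ≥ 50 (default
  100) pixels per compartment drawn from unambiguous regions (cell
  interior, channel away from the membrane), as an analyst would select.
* `gap_profile()` — mean channel DMSO intensity binned by Chebyshev
  distance to the nearest extracellular-ice pixel (default 6 equal-width
  bins; only occupied bins are reported). Chebyshev distance is the
  natural pixel-adjacency metric; the binning axis is a package
  convention.
* `nucleus_cytosol_ratio()` — nucleus from an Otsu threshold of the DNA
  band within the cell; mean DMSO in the nucleus over mean DMSO in the
  remaining cytosol.
* `replicate_summary()` — mean, standard error, and a two-sample t-test.
  Welch's unequal-variance form is the safer default when group
  variances may differ; `welch = FALSE` gives the pooled Student form.
* `abbe_resolution()` — the diffraction limit λ/(2·NA), the form
  consistent with the instrument's quoted ~0.3 µm at 532 nm and NA 0.90;
  the 0.61·λ/NA Rayleigh variant is available behind a flag and does not
  reproduce that figure.

## The synthetic phantom

Raw low-temperature image cubes of this kind are rarely shareable, so
every stage is validated against `generate_scene()` / `render_cube()` phantoms with
known truth. The scene is a disk cell (default radius 10 px in a 45 × 45
raster) with a disk nucleus, extracellular space tiled by Voronoi ice
crystals separated by unfrozen channels of configurable width (default
4 px — wide enough to carry a measurable interior concentration profile)
plus an unfrozen halo around the cell, and optional intracellular ice
pockets grown to a target area fraction within ±0.02. Single-pixel
protrusions of either extracellular phase are reassigned to the local
majority, since real crystal fronts are compact at this resolution.

Concentration fields: intracellular DMSO is an i.i.d. lognormal field
with relative spread `heterogeneity_sd` (default 0.15, the CV observed
for cells frozen in 5–10% DMSO; the low-concentration preset uses 0.42);
channel DMSO is flat, or rises with distance from the ice interface when
`gradient_toward_ice` emulates solute polarization; DMSO is zero on all
ice. The default channel/cell ratio is 1.07, the baseline condition;
presets cover the low-concentration (0.21), fast-cooling (1.30) and
intracellular-ice conditions. The Amide I field is 100 inside the cell
(lognormal, 10% spread) against a background of 5; OH is 100 on ice, 25
in channels, 20 in the cell; DNA is 40 in the nucleus against 4 in the
cytosol.

Rendering places a Gaussian line of sd = 2 axis steps at each band's
starting wavenumber, scaled by the pixel's concentration, over a constant
baseline of 20. Detector noise is zero-mean Gaussian with sd =
`noise_sd` × local signal + floor (floor = 10 × `noise_sd`), defaulting
to 1%. The default matters: at several percent noise the per-sample slope
noise rivals the Gaussian flank slopes, the derivative-threshold window
jitters between 4 and 8 steps from pixel to pixel, and with chord
background subtraction the integral differs severalfold between those
widths — the map variance becomes window-jitter-dominated, which
contradicts the documented consistent-width regime. At 1% the walk
deterministically reaches the 8-step clamp and integrals are stable.
Absent a detector noise model to fit, this default is the convention
that reproduces the consistent-width operating regime.
Cosmic spikes are injected as single-sample spikes of
`spike_amplitude` × the maximum clean signal (default 10×) at sparse
random pixels (pairwise Chebyshev separation ≥ 2, so injected counts are
exact) at wavenumbers within ±2 steps of a configurable band's peak
(default DMSO, so the spike count on the DMSO map equals `n_spikes`).
All randomness flows from one seed through named substreams (geometry,
fields, noise, spikes), so stages can be varied independently and every
scene and cube is bit-reproducible.

What the phantom does **not** emulate: freezing physics (no transport
equations or phase-field growth — geometry and fields are statistical
stand-ins), spatially correlated intracellular structure (heterogeneity
is i.i.d., so subcellular organelles' smooth texture is absent),
realistic fluorescence baselines (the baseline is constant), or detector
nonlinearity. Passing tests therefore demonstrate that the *algorithms*
recover known truth under the assumed statistical structure, not that the
pipeline is robust to every artifact of real instruments.

## Numerical choices and degenerate inputs

Windows are clamped symmetrically about the located maximum with
upper-side tie preference; flat spectra yield a minimal centered window
whose integral is zero. A constant ice map yields empty ice masks; a
degenerate DNA signal raises a no-nucleus error; an empty channel raises
an empty-channel error ($C_o$ undefined); a cell mask averaging to zero
raises a degenerate-cell error. Cube tables are written at full double
precision (`%.17g`) and round-trip exactly. Otsu thresholds use 256
histogram levels on the normalized range. The spacing of a supplied axis
may deviate from its nominal step by at most 10%.

## Problem sizes

The test suite and the analysis scripts work at the native image
scale of such measurements (45 × 45 pixels, 549 spectral samples) with 20-phantom sweeps for
the recovery and cross-validation properties and 5–8 phantom batches for
segmentation and ice properties; a full single-image analysis takes a few
seconds on one core. These sizes were chosen to match the imaging
conditions the pipeline targets while keeping every check runnable on a
laptop.

## Known limitations

* The derivative-threshold boundary rule (outward walk) is one of
  several defensible formulations of derivative thresholding; it is a
  package convention.
* Otsu thresholding of the OH map is the package's choice; a manual
  threshold can be substituted where an analyst prefers one.
* The spike detector's rejection count is evaluated on integrated maps;
  rays that fall outside every band's integration window are invisible
  to it (and to the statistics).
* With `exclude_iif_from_ci = FALSE` (default), $C_i$ mixes zero-DMSO ice
  pixels into the intracellular mean for ice-bearing cells; both
  conventions are available and explicitly configurable.
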