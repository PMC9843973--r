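---
title: "Multiscale infrared analysis of fungal lipids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale infrared analysis of fungal lipids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlipid)
```

`mirlipid` processes mid-infrared measurements of oleaginous, dimorphic
fungal biomass at three scales — bulk dried biomass (transmission and ATR
FTIR), single cells (FPA-FTIR imaging) and single lipid droplets (AFM-IR) —
and ships a forward simulator that generates all three kinds of data with
retained ground truth. This vignette explains the models behind each stage,
the tunable parameters and their defaults, what the simulator does and does
not emulate, and the numerical conventions.

## Bulk preprocessing

Absorbance is computed from single-beam intensities as A = −log10(S/B),
with strictly positive backgrounds enforced.

**Savitzky-Golay filtering** (`savitzky_golay()`) fits a local polynomial
in a sliding window. The defaults follow common FTIR practice: window 15
points, polynomial order 2, and derivative order 2 for band sharpening.
Derivatives are taken with respect to wavenumber (cm⁻¹), so the second
derivative of a·ν̃² is exactly 2a; edge points come from the polynomial
fitted at the nearest full window, keeping the output the same length as
the input (map pipelines need constant length). The filter is linear, which
the test suite asserts directly.

**EMSC** (`emsc_fit_correct()`) models each spectrum as
s = a + b·m + d₁t + d₂t² + e against a reference m, where t is the
wavenumber axis mapped affinely onto [−1, 1] before polynomial
construction — raw wavenumbers in the thousands would make the normal
equations badly conditioned, so coefficients d₁, d₂ are reported in mapped
units. The corrected spectrum (s − a − d₁t − d₂t²)/b removes additive
offsets, multiplicative scaling and smooth baseline trends while leaving
the chemical residual intact. The reference defaults to the collection mean
(standard practice when no extract spectrum is available; an explicit
reference can be passed). Spectra with |b| below `b_tol` (default 1e-8) are
flagged and returned uncorrected rather than divided by a near-zero scale.
Correction is idempotent: the residual is orthogonal to the model basis, so
a second pass fits (a, b, d₁, d₂) = (0, 1, 0, 0).

The derivative-then-EMSC order is the default preprocessing sequence for
the campaign analysis; both orders are supported since the optimal choice
depends on whether scatter enters additively or multiplicatively in a given
data set.

**Spectral regions** follow the biochemical window convention for fungal
biomass: combined lipid (3050–2800 and 1800–1700 cm⁻¹), protein
(1700–1500), mixed (1500–1200), polysaccharide + polyphosphate (1200–700).
Regions are closed-interval unions, merged when overlapping; selecting a
disjoint region concatenates its blocks. Peak picking deliberately filters
the *full* spectrum before restricting to a region — filtering a
concatenated disjoint signal would manufacture edge artifacts at every
interval boundary.

## ANOVA-PCA

For a campaign with two crossed factors (cultivation condition and storage
day), `decompose_effects()` partitions the spectra-by-channel matrix X into

* grand mean (column mean of X),
* condition effect rows: condition-level mean − grand mean,
* day effect rows: day-level mean − grand mean,
* interaction rows: cell mean − both level means + grand mean,
* residual: the remainder.

The partition reconstructs X exactly (asserted to 1e-10), and for balanced
designs the partitions are mutually orthogonal so their sums of squares
add. Contributions (`effect_contributions()`) are the partition sums of
squares as fractions of their total; for pure noise they converge to the
degrees-of-freedom ratio, which the tests verify against a Monte-Carlo
oracle. Unbalanced designs fall back to cell-mean estimates and the
orthogonality assertion is only made when balanced. `effect_pca()` adds the
chosen factor's effect matrix back to the residual, column-centres, and
decomposes by SVD; scores carry the level labels so score plots can be
coloured by condition or day, and `score_silhouette()` quantifies level
separation along the leading components using `cluster::silhouette`.

## Instrument comparison

`align_axes()` interpolates two collections onto the overlap of their axes
at the coarser nominal resolution (band areas are preserved within 1 %,
checked against a trapezoid oracle). `pick_peaks()` takes band maxima as
local minima of the SG second derivative exceeding a relative prominence
threshold (default 5 % of the deepest minimum in the region — the choice of
"most prominent" is a package convention, configurable). `match_peaks()`
performs greedy one-to-one nearest matching within a window of 20 cm⁻¹
(larger than the instruments' resolution, smaller than inter-band spacing),
ties broken deterministically by lower wavenumber; shifts are reported as
ATR − HTS. `band_ratios()` evaluates absorbance at the detected
counterparts of nominal band pairs, flagging (not dropping) spectra where a
counterpart is missing.

## FPA hyperspectral pipeline

The working range is 3200–1000 cm⁻¹ (above 3200 water dominates, below
1000 the detector is noise-limited). Outliers are flagged per spectral map
at 3 scaled MADs (MAD × 1.4826, the consistency constant under normality)
from the map median, with a standard-deviation fallback when the MAD is
degenerate; pixels flagged in more than half the bands are global (dead or
hot) pixels. Flagged values are replaced by the mean of their non-flagged
8-neighbours (8-connectivity maximises clean-neighbour availability at FPA
pixel pitch), iterating so clusters repair from the outside in.

Segmentation builds per-pixel features from the seven marker bands 3010,
2955, 2925, 2855, 1742, 1708 and 1650 cm⁻¹ (nearest axis band within
±4 cm⁻¹, the FPA resolution), standardises each band, keeps principal
components reaching 99 % cumulative variance, and clusters with k-means
(k = 2). `stats::kmeans` does not provide k-means++ seeding, so the seeding
is implemented in-package (deterministic given the seed) with 10 restarts,
best inertia kept; the foreground is the cluster with the higher mean
amide-I (1650 cm⁻¹) absorbance. Standardisation makes the segmentation
invariant to per-band affine intensity rescaling, which is asserted on
synthetic cubes.

`descatter()` is a scatter-correction stage with a deliberately frozen
interface (cube + mask in, cube out): foreground spectra are EMSC-corrected
against the foreground mean with a quadratic baseline and SG-smoothed;
background pixels pass through bitwise. A model-based correction can
replace the internals without touching the pipeline. Ratio maps divide
band images on the foreground only, with a denominator floor of 1e-3
absorbance — pixels below it are masked and counted, never divided.

## AFM-IR pipeline

Topography levelling fits a least-squares polynomial surface (default
order 1, a plane) made robust to raised features by iteratively refitting
on the lower-residual half of the pixels, then subtracts each scan line's
median height (scan lines are rows). Absorption maps are not line-levelled
by default; they receive only dropout repair and power normalisation
(configurable).

Contact-loss dropouts occupy single scan lines, so detection screens each
pixel against the running median of its *column* (window 5): a pixel more
than 3 scaled MADs below that reference, which has lost over half the local
signal level and whose two vertical neighbours sit at the column level, is
a dropout. The one-sided rule can never flag genuinely bright droplet
pixels, and the vertical-neighbour condition distinguishes line artifacts
from genuine two-dimensional structure boundaries. The paper trail for this
stage specifies only the replacement (neighbour means); the detection rule
is a package convention.

Drift registration estimates a rigid transform (translation + rotation)
mapping the fixed 1600 cm⁻¹ topography onto each moving wavenumber's
topography. For each candidate rotation on a ±10° grid at 0.25°, the moving
image is unrotated, the sub-pixel translation estimated by zero-padded FFT
cross-correlation with parabolic peak refinement, and the candidate scored
by its mean squared mismatch after full alignment — scored *symmetrically*,
with half the transform applied to each image, so both sides suffer the
same single resampling. Without this symmetry the once-interpolated side is
smoother than the untouched side and the mismatch optimum migrates away
from the true transform on content that is nearly invariant under small
shift-rotation combinations (an elongated hypha is exactly such content).
A Nelder-Mead polish refines all three parameters jointly; estimates below
the interpolation accuracy floor (0.05 px / 0.05°) are treated as identity
so that already-registered maps pass through bitwise. Bilinear resampling
is used throughout; out-of-frame pixels are masked and excluded from
statistics.

Topography is then converted to micrometres, shifted so its minimum is
zero, and values below the 5th percentile (linear-interpolation percentile
convention) are raised to it; absorption maps are divided by the source
(background) power interpolated at their wavenumber, making maps at
different wavenumbers comparable. Segmentation uses the fixed wavenumber's
topography and deflection plus every normalised absorption map,
standardised, k-means k = 2, hypha = higher mean topography. Log-ratio maps
take log10 of 1742:1600 and 1708:1600 absorption ratios and of
absorption/topography at each wavenumber, foreground only; non-positive
numerators or denominators are masked and counted, never clipped, to avoid
fabricating extreme ratios. Samples flagged as over-thick (> 2–3 µm, e.g.
yeast-like cells) are refused by the correction chain: the tip loses
contact on such surfaces and no reliable maps exist to correct.

Point spectra from one acquisition point (typically 4–5 repeats over the
1800–1510 cm⁻¹ QCL range at 1 cm⁻¹) are averaged, SG-smoothed (window 15,
order 1) and optionally EMSC-corrected against a caller-supplied reference;
a second-derivative variant resolves the TAG ester band at 1742 cm⁻¹, the
FFA dimer band at 1708 cm⁻¹ and mono/diglyceride shoulders near 1735 cm⁻¹.

## The forward simulator

All synthetic data are Beer-Lambert style sums of Gaussian (optionally
Lorentzian) bands from a band library whose centres follow standard
assignments for fungal biomass (TAG ester carbonyl 1742, FFA dimer 1708,
ionized-FFA COO⁻ 1600, amide I/II 1650/1545, polyphosphate P=O 1265,
polysaccharide C-O-C 1025, acyl C-H stretches 2955/2925/2855, unsaturation
3010, C-H bends 1465/1415/1375 cm⁻¹). Widths (9–25 cm⁻¹ by band class,
narrow for carbonyls, broad for water) and relative amplitudes are
order-of-magnitude modelling choices of this package, not measured values.
Acyl-chain and unsaturation band amounts scale with the TAG + FFA content
(unsaturation index 0.3), so lipid-rich compositions light up the full C-H
region as real biomass does.

**ATR mode** weights every band by d_p(centre)/d_p(1742), where
d_p = λ/(2π n₁ √(sin²θ − (n₂/n₁)²)) is the evanescent-wave penetration
depth (diamond n₁ = 2.40, sample n₂ = 1.50, θ = 45°), and displaces band
centres toward lower wavenumber by δ(ν̃) = δ₀ (ν̃₀/ν̃)^γ with defaults
δ₀ = 7 cm⁻¹ at ν̃₀ = 1375 and γ = 2, giving under 2 cm⁻¹ of shift at
2925 cm⁻¹ and about 7 cm⁻¹ at 1375 cm⁻¹. The inverse-square exponent is a
phenomenological stand-in for refractive-index dispersion; a first-power
law cannot simultaneously produce negligible shifts in the C-H stretch
region and multi-cm⁻¹ shifts in the bending region, which is the observed
pattern.

**Campaigns** reproduce the phosphate design: six conditions (Pi4 … Pi0,
grams per litre of phosphate salts), three technical replicates, and for
ATR a seven-day storage series — 18 transmission and 126 ATR spectra. The
condition effect scales TAG content (±40 % across conditions at unit
amplitude) and ties polyphosphate content to the phosphate level; the day
effect (default one fifth of the condition amplitude) drifts the water and
lipid bands. Axes default to 2–3 cm⁻¹ point spacing — half the nominal
4/6 cm⁻¹ optical resolutions, as spectrometers digitise with twofold
zero-filling. Replicate noise is i.i.d. Gaussian (sd 0.002 absorbance,
a realistic bench-top noise floor).

**FPA scenes** are 128 × 128 pixels at 0.7 µm/pixel (the pixel count that
matches 16,384 spectra per area; three areas give 49,152 pixel spectra)
over 900–3900 cm⁻¹ at 8 cm⁻¹. Cell forms use geometry presets — thin
capsules (flat hyphae), wide capsules (swollen) or disk fields (yeast) —
with TAG-enriched droplet disks and lipid-to-protein scalars that enforce
the biological ordering flat < swollen < yeast. Each pixel gets a smooth
random quadratic scatter baseline (sd 0.02, emulating the Mie-type
baseline variation that motivates descattering), additive noise (default
sd 0.02, i.e. signal-to-noise ≈ 20 at the strong bands) and planted hot
pixels whose amplitude is ten scaled MADs of their band.

**AFM-IR scenes** build a vertical hypha with a meandering centreline,
longitudinal height modulation and a cell-wall step at the edge (real
hyphae present steep walls and are not straight uniform cylinders; the
modulation also makes the drift observable along the scan direction),
droplet height bumps placed at the hypha edge for flat forms and centrally
for swollen forms, cytoplasmic baseline lipids plus droplet-concentrated
TAG/FFA with configurable TAG:FFA ratios, and a COO⁻/cell-wall component
absorbing at 1600 cm⁻¹. Absorption maps are species absorptivities
(evaluated from the band library) times local amounts times an optical
thickness factor times the laser power at that wavenumber. The artifact
chain applies per-wavenumber rigid drift, a tilt plane, per-scan-line
height offsets, noise, and zeroed 5-pixel contact-loss segments. Droplet
Gaussians are truncated at 3σ so the substrate is exactly zero — which is
what makes "the correction chain is the identity on an artifact-free
scene" a well-posed, exactly-testable property.

**What the simulator does not emulate:** resonant Mie scattering and its
derivative-shaped band distortions, water-vapour lines, detector
nonlinearity, mosaic stitching seams, cantilever dynamics and resonance
tracking, and sample damage. Passing recovery tests on these scenes shows
the algorithms are correctly implemented and statistically calibrated
under the stated noise models; it does not certify performance on real
instrument data with artifacts outside these models.

## Numerical choices and problem sizes

Ties and degeneracies: axis order is ascending everywhere internally
(instrument-style descending files are normalised on read); k-means uses a
fixed seed (default 0) with 10 restarts; zero-MAD maps fall back to the
standard deviation with a warning; flagged pixels with no clean neighbour
repair iteratively and error out after 10 passes with a pixel listing;
degenerate EMSC fits are flagged, not divided. Storage is float32 on disk
(instrument-realistic), float64 in memory.

The test suite runs the full bulk campaign (126 spectra × ~1800 channels),
128 × 128 × 376 FPA cubes and 64 × 64 AFM-IR scenes; the drift-recovery
property is asserted over eight seeded scenes in the unit tests and twenty
in the acceptance checks. These sizes keep the whole suite in the
low minutes on a single core while matching the designed campaign sizes
exactly where a count is the property under test.
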