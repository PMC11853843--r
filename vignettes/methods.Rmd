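---
title: "Phantom simulation, CEM detection and FCLS unmixing: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom simulation, CEM detection and FCLS unmixing: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsiphantom)
```

This vignette explains the models behind `hsiphantom`, the parameters
that matter, and the choices made where the design was genuinely open.
It reports no numbers that the test suite and `scripts/acceptance.R` do
not themselves compute.

## The measurement chain being emulated

A SWIR hyperspectral camera images a tissue-mimicking phantom: agar
"collagen" slabs, lard (lipid) inclusions at known depths, concentration
panels, and a sloped lard wedge. Each pixel carries a 900–1700 nm
reflectance spectrum. Two analyses are validated against the phantom's
known geometry:

1. **Detection** — find the lard through the collagen with a constrained
   energy minimization (CEM) matched filter, binarize the resulting
   abundance map with Otsu's method, and score the mask against ground
   truth with the Tanimoto index.
2. **Unmixing** — treat each pixel as a linear mixture `r = Mα + n` of
   endmember spectra and estimate abundances `α` with fully constrained
   least squares (FCLS), comparing them with the known concentrations or
   depths.

Real camera cubes of this kind are rarely shareable, so the package pairs
the estimators with a simulator whose scenes have exact ground truth;
every accuracy claim in the tests is made against that truth.

## Optical forward model

**Endmember spectra.** Reflectance is modelled as the exponential of a
smooth absorbance: a flat baseline plus one Gaussian per absorption peak,
`R(λ) = exp(−b − Σᵢ dᵢ exp(−(λ−cᵢ)²/2σᵢ²))`. Peak centers follow the SWIR
overtone assignments (water 970/1180/1430 nm; lipid 920/1210/1730/1760 nm;
collagen 1200/1500/1725 nm); peaks above the 1700 nm grid top are dropped
with a message. Peak depths (0.4–1.2 absorbance units), widths (30 nm
standard deviation) and baselines (0.25–0.40) are declared defaults chosen
to give visibly structured, strictly positive spectra with reflectance in
(0, 1]; they are configurable in `build_endmember()` and are **not** fits
to any instrument. This matters for interpretation: absolute detection
depths in simulation depend on these magnitudes, so only *relative*
statements (deeper is harder, more concentrated is more abundant) transfer
to real data.

**Attenuation.** A target under `z` mm of collagen contributes the
fraction `f(z) = exp(−2 μ_eff z)` of its spectrum to the observed pixel,
the remainder being collagen. The factor 2 models the two-way
illumination-and-return path of reflectance geometry; it is a standard
diffuse-reflectance heuristic, not a radiative-transfer solution, and
`μ_eff` simply rescales depth. The default `μ_eff = 0.04 /mm` makes the
studied depth range 7–68 mm span strong (`f ≈ 0.57`) to faint
(`f ≈ 0.004`) targets, which is the regime of interest for a detector
benchmark.

**Mixing.** Mixed pixels are convex combinations of endmember spectra in
reflectance space (`linear_reflectance` mode). This makes the simulator
and the FCLS estimator share the same linearity assumption, which is
deliberate: the unmixing experiments test estimator correctness, not
model adequacy. A `beer_lambert` mode (absorbance scales with
concentration, so reflectance is exponentiated) is provided for the
concentration scaling law, and is how the distinct 2% and 5% collagen
spectra are generated before they are linearly mixed.

**Noise.** I.i.d. Gaussian per band with `σ = 0.005` reflectance units
by default (`σ = 0.002` in the concentration scenes), clipped at zero so
reflectance stays non-negative. No camera noise statistics were available
to emulate; the chosen levels are a few percent of typical signal,
comparable to a well-exposed InGaAs sensor after flat-field correction.
The clipping introduces a slight positive bias only where the signal is
within ~2σ of zero.

**What the simulator omits.** Scattering and its depth-dependent blur,
spectral crosstalk between adjacent phantoms, illumination
non-uniformity, specular highlights, and boundary partial-volume mixing
beyond the geometric block edge. Consequently, passing tests demonstrate
that the estimators are correct under the linear model and robust to
band-wise noise — not that they would achieve the same scores on camera
data.

## Scene geometries and defaults

| Scene | Defaults | Ground truth |
|---|---|---|
| `slab_series` | thicknesses 10–80 mm over a 0.9/0.3 albedo grid | attenuation law itself |
| `embedded_target` | 120×120 px, 40×40 px block, depth 20 mm | block mask + true `f` |
| `concentration_panels` | 2/3/4/5%, equal-width vertical panels | per-pixel abundance pair |
| `sloped_wedge` | 80 columns, 28.25°, max depth 40 mm | per-column depth and `f` |

The wedge's pixel pitch is derived from the slope and maximum depth so
that the columns span 0–40 mm exactly; the leftmost column is pure lard.
Scene rasters are kept at desk scale (≤ 120×120×161) so the full suite
runs in well under a minute per experiment; all sizes are scene
parameters, and results quoted anywhere in the package state the size
used. The target block is axis-aligned with no partial-boundary pixels,
so noiseless detection recovers the mask exactly; the depth experiment
additionally reports a Tanimoto index excluding a one-pixel boundary
ring, since on real phantoms disagreement concentrates at the
lard–collagen boundary.

Determinism is part of the scene contract: identical scene + seed gives
bit-identical cubes and truth; a different seed changes only the noise.

## Numerical choices

**CEM.** `R` is accumulated over *all* pixels, target included — the
global-statistics convention. A ridge `ε = 10⁻⁶ · trace(R)/L` is added
before the symmetric solve: simulated scenes contain a handful of
distinct spectra, so the raw `R` is numerically singular, and the
trace-scaled ridge regularizes without materially moving `w` (the
unit-response constraint `dᵀw = 1` is exact by construction regardless).
The solve is a linear solve, never an explicit inverse. The applied `ε`
is recorded on the fit.

**Otsu.** 256 equal-width bins on min–max-normalized values; candidate
thresholds are the interior bin edges; between-class variance
`w₀w₁(μ₀−μ₁)²` is maximized with ties broken toward the lower edge; the
mask is `value > threshold`. Tie-breaking matters: for a cleanly bimodal
map every threshold in the inter-mode gap is optimal, and this rule picks
the gap's lower edge deterministically. A constant map has no threshold
and is an error, not a silent answer.

**SCLS.** The printed closed form in the unmixing literature for the
sum-to-one correction is implemented as
`α = α_LS + (MᵀM)⁻¹1 · (1ᵀ(MᵀM)⁻¹1)⁻¹ · (1 − 1ᵀα_LS)` via Cholesky
factorization of `MᵀM`; the tests verify it against a KKT-system solve of
the equality-constrained problem.

**FCLS.** Active-set in the Heinz–Chang style: start from SCLS, clamp the
single most negative coordinate to zero, re-solve on the surviving
support, repeat. Support only shrinks (no re-entry), so termination in at
most `p − 1` steps is guaranteed; `tol = 10⁻⁹`, `max_iter = 10p`. For the
`p ∈ {2, 3}` problems the experiments use, this matches an exhaustive
simplex grid search (step 10⁻³) on every tested instance; re-entry can
matter only for larger, more collinear endmember sets, which is a
documented limitation. Final magnitudes below `tol` are clamped to zero
and the vector renormalized, so outputs satisfy the simplex constraints
to 10⁻⁹ exactly as promised. Cube-level unmixing vectorizes the SCLS pass
and re-solves only offending pixels. Endmember matrices must have full
column rank; condition numbers above 10¹⁰ trigger a warning.

**ENVI I/O.** The minimal interoperable dialect: float32 little-endian,
text header with `samples/lines/bands/interleave/data type/byte
order/wavelength`, BSQ/BIL/BIP interleaves. Values are float32 on disk,
so round trips are bit-exact precisely for float32-representable data.
Pixel order convention is row-major `(row, col, band)` everywhere,
including the flattening used by the autocorrelation matrix.

**Band count.** The default grid is 900–1700 nm at 5 nm (161 bands).
Sensor documentation in this range often quotes both a 5 nm optical
resolution and a several-hundred detector-band count; the two are not
reconcilable on one grid, so the band count is a plain parameter and
nothing assumes 161.

## Experiment definitions

- **Depth experiment**: one scene per depth (seeds offset per depth so
  scenes are independent), CEM with the simulator's pure lipid spectrum
  as the signature, Otsu binarization, Tanimoto index vs. the block mask.
  The target signature in a real pipeline would come from a reference
  region or library spectrum; both are supported
  (`select_endmembers_from_image()` / two-column text files in the CLI).
- **Concentration experiment**: endmembers are the mean spectra of the
  extreme (2% and 5%) panels, accuracy is the squared Pearson correlation
  between panel-mean FCLS abundance of the high-concentration endmember
  and true concentration — a linear-correlation analysis on the 4 panel
  means, not a per-pixel correlation.
- **Slope experiment**: endmembers are the shallowest and deepest column
  means. Spearman's ρ at each marker depth (1–4 cm) is computed
  *cumulatively* over all columns from the surface to that marker. A
  per-row-only Spearman would be equally defensible; the cumulative
  reading is the documented choice because it is well-defined for any
  marker spacing and reduces to the same value when fractions are
  strictly monotone.
- **Penetration experiment**: mean reflectance at the band nearest
  1073 nm per slab thickness — 1073 nm sits in a window where water
  absorbs weakly and collagen contrast is good — plus NIR-II pseudocolor
  composites at 1091/1211/1318 nm.

## Known limitations

- The linear mixing assumption is shared between simulator and estimator;
  agreement does not validate the linear model against real tissue.
- Active-set support shrinking without re-entry is exact only empirically
  for the small endmember counts used here.
- Otsu binarization assumes a bimodal abundance map; scenes where the
  target occupies either almost none or almost all of the image can
  produce degenerate thresholds.
- The simulator's optical magnitudes are declared defaults; depth scales
  quoted anywhere in the package are meaningful only relative to
  `μ_eff`.
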