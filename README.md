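# hsiphantom

Subpixel target detection and linear spectral unmixing for short-wave
infrared (SWIR, 900–1700 nm) hyperspectral images of tissue-mimicking
phantoms, with a seeded synthetic phantom generator that provides exact
ground truth.

In the SWIR range water, lipid and collagen have distinct absorption
overtones (water at 970/1180/1430 nm, lipid at 920/1210 nm within the
sensed range, collagen at 1200/1500 nm), so a reflectance spectrum carries
enough information to find a lipid target buried under tens of millimetres
of collagen or to estimate how much of each component a mixed pixel
contains. The package is aimed at researchers validating SWIR imaging
pipelines: it reproduces the full measurement chain — phantom, cube,
detector, unmixer, accuracy metric — entirely in software, so every stage
can be tested against known truth.

Two estimators form the core:

- **Constrained energy minimization (CEM).** Given the per-image
  autocorrelation matrix `R = (1/N) Σᵢ rᵢ rᵢᵀ` over all pixel spectra and a
  target signature `d`, CEM minimizes the mean filter output energy
  `wᵀRw` subject to a unit target response `dᵀw = 1`, giving
  `w = R⁻¹d / (dᵀR⁻¹d)`. Applying `w` to each pixel yields an abundance
  map that is binarized with Otsu's method and scored against ground truth
  with the Tanimoto (Jaccard) index `TI = |X∩Y| / |X∪Y|`.
- **Fully constrained least squares (FCLS).** Under the linear mixing
  model `r = Mα + n` with endmember matrix `M = [m₁ … m_p]`, FCLS
  minimizes `‖r − Mα‖²` subject to `Σⱼ αⱼ = 1` and `α ≥ 0`, via an
  active-set iteration starting from the closed-form sum-to-one solution.
  Unconstrained LS and sum-to-one-only (SCLS) solvers are also exposed.

The simulator generates the four phantom geometries used for validation —
slab thickness series, lard block embedded at depth, collagen
concentration panels (2–5%), and a sloped lard wedge (28.25°, down to
40 mm) — under a two-way Beer–Lambert attenuation model
`f(z) = exp(−2 μ_eff z)` with per-band Gaussian noise. Cubes read and
write an ENVI-compatible raster format (float32 + text header, BSQ/BIL/BIP).

## Worked example

```r
library(hsiphantom)

# lard block under 20 mm of collagen, default optics and noise
scene <- phantom_scene("embedded_target", depth_mm = 20, seed = 7)
sim   <- simulate_embedded_target(scene)

fit <- cem(sim$cube, sim$endmembers$lipid)
fit
#> <cem> matched filter, 161 bands, ridge = 4.28e-07
#>   d'w = 1.000000000000 (unit target-response constraint)

ot <- otsu_threshold(predict(fit, sim$cube))
tanimoto_index(ot$mask, sim$truth$mask)
#> [1] 1
```

The filter honours the unit-response constraint exactly, and at 20 mm
(mixing fraction `f = exp(−2·0.04·20) ≈ 0.20`) the binarized detection
coincides with the ground-truth block, so the Tanimoto index is 1.

```r
run_concentration_experiment(seed = 11)
#> Collagen concentration unmixing experiment
#>   endmembers: mean spectra of the 2% and 5% panels
#>   concentration mean_alpha1 mean_alpha2
#> 1             2      0.9997      0.0003
#> 2             3      0.6667      0.3333
#> 3             4      0.3333      0.6667
#> 4             5      0.0003      0.9997
#>   R^2 (panel-mean abundance vs concentration) = 1.0000
```

Panel-mean FCLS abundances land on the true mixing ladder (1, 2/3, 1/3, 0)
to four decimals despite per-band noise, and the abundance of the
high-concentration endmember correlates linearly with concentration.

```r
run_slope_experiment(seed = 5)
#> Sloped-wedge unmixing experiment
#>   depth_cm  frac1  frac2 rho1 rho2
#> 1        1 0.4395 0.5605   -1    1
#> 2        2 0.1714 0.8286   -1    1
#> 3        3 0.0523 0.9477   -1    1
#> 4        4 0.0010 0.9990   -1    1
```

On the wedge, the shallow (lard-like) endmember fraction decays with depth
while the deep endmember rises, with Spearman correlations of ±1 at every
marker depth.

A command-line wrapper (`inst/scripts/hsiphantom`) exposes `simulate`,
`detect`, `unmix` and `experiment` subcommands over the same functions;
see `?hsi_main`.

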