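# mcxray

Quantitative X-ray microanalysis of breast-tissue microcalcifications.

Micrometre-scale calcium phosphate deposits (microcalcifications, MC) in
breast biopsies carry diagnostic information: benign deposits tend to contain
a rim of Mg-bearing whitlockite (WHIT) and low-crystallinity hydroxyapatite
(HAP), while deposits in carcinoma tissue are dominated by highly crystalline
apatite. `mcxray` implements the three scanning X-ray analyses used to
establish this picture, for researchers working with raster-scanned spectral
data of mineralized tissue:

1. **XRF quantification with a per-pixel thickness constraint.** The
   transmitted beam gives the effective matrix thickness by Beer–Lambert
   inversion, *t*<sub>eff</sub> = −ln(*I*/*I*₀) · δ(matrix, *E*), with
   δ = 1/(ρ·μ/ρ) the 1/e attenuation length. Each pixel's fluorescence
   spectrum is then fitted with that thickness entering the self-absorption
   factor *A*(*t*) = (1 − e^(−χρt))/(χρt),
   χ = (μ/ρ)(*E*<sub>in</sub>)/sin α + (μ/ρ)(*E*<sub>line</sub>)/sin β.
   Mass fractions are matrix-referenced: the heaviest excited matrix element
   (Ca at 4.2 keV, P at 2.5 keV, O at 2.1 keV) is fixed to its theoretical
   fraction and every other element is quantified relative to it,
   *w*<sub>Z</sub> = (*A*<sub>Z</sub>/*S*<sub>Z</sub>)/(*A*<sub>ref</sub>/*S*<sub>ref</sub>) · *w*<sub>ref</sub>.
   Spectra can be grouped into effective-thickness bins, and the linear trend
   of *w*<sub>P</sub> with thickness is inverted through the carbonate
   dilution model *x*<sub>P,eff</sub> = (1 − α)·*x*<sub>P,HAP</sub>.
2. **Ca K-edge XANES linear-combination fitting.** Spectra are edge-step
   normalized, and fitted as non-negative combinations of reference spectra
   (HAP, A/B-type carbonated apatite, WHIT, calcite, amorphous calcium
   carbonate). Species are grouped into tot HAP, the whitlockite share
   WHIT/(WHIT + tot HAP), and a carbonate fraction.
3. **WAXS profile classification and refinement.** Azimuthally integrated
   1D profiles are classified by a greedy least-correlated-representative
   method; whole-pattern refinement with pseudo-Voigt peaks at the
   reflection positions (hexagonal setting, 1/d² = (4/3)(h²+hk+k²)/a² + l²/c²)
   refines the cell (a, c) and anisotropic Scherrer domain sizes along
   [00l] and [hk0] (FWHM in q of a size-broadened peak is 2πK/D).

Because no raw scan data are publicly deposited, the package ships a
first-class synthetic phantom generator that renders co-registered
transmission maps, XRF spectrum cubes at 2.1/2.5/4.2 keV, XANES point
spectra and WAXS profiles from one ground-truth scene, emulating the benign,
DCIS (ductal carcinoma in situ) and IDC (invasive ductal carcinoma) deposit
morphologies.

## Worked example

```r
library(mcxray)
scene  <- build_scene("benign", seed = 42, nx = 24, ny = 24)
report <- run_all(scene, seed = 42)
print(report)
#> <mc_report> benign preset, seed 42
#>   Mg bin slope: -0.00396 /um -> rim_Mg_enhanced = TRUE
#>   WHIT share rim 0.629 vs core 0.095 -> whit_rim_lcf = TRUE
#>   whit_rim_waxs = TRUE; whit_rim = TRUE
```

The negative slope of the binned Mg mass fraction against effective
thickness says Mg is enriched where the deposit is thin (the rim); the XANES
line scan puts the whitlockite share at 0.63 in the rim versus 0.10 in the
core; and the WAXS classification finds a whitlockite-like component
concentrated in the rim ring. All three modalities agree — the benign
signature. The binned table behind the first flag:

```r
round(as.data.frame(report$stages$bins[["2.5"]])[, c("t_mean", "n_pixels", "w_Mg")], 4)
#>   t_mean n_pixels   w_Mg
#> 1 0.7851      100 0.0173
#> 2 1.2944       31 0.0315
#> 3 1.6761       13 0.0339
#> 4 2.9163        8 0.0125
#> 5 3.4807       55 0.0153
#> 6 4.4038       45 0.0144
```

The thin bins (1.3–1.7 µm, the rim) carry Mg fractions near the theoretical
whitlockite value of 0.023–0.03, while the thick core sits near 0.013. Run
the same two lines with `"idc"` to see every flag turn `FALSE`.

Individual stages are plain functions: `effective_thickness_map()`,
`fit_spectrum()`/`fit_cube()`, `bin_by_thickness()`,
`carbonate_dilution_model()`, `normalize_xanes()`, `lcf_fit()`,
`classify_profiles()`, `refine_profile()`, `collagen_d_spacing()`. A thin
command-line wrapper lives at `inst/cli/mcxray.R`.

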