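---
title: "Methods: thickness-constrained XRF, XANES LCF and WAXS refinement"
author: "mcxray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thickness-constrained XRF, XANES LCF and WAXS refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcxray)
```

# The problem

Microcalcifications in breast tissue are micrometre-scale mineral deposits
whose mineralogy correlates with malignancy: benign deposits carry a rim of
Mg-bearing whitlockite and amorphous calcium phases around a low-crystallinity
apatite core, while deposits in carcinoma tissue are dominated by highly
crystalline apatite with less Mg. `mcxray` implements the three X-ray
modalities that jointly establish this signature — thickness-constrained XRF
elemental mapping, Ca K-edge XANES linear-combination fitting (LCF), and WAXS
classification/refinement — together with a synthetic phantom generator that
stands in for the (undeposited) raw scans.

# Physics tables

All quantification rests on a pinned tabulation of elemental mass attenuation
coefficients (`inst/extdata/mass_attenuation.csv`; H, C, N, O, Na, Mg, Si, P,
S, Cl, Ca, Sr, Y on 0.5–15 keV grids). Values are transcribed from standard
photoabsorption tabulations; absorption edges are represented as pairs of
closely spaced grid points so that log-log interpolation between grid points
is smooth, monotone and never crosses an edge. Matrix coefficients follow the
mass-weighted mixture rule. The shipped values are believed accurate to
5–10% per element; this is the dominant systematic on any absolute
attenuation length the package reports. With this tabulation, stoichiometric
hydroxyapatite (ρ = 3.16 g cm⁻³) has 1/e lengths of ≈5.0, 4.6 and 5.4 µm at
the three excitation energies (2.1, 2.5, 4.2 keV), ≈1.26 µm at the Mg Kα
energy and ≈13 µm at the Ca Kα energy. The latter two are shorter than the
1.5 µm and 18 µm sometimes quoted for the same system; we could not find a
density/composition convention under which a normal-incidence 1/e length of
18 µm at 3.69 keV is reachable (the P K-shell contribution alone forbids it),
and we report the values our tabulation actually implies.

Printed reference mass fractions (w_Ca = 0.39, w_P = 0.196 for the apatite
reference; 0.182/0.169 for A/B-type carbonated apatite; w_Mg = 0.023 for
whitlockite) take precedence over stoichiometric computation in all
quantification; `theoretical_mass_fraction()` reports both with a consistency
flag. Fits use full-precision tabulated line energies (e.g. Ca Kα 3.6917 keV);
the rounded display values are metadata only.

# XRF forward model and inversion

The forward model (`simulate_spectrum()`) is a classical
fundamental-parameter description: for every emission line whose edge lies
below the excitation energy, counts are proportional to

- the element's mass fraction,
- its photoabsorption at E_in times the K (or L3) shell fraction, taken from
  the tabulation's own edge jump, times the fluorescence yield and line
  fraction,
- the thickness self-absorption factor
  A(t) = (1 − exp(−χρt))/(χρt) with
  χ = (μ/ρ)(E_in)/sin α + (μ/ρ)(E_line)/sin β,

convolved with a Gaussian detector response. Defaults: incidence α = 84°,
exit β = 6° (the detector is treated as a point; the 6–10° opening is a
documented systematic to be explored by varying β), FWHM² = FWHM_noise² + kE
calibrated to 150 eV at 5.9 keV (Mn Kα convention) with an 80 eV noise floor,
escape peaks at E − 1.742 keV for lines above the Si K edge with a 1.5%
escape fraction. Escape modelling matters: dropping it biases P and S upward
at 4.2 keV because the Ca Kα escape line lands on the P Kα position — the
test suite asserts this bias direction.

The inversion (`fit_spectrum()`) estimates a SNIP-style low-clipped continuum
(configurable window, default 24 channels; set `bg_window = 0` to disable),
then solves non-negative least squares for one amplitude per element (all of
its lines with fixed relative intensities, escape peaks included) plus an
elastic peak and a flat continuum column. The flat column exists because a
min-filter background estimate sits on the lower envelope of Poisson noise;
letting NNLS absorb the remainder removes most of the resulting positive bias
on weak lines. Mass fractions are matrix-referenced with the reference
element fixed to its registry value; they are exact for the reference by
construction, and `fit ∘ simulate` is an identity to 1e-6 on noise-free
spectra — the module's master oracle. Remaining known bias: with correlated
weak lines (Na next to Mg) NNLS truncation at zero inflates a weak line by a
few percent at realistic counts; this is inherent to non-negative
deconvolution.

Per-pixel thickness always comes from the 2.5 keV transmission scan
(`effective_thickness_map()`), assuming a B-type carbonated apatite matrix;
mass fractions are reported only where t_eff ≥ 0.5 µm (maps carry 0.3/0.5/1.0
µm contours; masked pixels are NA, never zero). `bin_by_thickness()` averages
spectra within effective-thickness bins before fitting, which suppresses both
counting noise and geometry systematics — this is the analysis behind the
mass-fraction-versus-thickness curves, and the input to
`carbonate_dilution_model()`, which fits w_P linearly against t_eff and
inverts the fraction α of a Ca-containing, P-free diluent via
x_P,eff = (1 − α)·x_P,HAP.

The Sr/Y estimates from the 2.1 keV scan are rescaled to the 2.5 keV scale by
w(Z) ← w(Z, 2.1) · w(Mg, 2.5)/w(Mg, 2.1), which preserves ratios among the
rescaled elements and is masked where w(Mg, 2.1) ≤ 0.

# XANES

`normalize_xanes()` subtracts a linear pre-edge fit (default 4020–4035 eV)
and divides by the edge step, the post-edge linear fit (default 4075–4120 eV)
evaluated at the edge position (maximum derivative). The procedure is
idempotent and affine-invariant; optional flattening removes the post-edge
slope. `white_line_position()` refines the absorption maximum with a local
parabola, giving sub-grid accuracy.

No measured reference spectra are available, so `xanes_references()`
generates a parametric library (arctan edge + Gaussian white line + shoulder
+ damped post-edge cosine) encoding the qualitative contrasts that drive the
analysis: apatite white line at 4048.6 eV, whitlockite shifted to 4049.5 eV,
an apatite absorption enhancement near 4060 eV that whitlockite lacks, and a
broad featureless amorphous carbonate. Measured references in two-column text
files drop in via `read_xanes()`.

`lcf_fit()` solves non-negative least squares over 4035–4090 eV; the
sum-to-one constraint (default on, both modes supported) is imposed through a
soft equality row followed by exact renormalization — on noise-free simplex
mixtures the solution is exact anyway, which the tests sweep in 0.1 steps. A
cross-correlation energy shift against the best single reference is reported
as a diagnostic but never applied, and fluorescence-yield spectra are tagged
but not over-absorption corrected. The three apatite references are nearly
collinear (as measured ones are), so individual within-family weights carry
large variance while the grouped quantities — tot HAP, the whitlockite share
WHIT/(WHIT + tot HAP), carbonate — are stable; the noise study in the test
suite (200 replicates, 5% noise) asserts grouped bias < 0.03.

# WAXS

Reflection positions follow the hexagonal-setting spacing
1/d² = (4/3)(h² + hk + k²)/a² + l²/c², with the obverse rhombohedral
condition −h + k + l = 3n applied to whitlockite over all in-plane
symmetry equivalents. Working in momentum transfer simplifies Scherrer
bookkeeping: the FWHM in q of a size-broadened peak is exactly 2πK/D, with
K = 0.9 fixed (the round trip width→domain→width closes to 1e-10, so any
fixed K is self-consistent). Anisotropy uses a two-direction model
1/D(φ) = cos²φ/D_[00l] + sin²φ/D_[hk0].

`refine_profile()` replaces a full structure-factor Rietveld treatment with
free-intensity whole-pattern fitting: pseudo-Voigt peaks (fixed η = 0.5,
configurable) at the computed positions, intensities solved by non-negative
least squares at every step (variable projection), and Levenberg–Marquardt
over {a, c, D_[00l], D_[hk0]} per phase in log space. The background is
interpolated through anchor points and never refined; instrumental broadening
(a config scalar or curve, default 0.05 nm⁻¹) is added in quadrature during
synthesis and removed the same way during refinement. This is the minimum
machinery that reproduces the published quantities (cell parameters to
4 decimals and domains within 2% on noise-free profiles, from +1% perturbed
starts) and is documented as a simplification: no spherical-harmonics
broadening, no absolute phase fractions.

`classify_profiles()` is a documented greedy variant of least-correlated
signal classification, not a clone of the published algorithm: profiles are
boxcar-smoothed (default window 4) and restricted to q = 5.75–34.4 nm⁻¹; the
first representative maximizes intensity variance, each further one minimizes
its maximum correlation with those selected, and pixels are assigned to the
representative they correlate best with. Two guards make this robust on
counting noise: representative candidates need a smoothed variance of at
least 2% of the maximum (pure-noise profiles are otherwise the "least
correlated" of all), and the lowest-intensity profile is always included so
that, after relabelling by integrated intensity, component 0 is the
background family. The smoothing window matters for sparse narrow-peak
families: the tests demonstrate that a 10-point window makes a
whitlockite-containing family measurably more correlated with plain apatite
than the 4-point default does.

`collagen_d_spacing()` fits detected SAXS orders to q_n = 2πn/D by weighted
regression through the origin, tolerant of missing orders.
`azimuthal_integrate()` converts detector frames with q = (4π/λ)sin θ,
2θ = atan(r/L), in 16 azimuthal segments.

# The phantom and what it does (not) show

`build_scene()` produces a 64×64 (default; tests and examples use 12–24
pixel grids to stay light) elliptical deposit with four regions: background
(3 µm embedding paraffin only), a 0.5–1 µm periphery, a 3–5 µm core, and a
rim ring at 1–1.8 µm, with 4% log-normal thickness texture. Presets pin the
region mineralogy: the benign scene has a low-crystallinity apatite core
(96/53 Å domains) and a rim with 35% whitlockite, Mg up to 0.021 and a 25–30%
amorphous-carbonate XANES share; DCIS has high-crystallinity apatite
(244/129 Å) and patchy Mg peaking at 0.03; IDC has the lowest Mg (~0.007),
elevated Na, and no whitlockite anywhere. Traces sit in realistic ranges
(Na 0.005–0.02, S 0.001–0.01, Cl 0.002–0.004, Y above Sr). The thin-region
Mg enrichment is deliberately benign-only, mirroring the contrast the
pipeline is meant to detect. Mixed-matrix pixels are rendered as intimate
mixtures (one effective μ per pixel), not as stratified layers.

Renderers add Poisson counting noise (XRF, WAXS) or Gaussian noise (XANES,
transmission), all deterministic under a fixed seed. The default XRF count
scale (`flux_time = 2e6`, about 6×10⁴ detected counts per spectrum) makes
per-pixel trace quantification noisy — as in practice — while binned fits are
stable; recovery tests that probe per-pixel trace accuracy use 1e8 (a few
10⁶ counts per spectrum, a high-rate detector at 6 s dwell), since the true
exposure of such experiments is a free parameter of the generator.

Passing the phantom suite shows the pipeline is internally consistent — each
inversion recovers what the forward model generated, and the three modalities
agree on the rim of the benign scene (Mg bin-slope sign, LCF whitlockite
share rim > core, whitlockite WAXS component confined to the rim). It does
not validate detector physics beyond the model used (no Compton continuum,
no pile-up, no secondary fluorescence), nor the parametric XANES shapes
against measured standards, nor real tissue morphology.

# Numerical choices and degenerate inputs

- Transmission I > I₀ is clipped to t = 0 and counted; I ≤ 0 flags the pixel
  invalid (NA). Quantification below 0.5 µm effective thickness is masked
  because the matrix assumption loses meaning outside the deposit.
- A reference-element amplitude ≤ 0 flags the pixel unquantifiable; a design
  condition number above 1e8 flags degeneracy. Per-pixel failures never abort
  a cube fit.
- The pipeline's rim-enhancement flag requires the binned Mg trend to lose at
  least 20% of its mean level across the thickness range, so a noise-level
  slope does not count as enhancement.
- `run_all()` derives stage seeds from the master seed; reruns are
  byte-identical, and every decided default (matrix, angles, K, escape
  fraction) is recoverable from the objects it returns.
- Empty thickness bins are dropped and reported; a single-pixel bin equals
  the per-pixel fit exactly.

# Limitations

- Absolute XRF accuracy inherits the 5–10% uncertainty of the hand-pinned
  attenuation tabulation and the point-detector geometry; matrix-referenced
  ratios and all trend statements are far less sensitive.
- LCF weights within the apatite family are not individually trustworthy;
  use the grouped quantities.
- The WAXS classifier is a variant; with very low signal-to-noise it can
  still split noise families if the variance floor is relaxed.
- HDF5/TIFF interchange is replaced by plain-text bundles (`write_cube()`,
  two-column profiles, CSV maps), keeping the package dependency-light.
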