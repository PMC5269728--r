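---
title: "Methods: MSP spectra, lambda-max estimation and population comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSP spectra, lambda-max estimation and population comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspfit)
```

This vignette records the models behind `mspfit`, the assumptions they
make, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices a
maintainer would want explained. It states no empirical result that the
test suite does not itself compute.

## 1. The pigment template and its inversion

Every λ_max estimator in the package inverts the vitamin-A1 absorbance
template of Govardovskii et al. (2000): an α band

$$S_\alpha(\lambda) = \frac{1}{e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D},
\qquad x = \lambda_{max}/\lambda,$$

with $a$ itself a slowly varying function of λ_max, plus a Gaussian β
band whose position (189 + 0.315 λ_max) and width (−40.5 + 0.195 λ_max)
scale with λ_max. The constants live in one table
(`govardovskii_constants()`, exported as delimited text via
`write_template_constants()` and shipped under `inst/extdata/`), not
scattered through code. The curve is renormalised so its maximum is 1;
peak heights on a fine grid are cached per session behind a spline
interpolator so renormalisation costs nothing in the hot path.

Assumptions worth stating:

- **A1 chromophore only.** Parrots, like most diurnal birds, use
  vitamin-A1 pigments; A2/porphyropsin templates are out of scope.
- **β band included by default.** The original description of the
  figure-level template use does not say whether the β band was included;
  `beta = TRUE` is the default everywhere, with a flag to drop it. For
  the long-limb estimators the choice is nearly irrelevant (the β band
  lives far short of the peak); it matters only for UV-pigment curve
  shapes below 400 nm.
- **Monotone long limb.** For λ > λ_max + 5 nm the template is strictly
  decreasing, so the forward map fraction → λ_max at a fixed wavelength
  is strictly increasing and the inversion (`invert_long_limb()`) is a
  bracketed bisection, robust and oracle-checkable, run to 0.001 nm. A
  mirrored branch serves points short of the peak, where the template is
  monotone decreasing in λ_max.

## 2. Scan merging and normalisation

The instrument protocol samples 750 → 350 nm outward and 351 → 749 nm on
the return, 2 nm steps. `merge_scans()` averages each return sample with
the outward sample 1 nm below it and reports the mean at the pair
midpoint, giving a 200-sample merged curve on 350.5–748.5 nm. The
pairing is deterministic; grids that do not interleave are format errors
naming the offending wavelengths.

Normalisation (`normalize_spectrum()`) subtracts a baseline — the mean
absorbance in a far-red window (default 730–750 nm) where no pigment
absorbs — and rescales to peak 1, recording the peak-minus-baseline
**transverse density** used by quality control. The peak-height rule is
the one genuinely open design choice here, and it matters:

- the **raw maximum** of signal-plus-noise is biased high (it picks the
  most favourable noise excursion near the peak). At 10% noise this
  inflates the density estimate by about +3%, deflates every limb
  fraction correspondingly, and drags λ_max about 2 nm short-ward — a
  systematic error, not a random one.
- the default is therefore a **whole-curve template fit**: least squares
  over (λ_max, amplitude), a 1 nm grid with analytic amplitude per
  candidate and quadratic refinement. It is essentially unbiased under
  noise and exact on noise-free input. The fit is used *only* to set the
  normalisation (peak height and location); the λ_max estimators remain
  the per-point inversions described next, so the template fit never
  substitutes for the estimator it supports.
- `peak_method = "max"` remains available, reproduces a noise-free
  spectrum's shape exactly, and is what droplet spectra use (their
  plateau shape is not a pigment template).

A spectrum whose maximum does not exceed its baseline is flagged
degenerate and carried through to a failed QC verdict rather than
dropped, so exclusion counts are reportable.

## 3. The two λ_max estimators

**Primary (long limb, n = 20).** The 20 merged samples immediately
long-ward of the peak whose fractional absorbance lies in a window are
each inverted through the template; the mean is the estimate and the SD
of the 20 per-point values is the "right-hand limb SD" used by QC.
Two numerical choices:

- *Point-selection window.* The preferred window is 0.20–0.80 fractional
  absorbance. At 2 nm sampling, however, a 365 nm UV pigment offers only
  11 limb samples in that window — the 20-point procedure is structurally
  impossible there — so when the preferred window is too sparse the
  selection falls back once to 0.05–0.95 (22 samples at 365 nm) before
  declaring the limb insufficient. The window in use is recorded per
  cell. Both windows are configuration, not constants.
- *Root bracketing.* Each per-point inversion is restricted to ±40 nm of
  the whole-curve template fit. Without this, a noisy tail fraction can
  invert to a root tens of nanometres long of the true peak (the
  template's tail is shallow in the λ_max direction), and at 15% noise
  the UV-pigment estimate develops a double-digit positive bias with a
  heavy upper tail. Restricted, points with no admissible root make the
  cell report an inversion failure instead of a wild number.

**Secondary (peak-centred, n = 50).** Fifty merged samples centred on
the peak: long-limb points invert as in the primary method; points at or
short of the peak use the mirrored short-limb branch; samples too close
to the peak or the noise floor to constrain the template (fraction
outside 0.02–0.995) contribute the peak wavelength or are dropped, with
the count reported. For a 365 nm pigment the centred window would extend
below the 350 nm scan floor, so the secondary estimate — and with it the
inter-method QC criterion — is structurally unavailable for UVS; this is
harmless because UVS falls under the relaxed QC regime, which does not
use it.

## 4. Quality control

Strict regime (rod, LWS, MWS), thresholds exactly as printed, strict
inequalities: transverse density **> 0.01** OD, limb SD **< 12** nm,
inter-method difference **< 6** nm. Relaxed regime (SWS, UVS, rare cell
classes): thresholds waived; a cell is retained iff it shows convincing
post-measurement bleaching *and* produced a usable estimate (the second
clause is this package's addition — without it a cell with no estimate
could "pass" QC while contributing nothing, breaking the invariant that
report counts equal manifest counts minus logged exclusions).

`check_bleach()` passes when post-bleach absorbance at the pre-bleach
peak falls below 50% of its pre-bleach value and mean short-wave
(≤ 420 nm) absorbance has not decreased (photoproduct appearance). The
short-wave clause is skipped when the pre-bleach peak itself lies inside
the short-wave window: for a UV pigment the window is dominated by the
pigment's own α band, whose disappearance necessarily lowers short-wave
absorbance, and any photoproduct large enough to compensate at 380 nm
would also violate the peak-collapse clause at 365 nm — the two clauses
are jointly unsatisfiable there, so the verdict rests on peak collapse
alone. Missing post-bleach scans are "unverified": no effect under the
strict regime (bleaching is not one of its criteria), failure under the
relaxed regime (where bleaching is the sole retention criterion).

## 5. Oil droplet λ_cut

The Lipetz construction: find the unique falling-edge crossing of 50% of
maximum (baseline-subtracted) absorbance, fit a least-squares line over
the 5 merged samples centred on it (≈ 10 nm — wide enough to average
noise, narrow enough to bound curvature bias), and extrapolate to the
maximum measured absorbance; that wavelength is λ_cut. The construction
is scale invariant, sits short-ward of the tangent point on a falling
absorbance limb, and refuses spectra with zero or multiple crossings
(diagnostics name the crossing wavelengths). T-type droplets have no
detectable absorbance and are recorded but excluded from λ_cut analysis;
P-type droplets belong to double cones and are excluded from the eye
model but summarised like the rest.

One caveat a user should know: "maximum measured absorbance" on a finite
grid is slightly below a logistic's asymptote, so translating a spectrum
across the grid moves λ_cut by the difference in truncated plateau —
about 10⁻³ nm in the tested configurations. Shift equivariance therefore
holds to that order, not to machine precision.

## 6. Population comparison and ICC

The model for each pigment or droplet type is
$y_{ij} = \mu_{pop(i)} + b_i + \varepsilon_{ij}$ with a random intercept
$b_i \sim N(0, \sigma_b^2)$ per bird — cells from one bird are not
independent — fitted by REML. The implementation profiles the variance
ratio $\theta = \sigma_b^2/\sigma_e^2$ (block-diagonal algebra via the
Woodbury identity, a bounded 1-D search with the boundary θ = 0
evaluated explicitly, then Newton polishing on wide-step finite
differences because the profiled criterion is numerically flat near its
minimum). It is authored in this package and cross-checked in the test
suite against `lme4` (variance components, fixed effects, REML
log-likelihood) and against closed-form ANOVA results in the balanced
and boundary limits.

- **Type-III F** of the population effect, with **Satterthwaite**
  denominator df by default (gradient of the contrast variance against
  the inverse REML information, computed numerically) and **containment**
  df (birds − populations) by configuration; both are reported in the
  output metadata because the original analysis software's df rule
  cannot be pinned down from the published tables.
- **EMMs**: cell-means coding makes the estimated marginal means the
  coefficients themselves; in balanced designs they equal raw population
  means to 10⁻⁹.
- **ICC** from an intercepts-only REML fit,
  $\sigma_b^2/(\sigma_b^2+\sigma_e^2)$; undefined (with a reason, not a
  number) when no bird has repeated measurements.
- Boundary fits (σ²_b → 0) are flagged, not errors; there the F
  statistic coincides with the one-way ANOVA F and the residual df is
  used.
- No multiple-testing correction by default, matching the per-type raw
  reporting convention; Holm correction is a configuration option left
  to users.

## 7. The synthetic-data generator

`generate_study()` draws population → bird → cell: per class, a bird
effect ~ N(0, σ²_bird); each cell's true λ_max is class mean +
population contrast + bird effect + N(0, σ²_resid); the cell is rendered
as outward/return scans of density × template + baseline + i.i.d.
Gaussian OD noise, with a post-bleach scan (pigment removed, Gaussian
photoproduct band added) and logistic droplet cut-off spectra whose
analytic λ_cut is recorded. A single RNG stream seeded once makes a
study byte-reproducible; every latent value lands in a ground-truth
table.

Defaults are the stated world of the study the package emulates: 7 + 5
birds; class means 500.4 (rod), 563.2 (LWS), 499.5 (MWS), 450.3 (SWS),
359.3 (UVS) nm with contrasts 6.0, 4.4, 8.8, −3.5, 6.4 nm; between-bird
and residual SDs chosen so the implied ICCs are 0.75 (rod), 0.30 (LWS)
and 0.55 (MWS) — the printed repeatabilities used as generator settings,
not as claims; transverse densities ~ N(0.020, 0.005²) OD floored at
0.005, straddling the 0.01 QC threshold; spectrum noise 10% of density
(5–15% in the recovery tests); droplet cut-off means per type with the
Y-type flaveolus mean taken as elegans + 1 nm because the printed
flaveolus value is internally inconsistent with every other Y/C entry
(an apparent typographical error; nothing targets it). The photoproduct
band is centred at 400 nm, width 35 nm, amplitude 80% of density: wide
and large enough that the short-wave clause of `check_bleach()` clears
the pigment's own short-wave tail for an SWS cell (≈ 0.40 × density)
with margin, while staying clear of every class's peak-collapse clause.

What the generator does **not** emulate: wavelength-calibration error,
instrument point-spread, baseline drift that curves with wavelength,
photoproduct spectra of real bleaching chemistry, droplet spectra that
deviate from a logistic edge, or cell-to-cell correlation beyond the
bird intercept. A green test therefore establishes that the pipeline
recovers the stated hierarchical world at the stated noise — not that it
is robust to instrument pathologies outside that world.

`generate_failures()` complements it with single-violation QC fixtures:
a sub-threshold density record; a limb distorted by a zero-mean
sinusoidal ripple (per-point inversions scatter far past 12 nm while
their mean, and the secondary estimate, barely move); a record whose
short-wavelength side is saturated at peak height, dragging the
secondary estimate more than 6 nm from the clean-limb primary; and an
SWS record whose post-bleach scan equals its pre-bleach spectrum. Each
fails exactly its intended criterion under the default configuration.

## 8. Known limitations

- The primary estimator's per-point inversion is mildly nonlinear in the
  observed fraction, so a small negative bias (a few tenths of a
  nanometre, growing with noise) survives even after the normalisation
  fix; at 15% noise the LWS bias approaches the 1 nm bound that the
  recovery tests enforce on the 5–15% mixture.
- UV pigments at 2 nm sampling sit at the edge of what the 20-point
  procedure supports; at the highest tested noise a third of UV cells
  are (correctly) flagged rather than estimated.
- The Satterthwaite implementation uses numerical second derivatives of
  the REML criterion; for very small or boundary-adjacent variance
  components it falls back to containment-style df.
- The eye model's cone ratios are 1:1:1:1 unless supplied — the source
  study never printed its ratios, and inventing non-trivial ones would
  masquerade as data. Ratio weighting only activates when ratios are
  user-supplied.
- Wavelengths are treated as exact instrument readings in nm; the
  vacuum/air distinction is far below instrument precision and ignored.
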