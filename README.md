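# mspfit

Microspectrophotometry (MSP) pipelines for visual pigment and oil droplet
spectra, with a biostatistics core for comparing photoreceptor tuning
between populations.

## The scientific problem

Microspectrophotometry measures the absorbance spectrum of a single
photoreceptor outer segment (or a cone oil droplet) by passing a
micro-beam transversely through it. Two quantities summarise each record:

- **λ_max** — the wavelength of maximum absorbance of the visual pigment,
  estimated per cell by fitting the measured spectrum to a universal
  pigment template;
- **λ_cut** — the cut-off wavelength of a coloured oil droplet, obtained
  by the Lipetz tangent construction on its absorbance spectrum.

Whether these quantities differ *within* a species — between populations
or subspecies occupying different light environments — is a question
about the raw material of sensory evolution. Answering it requires a
measurement pipeline (scan merging, normalisation, template inversion,
strict quality control) and an inferential one (cells are nested in
birds, so population comparisons need random-intercept mixed models, and
the repeatability of λ_max within birds is quantified by the intraclass
correlation coefficient). `mspfit` implements both ends, plus a
hierarchical synthetic-data generator so every stage can be exercised and
calibrated without instrument data.

## The model in brief

**Pigment template.** The vitamin-A1 (rhodopsin-like) absorbance template
of Govardovskii et al. (2000): an α band

S_α(λ) = 1 / [e^{A(a−x)} + e^{B(b−x)} + e^{C(c−x)} + D],  x = λ_max/λ,

plus a Gaussian β band, renormalised to peak 1. The curve is fully
determined by λ_max, so an absorbance *fraction* observed at a wavelength
on the descending long-wavelength limb identifies λ_max uniquely; the
per-cell **primary estimate** is the mean of 20 such per-point
inversions, the **secondary estimate** averages 50 template placements
centred on the peak, and a cell is retained only if it passes the
selection criteria (transverse density > 0.01 OD, right-limb SD < 12 nm,
inter-method difference < 6 nm; relaxed for the rare SWS/UVS classes,
which are retained on convincing bleaching evidence instead).

**Oil droplets.** λ_cut is the wavelength at which the tangent at the
half-maximum point of the falling absorbance edge, extrapolated, reaches
the maximum measured absorbance.

**Inference.** For each pigment and droplet type, λ values are modelled
as y = population + bird(ID) + ε by REML, with a type-III F test of the
population effect (Satterthwaite or containment denominator df),
estimated marginal means ± SE, and ICC = σ²_bird / (σ²_bird + σ²_resid)
from an intercepts-only fit.

**Eye model.** Predicted single-cone sensitivity is pigment absorbance ×
oil droplet transmittance under the standard avian pairing LWS–R, MWS–Y,
SWS–C, UVS–T (the T-type droplet is transparent).

## Worked example

```r
library(mspfit)

# a reduced synthetic study: 4 vs 3 birds, all five pigment classes
design <- study_design(n_birds = c(elegans = 4L, flaveolus = 3L))
design$pigment_classes$cells_per_bird <- c(4L, 4L, 2L, 1L, 1L)
design$droplet_classes$per_bird      <- c(2L, 2L, 1L, 2L, 1L)
study <- generate_study(design, seed = 7)

res <- run_pipeline(study)
estimate_lambda_max(study$records[[1]])
```

The per-cell estimate prints as

```
lambda_max estimate for cell elegans_b01_rod_c01
  primary   502.23 nm (limb SD 4.03 nm, n = 20)
  secondary 502.58 nm (n = 50); method diff 0.35 nm
  transverse density 0.0157 OD; bleached: TRUE
QC verdict (strict regime): PASS
          criterion threshold   observed pass
 transverse_density      0.01 0.01573689 TRUE
            limb_sd     12.00 4.02919996 TRUE
  method_difference      6.00 0.35133331 TRUE
```

(the generator's ground truth for this cell is 503.59 nm), and the
population comparison (`res$report`) begins

```
 pigment n_elegans mean_elegans se_elegans n_flaveolus mean_flaveolus ...
     MWS         8       496.60    0.77444           6         506.90
     rod        15       500.58    1.16771          12         506.30
```

with, per row, the type-III F, its degrees of freedom, the p value, a
significance flag at α = 0.05, and the ICC with its variance components
(here the rod contrast of ~5.7 nm is detected with p = 0.023 despite only
seven birds; the sparse UVS/SWS classes are reported with the statistics
they can support). `res$eye_models$curves` holds the predicted
single-cone sensitivity curves per population.

A command-line interface wraps the same steps:

```sh
inst/cli/mspfit generate --seed 7 --out study_dir
inst/cli/mspfit run-all --manifest study_dir --out results_dir
```

## Layout

- `R/templates.R` — pigment template, long-limb inversion, droplet
  transmittance (the mathematical kernel)
- `R/msp.R` — scan merging, normalisation, λ_max estimators, QC
- `R/droplets.R` — Lipetz λ_cut and droplet summaries
- `R/stats.R` — REML random-intercept models, type-III F, EMMs, ICC
- `R/eyemodel.R` — predicted single-cone sensitivity curves
- `R/synth.R` — hierarchical synthetic study generator and QC fixtures
- `R/io.R`, `R/pipeline.R` — file formats, configuration, orchestration,
  CLI
- `vignettes/msp-methods.Rmd` — the methods notes: model assumptions,
  tunables, generator scope, numerical choices, limitations
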