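Package: mspfit
Title: Microspectrophotometry Pipelines for Visual Pigment and Oil Droplet
    Spectra
Version: 0.1.0
Authors@R:
    person("MSP", "Maintainers", email = "msp@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-cell microspectrophotometry (MSP)
    records of vertebrate photoreceptors: merging and normalising paired
    wavelength scans, estimating visual pigment peak sensitivity (lambda-max)
    by inversion of the Govardovskii A1 absorbance template with the standard
    quality-control criteria, estimating oil droplet cut-off wavelengths
    (lambda-cut) by the Lipetz tangent construction, comparing populations
    with random-intercept linear mixed models fitted by REML (type-III F
    tests, estimated marginal means, intraclass correlation coefficients),
    and building predicted single-cone sensitivity curves that combine
    pigment absorbance with oil droplet transmittance. Includes a
    hierarchical synthetic-data generator that emulates raw MSP records
    (population, bird and cell levels) so the whole pipeline can be
    exercised and calibrated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
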