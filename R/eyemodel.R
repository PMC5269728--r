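# Predicted single-cone spectral sensitivity: pigment absorbance filtered
# by the overlying oil droplet, per cone class and per population.
#
# The fixed pigment/droplet pairing of avian single cones is used:
# LWS-R, MWS-Y, SWS-C, UVS-T; the T-type droplet has no detectable
# absorbance, so the UVS curve is the bare pigment template. Double cones
# (P-type droplets) play no part in the colour-vision model and are
# excluded.

.cone_droplet_pairing <- c(LWS = "R", MWS = "Y", SWS = "C", UVS = "T")

#' Specify a single-cone eye model
#'
#' @param lambda_max Named numeric: pigment peak wavelength (nm) for each
#'   of `UVS`, `SWS`, `MWS`, `LWS`.
#' @param lambda_cut Named numeric: droplet cut-off wavelength (nm) for the
#'   `R`, `Y` and `C` droplets (the T-type droplet is transparent and needs
#'   none).
#' @param cone_ratios Named positive weights for the four classes. The
#'   default 1:1:1:1 carries no information and is only used when
#'   normalisation mode `"ratio"` is explicitly requested with
#'   user-supplied ratios.
#' @param grid Wavelength grid, nm.
#' @param b_mid,mid_offset Droplet filter shape, see
#'   [droplet_transmittance()].
#' @return An object of class `eye_model_spec`.
#' @export
eye_model_spec <- function(lambda_max, lambda_cut,
                           cone_ratios = c(UVS = 1, SWS = 1, MWS = 1,
                                           LWS = 1),
                           grid = seq(330, 700, by = 1),
                           b_mid = 0.04, mid_offset = 15) {
  classes <- c("UVS", "SWS", "MWS", "LWS")
  if (!all(classes %in% names(lambda_max)))
    stop("lambda_max must name all of UVS, SWS, MWS, LWS", call. = FALSE)
  need_cut <- .cone_droplet_pairing[setdiff(classes, "UVS")]
  if (!all(need_cut %in% names(lambda_cut)))
    stop("lambda_cut must name the R, Y and C droplets", call. = FALSE)
  if (any(cone_ratios <= 0))
    stop("cone ratios must be positive", call. = FALSE)
  structure(list(lambda_max = lambda_max[classes],
                 lambda_cut = lambda_cut,
                 cone_ratios = cone_ratios[classes],
                 grid = grid, b_mid = b_mid, mid_offset = mid_offset),
            class = "eye_model_spec")
}

#' Predicted sensitivity curve of one cone class
#'
#' Sensitivity is proportional to pigment absorbance multiplied by the
#' transmittance of the paired oil droplet (identically 1 for the
#' transparent T-type over the UVS pigment), evaluated on the model grid.
#'
#' @param spec An [eye_model_spec()].
#' @param class One of `"UVS"`, `"SWS"`, `"MWS"`, `"LWS"`.
#' @param normalize `"peak"` scales the curve to maximum 1;
#'   `"ratio"` scales peak-1 curves by the class cone ratio (relative
#'   abundance weighting); `"none"` returns the raw product.
#' @return Numeric sensitivity on `spec$grid`.
#' @export
cone_sensitivity <- function(spec, class,
                             normalize = c("peak", "ratio", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(spec, "eye_model_spec"))
  class <- match.arg(class, c("UVS", "SWS", "MWS", "LWS"))
  pig <- pigment_absorbance(spec$lambda_max[[class]], spec$grid)
  dtype <- .cone_droplet_pairing[[class]]
  if (dtype == "T") {
    tr <- rep(1, length(spec$grid))
  } else {
    lcut <- spec$lambda_cut[[dtype]]
    if (is.null(lcut) || !is.finite(lcut))
      stop(sprintf("missing lambda_cut for the %s droplet (class %s)",
                   dtype, class), call. = FALSE)
    tr <- droplet_transmittance(spec$grid, lambda_cut = lcut,
                                b_mid = spec$b_mid,
                                mid_offset = spec$mid_offset)
  }
  s <- pig * tr
  switch(normalize,
         peak = s / max(s),
         ratio = spec$cone_ratios[[class]] * s / max(s),
         none = s)
}

#' Sensitivity curves for all cone classes
#'
#' @inheritParams cone_sensitivity
#' @return A data.frame: `wavelength`, `class`, `sensitivity`.
#' @export
eye_model_curves <- function(spec, normalize = "peak") {
  classes <- c("UVS", "SWS", "MWS", "LWS")
  do.call(rbind, lapply(classes, function(cl)
    data.frame(wavelength = spec$grid, class = cl,
               sensitivity = cone_sensitivity(spec, cl,
                                              normalize = normalize),
               stringsAsFactors = FALSE)))
}

#' Build per-population eye models from a comparison report
#'
#' Constructs one [eye_model_spec()] per population from the estimated
#' marginal means of the four cone pigments and the R/Y/C droplet cut-off
#' means, and evaluates its sensitivity curves. Populations missing a cone
#' class yield a warning and omit that curve.
#'
#' @param report A [comparison_report()] whose pigment table carries EMMs
#'   for `UVS`, `SWS`, `MWS`, `LWS` and whose droplet table carries R, Y
#'   and C means.
#' @param grid,cone_ratios,normalize,b_mid,mid_offset Passed through to the
#'   model spec.
#' @return A list with `specs` (per population) and `curves` (one
#'   data.frame with a `population` column).
#' @export
population_eye_models <- function(report, grid = seq(330, 700, by = 1),
                                  cone_ratios = c(UVS = 1, SWS = 1,
                                                  MWS = 1, LWS = 1),
                                  normalize = "peak",
                                  b_mid = 0.04, mid_offset = 15) {
  stopifnot(inherits(report, "comparison_report"))
  pops <- report$meta$populations
  specs <- list()
  curves <- list()
  for (p in pops) {
    lm_col <- paste0("mean_", p)
    pig <- report$pigments
    lmx <- stats::setNames(
      vapply(c("UVS", "SWS", "MWS", "LWS"), function(cl) {
        v <- pig[[lm_col]][pig$pigment == cl]
        if (length(v) == 1L) v else NA_real_
      }, numeric(1)), c("UVS", "SWS", "MWS", "LWS"))
    drp <- report$droplets
    lct <- stats::setNames(
      vapply(c("R", "Y", "C"), function(tp) {
        v <- drp[[lm_col]][drp$droplet_type == tp]
        if (length(v) == 1L) v else NA_real_
      }, numeric(1)), c("R", "Y", "C"))
    if (anyNA(lmx) || anyNA(lct)) {
      warning(sprintf(
        "population %s: missing cone class or droplet mean; model skipped",
        p), call. = FALSE)
      next
    }
    sp <- eye_model_spec(lmx, lct, cone_ratios = cone_ratios, grid = grid,
                         b_mid = b_mid, mid_offset = mid_offset)
    cv <- eye_model_curves(sp, normalize = normalize)
    cv$population <- p
    specs[[p]] <- sp
    curves[[p]] <- cv
  }
  list(specs = specs,
       curves = if (length(curves)) do.call(rbind, curves) else NULL)
}
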