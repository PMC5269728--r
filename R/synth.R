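# Hierarchical synthetic-data generator. Stands in for the raw retinal MSP
# records of the original study design: two populations of wild-caught
# birds (7 and 5), cells nested in birds, template-shaped absorbance
# spectra with baseline and instrument noise, post-bleach scans, and
# logistic oil droplet cut-off spectra. Every latent value is written to a
# ground-truth table so estimator recovery can be scored.

#' Describe a synthetic MSP study
#'
#' Returns the default study design: population sizes, per-class lambda_max
#' means for the baseline population, population contrasts, between-bird
#' and residual (cell) SDs, cells per bird, droplet classes, and the
#' spectral parameters (transverse density distribution near the QC
#' threshold, baseline OD, noise as a fraction of density, photoproduct
#' band). Pass modified copies to [generate_study()] to change the world
#' being simulated.
#'
#' Between-bird and residual SDs default to values whose implied
#' intraclass correlations are 0.75 (rod), 0.30 (LWS) and 0.55 (MWS), with
#' a rod population contrast of 6.0 nm — the regime the pipeline's power
#' and recovery checks are calibrated against.
#'
#' @param n_birds Named integer vector: birds per population. Names are the
#'   population labels; the first is the baseline to which `delta` applies.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_birds = c(elegans = 7L, flaveolus = 5L)) {
  if (is.null(names(n_birds)) || any(!nzchar(names(n_birds))) ||
      length(n_birds) < 1L || any(n_birds < 1L))
    stop("n_birds must be a named vector of positive counts", call. = FALSE)
  design <- list(
    n_birds = n_birds,
    pigment_classes = data.frame(
      class = c("rod", "LWS", "MWS", "SWS", "UVS"),
      mean = c(500.4, 563.2, 499.5, 450.3, 359.3),
      delta = c(6.0, 4.4, 8.8, -3.5, 6.4),
      sd_bird = c(2.0, 1.5, 2.0, 2.0, 2.0),
      sd_resid = c(1.1547, 2.2913, 1.8091, 3.0, 3.0),
      cells_per_bird = c(6L, 7L, 2L, 1L, 1L),
      stringsAsFactors = FALSE),
    droplet_classes = data.frame(
      type = c("R", "Y", "C", "P", "T"),
      mean = c(569.1, 408.2, 406.1, 423.1, NA),
      delta = c(0.2, 1.0, 1.8, 1.1, NA),
      sd_bird = c(1.0, 1.0, 1.0, 2.0, NA),
      sd_resid = c(1.5, 2.0, 1.5, 4.0, NA),
      per_bird = c(2L, 4L, 1L, 5L, 1L),
      stringsAsFactors = FALSE),
    density_mean = 0.020, density_sd = 0.005, density_floor = 0.005,
    baseline_od = 0.005,
    noise_sd_frac = 0.10,
    droplet_max_od = 0.05, droplet_steepness = 0.08,
    droplet_noise_frac = 0.02,
    photoproduct_center = 400, photoproduct_width = 35,
    photoproduct_amp_frac = 0.8)
  class(design) <- c("study_design", "list")
  design
}

.outward_grid <- function() seq(750, 350, by = -2)
.return_grid <- function() seq(351, 749, by = 2)

# Paired noisy scans of a deterministic absorbance function of wavelength.
.scan_pair <- function(od_fun, noise_sd) {
  wo <- .outward_grid()
  wr <- .return_grid()
  out <- spectral_scan(wo, od_fun(wo) + stats::rnorm(length(wo), 0, noise_sd),
                       direction = "outward")
  ret <- spectral_scan(wr, od_fun(wr) + stats::rnorm(length(wr), 0, noise_sd),
                       direction = "return")
  list(outward = out, return_scan = ret)
}

.pigment_od_fun <- function(lambda_max, density, baseline) {
  force(lambda_max); force(density); force(baseline)
  function(wl) density * .gov_template(lambda_max, wl) + baseline
}

.photoproduct_scan <- function(design, density) {
  wo <- .outward_grid()
  amp <- design$photoproduct_amp_frac * density
  od <- design$baseline_od +
    amp * exp(-((wo - design$photoproduct_center) /
                  design$photoproduct_width)^2) +
    stats::rnorm(length(wo), 0, design$noise_sd_frac * density)
  spectral_scan(wo, od, direction = "outward")
}

# Logistic long-pass absorbance whose Lipetz lambda_cut is analytically
# lcut: A(wl) = M / (1 + exp(k (wl - lh))) with lh = lcut + 2/k (the
# tangent at the half-maximum point reaches M at lh - 2/k).
.droplet_od_fun <- function(lcut, M, k, baseline) {
  lh <- lcut + 2 / k
  force(M); force(k); force(baseline)
  function(wl) M / (1 + exp(k * (wl - lh))) + baseline
}

.draw_density <- function(design) {
  max(design$density_floor,
      stats::rnorm(1, design$density_mean, design$density_sd))
}

#' Generate a complete synthetic MSP study
#'
#' Draws the hierarchical structure population -> bird -> cell: for each
#' class, a per-bird random effect ~ N(0, sd_bird^2); each cell's true
#' lambda_max is the class mean, plus the population contrast, plus the
#' bird effect, plus N(0, sd_resid^2). Each cell is rendered as outward and
#' return 2 nm scans of `density x template(lambda_max) + baseline` with
#' i.i.d. Gaussian OD noise, and a post-bleach scan in which the pigment is
#' gone and a short-wavelength photoproduct band appears. Oil droplets are
#' rendered as logistic cut-off spectra with drawn lambda_cut (the
#' transparent T-type has no absorbance band).
#'
#' @param design A [study_design()].
#' @param seed Integer RNG seed; recorded in the returned object and in
#'   every written manifest. The generator uses a single RNG stream, so a
#'   seed fixes the study byte-for-byte.
#' @param noise_sd_frac Optional override of the design's spectrum noise.
#' @return An object of class `msp_study`: `records` (list of
#'   `msp_record`), `droplet_records`, `truth_cells`, `truth_droplets`,
#'   `design`, `seed`.
#' @export
generate_study <- function(design = study_design(), seed = 1L,
                           noise_sd_frac = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(noise_sd_frac)) design$noise_sd_frac <- noise_sd_frac
  set.seed(as.integer(seed))
  pops <- names(design$n_birds)
  records <- list()
  droplets <- list()
  tc <- list()
  td <- list()
  for (pi in seq_along(pops)) {
    pop <- pops[pi]
    for (b in seq_len(design$n_birds[[pi]])) {
      bird <- sprintf("%s_b%02d", pop, b)
      pc <- design$pigment_classes
      for (ci in seq_len(nrow(pc))) {
        cls <- pc$class[ci]
        if (pc$cells_per_bird[ci] < 1L) next
        bird_eff <- stats::rnorm(1, 0, pc$sd_bird[ci])
        for (k in seq_len(pc$cells_per_bird[ci])) {
          lm_true <- pc$mean[ci] + if (pi > 1L) pc$delta[ci] else 0
          lm_true <- lm_true + bird_eff + stats::rnorm(1, 0, pc$sd_resid[ci])
          density <- .draw_density(design)
          cell_id <- sprintf("%s_%s_c%02d", bird, cls, k)
          sc <- .scan_pair(.pigment_od_fun(lm_true, density,
                                           design$baseline_od),
                           design$noise_sd_frac * density)
          pb <- .photoproduct_scan(design, density)
          records[[cell_id]] <- msp_record(cell_id, bird, pop, cls,
                                           sc$outward, sc$return_scan,
                                           post_bleach = pb)
          tc[[cell_id]] <- data.frame(
            cell_id = cell_id, bird_id = bird, population = pop,
            class = cls, lambda_max_true = lm_true,
            bird_effect = bird_eff, density = density,
            stringsAsFactors = FALSE)
        }
      }
      dc <- design$droplet_classes
      for (ci in seq_len(nrow(dc))) {
        tp <- dc$type[ci]
        bird_eff <- if (tp == "T") 0 else stats::rnorm(1, 0, dc$sd_bird[ci])
        for (k in seq_len(dc$per_bird[ci])) {
          did <- sprintf("%s_drop%s_%02d", bird, tp, k)
          if (tp == "T") {
            lcut_true <- NA_real_
            od_fun <- function(wl) rep(design$baseline_od, length(wl))
            noise <- design$droplet_noise_frac * design$droplet_max_od
          } else {
            lcut_true <- dc$mean[ci] + (if (pi > 1L) dc$delta[ci] else 0) +
              bird_eff + stats::rnorm(1, 0, dc$sd_resid[ci])
            od_fun <- .droplet_od_fun(lcut_true, design$droplet_max_od,
                                      design$droplet_steepness,
                                      design$baseline_od)
            noise <- design$droplet_noise_frac * design$droplet_max_od
          }
          sc <- .scan_pair(od_fun, noise)
          merged <- suppressWarnings(
            normalize_spectrum(merge_scans(sc$outward, sc$return_scan),
                               peak_method = "max"))
          droplets[[did]] <- droplet_record(did, bird, pop, tp, merged)
          td[[did]] <- data.frame(
            droplet_id = did, bird_id = bird, population = pop,
            droplet_type = tp, lambda_cut_true = lcut_true,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(records = records, droplet_records = droplets,
                 truth_cells = do.call(rbind, tc),
                 truth_droplets = do.call(rbind, td),
                 design = design, seed = as.integer(seed)),
            class = "msp_study")
}

#' @export
print.msp_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic MSP study (seed %d): %d cell records, %d droplets, %d birds\n",
    x$seed, length(x$records), length(x$droplet_records),
    sum(x$design$n_birds)))
  invisible(x)
}

#' Generate single-violation quality-control fixtures
#'
#' Builds a labelled fixture set in which each record violates exactly one
#' selection criterion while satisfying the others, plus a clean record per
#' regime:
#' \describe{
#'   \item{density}{a faint rod record (transverse density below 0.01 OD)
#'     with negligible noise, so the limb SD and method agreement stay
#'     healthy.}
#'   \item{limb_sd}{a rod record whose long-wavelength limb carries a
#'     zero-mean sinusoidal distortion: per-point template inversions
#'     scatter widely (limb SD above 12 nm) but their mean, and the
#'     peak-centred secondary estimate, barely move.}
#'   \item{method_difference}{a rod record whose short-wavelength side is
#'     saturated at peak height (a contaminated record): the long limb, and
#'     with it the primary estimate, stays clean while the 50-point
#'     peak-centred secondary estimate is dragged more than 6 nm.}
#'   \item{bleaching}{an SWS record (relaxed regime) whose post-bleach scan
#'     is identical to the pre-bleach spectrum.}
#' }
#'
#' @param seed RNG seed for the small amount of measurement noise.
#' @return A list: `records` (named list of `msp_record`), `intended`
#'   (data.frame mapping cell_id to the criterion it must fail; `"none"`
#'   for the clean records).
#' @export
generate_failures <- function(seed = 1L) {
  set.seed(as.integer(seed))
  design <- study_design()
  baseline <- design$baseline_od
  mk <- function(cell_id, cls, od_fun, noise_sd, post = "bleached",
                 density = 0.02) {
    sc <- .scan_pair(od_fun, noise_sd)
    pb <- switch(post,
                 bleached = .photoproduct_scan(design, density),
                 unbleached = spectral_scan(.outward_grid(),
                                            od_fun(.outward_grid()),
                                            direction = "outward"),
                 none = NULL)
    msp_record(cell_id, "fixture_bird", "fixture_pop", cls,
               sc$outward, sc$return_scan, post_bleach = pb)
  }
  recs <- list()
  # clean strict-regime record
  recs$clean_rod <- mk("clean_rod", "rod",
                       .pigment_od_fun(500, 0.02, baseline), 2e-4)
  # clean relaxed-regime record (passes on bleaching evidence)
  recs$clean_sws <- mk("clean_sws", "SWS",
                       .pigment_od_fun(450, 0.02, baseline), 2e-4)
  # transverse density at half the threshold
  recs$density_fail <- mk("density_fail", "rod",
                          .pigment_od_fun(500, 0.005, baseline), 5e-5,
                          density = 0.005)
  # sinusoidal limb distortion: zero-mean per-point scatter on the limb
  # inflates the per-point lambda_max SD far past 12 nm while the mean
  # (and the 50-point secondary estimate) barely move
  limb_fun <- function(wl) {
    fr <- .gov_template(500, wl)
    ripple <- 0.4 * sin(2 * pi * (wl - 505) / 16) *
      as.numeric(wl > 505 & wl < 565)
    0.02 * pmax(fr + ripple, 0) + baseline
  }
  recs$limb_sd_fail <- mk("limb_sd_fail", "rod", limb_fun, 2e-4)
  # saturated short-wavelength plateau (contaminated record): the long
  # limb, hence the primary estimate, is clean, but the peak-centred
  # secondary estimate is dragged more than 6 nm short-ward
  plateau_fun <- function(wl) {
    fr <- .gov_template(500, wl)
    fr[wl < 500 & wl > 420] <- 1
    0.02 * fr + baseline
  }
  recs$method_diff_fail <- mk("method_diff_fail", "rod", plateau_fun, 2e-4)
  # relaxed-regime record that refuses to bleach
  recs$bleach_fail <- mk("bleach_fail", "SWS",
                         .pigment_od_fun(450, 0.02, baseline), 2e-4,
                         post = "unbleached")
  intended <- data.frame(
    cell_id = c("clean_rod", "clean_sws", "density_fail", "limb_sd_fail",
                "method_diff_fail", "bleach_fail"),
    intended_failure = c("none", "none", "transverse_density", "limb_sd",
                         "method_difference", "bleaching"),
    stringsAsFactors = FALSE)
  list(records = recs, intended = intended)
}
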