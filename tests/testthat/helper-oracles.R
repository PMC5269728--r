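# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive results by brute force (grid search, closed
# forms, explicit enumeration) so they stay independent of the package's
# own numerical paths.

# Exhaustive grid-search inversion: lambda_max minimising
# |template(lambda_max, wavelength) - fraction| on a 0.01 nm grid over the
# long-limb domain.
oracle_invert_grid <- function(fraction, wavelength, halfspan = 120) {
  grid <- seq(max(300, wavelength - halfspan), wavelength - 0.25, by = 0.01)
  vals <- mspfit:::.gov_template(grid, wavelength)
  grid[which.min(abs(vals - fraction))]
}

# Independent re-implementation of the primary estimator using explicit
# pair averaging and two-stage grid-search inversion (no bisection).
oracle_estimate_primary <- function(outward, return_scan,
                                    window = c(0.20, 0.80),
                                    fallback = c(0.05, 0.95),
                                    n_points = 20L) {
  wo <- rev(outward$wavelengths)
  ao <- rev(outward$absorbance)
  wr <- return_scan$wavelengths
  ar <- return_scan$absorbance
  k <- seq_along(wr)
  wl <- (wo[k] + wr[k]) / 2
  ab <- (ao[k] + ar[k]) / 2
  base <- mean(ab[wl >= 730 & wl <= 750])
  y <- ab - base
  lm_grid <- seq(340, 620, by = 0.5)
  sse <- vapply(lm_grid, function(lm) {
    tv <- mspfit:::.gov_template(lm, wl)
    s <- sum(tv * y) / sum(tv * tv)
    sum((y - s * tv)^2)
  }, numeric(1))
  pk <- lm_grid[which.min(sse)]
  tv <- mspfit:::.gov_template(pk, wl)
  dens <- sum(tv * y) / sum(tv * tv)
  fr <- y / dens
  ipk <- which.min(abs(wl - pk))
  cand <- which(seq_along(fr) > ipk & fr > window[1] & fr < window[2])
  if (length(cand) < n_points)
    cand <- which(seq_along(fr) > ipk & fr > fallback[1] & fr < fallback[2])
  if (length(cand) < n_points) return(NA_real_)
  sel <- cand[seq_len(n_points)]
  lo <- max(300, wl[ipk] - 40)
  hi <- min(700, wl[ipk] + 40)
  pts <- vapply(sel, function(i) {
    g1 <- seq(lo, min(hi, wl[i] - 0.25), by = 0.1)
    v1 <- mspfit:::.gov_template(g1, wl[i])
    c1 <- g1[which.min(abs(v1 - fr[i]))]
    g2 <- seq(max(lo, c1 - 0.15), min(hi, c1 + 0.15), by = 0.01)
    v2 <- mspfit:::.gov_template(g2, wl[i])
    g2[which.min(abs(v2 - fr[i]))]
  }, numeric(1))
  mean(pts)
}

# Analytic Lipetz construction for a logistic cut-off spectrum sampled on
# a grid: half-max crossing and tangent from the closed-form derivative.
oracle_lipetz_logistic <- function(lcut, M, k, grid) {
  lh <- lcut + 2 / k
  a <- M / (1 + exp(k * (grid - lh)))
  a_max <- max(a)
  half <- a_max / 2
  l0 <- lh + log(M / half - 1) / k
  slope <- -k * half * (1 - half / M)
  l0 + (a_max - half) / slope
}

# Closed-form one-way ANOVA ICC estimator for balanced designs.
oracle_icc_anova <- function(value, bird) {
  kk <- unique(table(bird))
  stopifnot(length(kk) == 1L)
  msb <- kk * stats::var(tapply(value, bird, mean))
  msw <- mean(tapply(value, bird, stats::var))
  vb <- max(0, (msb - msw) / kk)
  vb / (vb + msw)
}

# Noise-free or noisy synthetic pigment record built through the package's
# scan constructors (spectral shapes from the template module).
make_pigment_record <- function(lambda_max, density = 0.02,
                                baseline = 0.005, noise_sd = 0,
                                cell_id = "cell", bird_id = "bird",
                                population = "pop", class = "rod",
                                post_bleach = TRUE) {
  sc <- mspfit:::.scan_pair(
    mspfit:::.pigment_od_fun(lambda_max, density, baseline), noise_sd)
  pb <- if (post_bleach)
    mspfit:::.photoproduct_scan(study_design(), density)
  else NULL
  msp_record(cell_id, bird_id, population, class,
             sc$outward, sc$return_scan, post_bleach = pb)
}

# Normalised merged spectrum of a pigment cell, shortcut for estimator
# tests.
make_merged <- function(lambda_max, density = 0.02, baseline = 0.005,
                        noise_sd = 0, peak_method = "template") {
  sc <- mspfit:::.scan_pair(
    mspfit:::.pigment_od_fun(lambda_max, density, baseline), noise_sd)
  suppressWarnings(normalize_spectrum(
    merge_scans(sc$outward, sc$return_scan), peak_method = peak_method))
}

# Hierarchical lambda_max measurement set (no spectra) for the stats
# module.
make_measurements <- function(n_birds = c(a = 7, b = 5), cells = 6,
                              mu = 500, delta = 0, sd_bird = 2,
                              sd_resid = 1.2) {
  rows <- list()
  for (p in seq_along(n_birds)) {
    for (b in seq_len(n_birds[[p]])) {
      bm <- mu + (if (p > 1) delta else 0) + stats::rnorm(1, 0, sd_bird)
      id <- sprintf("%s_b%02d", names(n_birds)[p], b)
      rows[[id]] <- data.frame(
        value = bm + stats::rnorm(cells, 0, sd_resid),
        bird_id = id, population = names(n_birds)[p],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Droplet merged spectrum with a logistic cut-off on the standard grid.
make_droplet_merged <- function(lcut, M = 0.05, k = 0.08, baseline = 0.005,
                                noise_sd = 0) {
  sc <- mspfit:::.scan_pair(
    mspfit:::.droplet_od_fun(lcut, M, k, baseline), noise_sd)
  suppressWarnings(normalize_spectrum(
    merge_scans(sc$outward, sc$return_scan), peak_method = "max"))
}

# Reduced designs for simulation-heavy tests.
rod_only_design <- function() {
  d <- study_design()
  d$pigment_classes <- d$pigment_classes[d$pigment_classes$class == "rod", ]
  d$droplet_classes$per_bird <- 0L
  d
}
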