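test_that("scan and record constructors validate their invariants", {
  expect_error(spectral_scan(seq(750, 350, -2), rep(0, 200), "outward"),
               "lengths differ")
  expect_error(spectral_scan(seq(750, 350, -3), rep(0, 134), "outward"),
               "steps")
  expect_error(spectral_scan(seq(351, 749, 2), rep(NaN, 200), "return"),
               "non-finite")
  ok_out <- spectral_scan(seq(750, 350, -2), rep(0.02, 201), "outward")
  ok_ret <- spectral_scan(seq(351, 749, 2), rep(0.02, 200), "return")
  expect_error(msp_record("c", "", "pop", "rod", ok_out, ok_ret),
               "non-empty")
  expect_error(msp_record("c", "b", "pop", "rod", ok_ret, ok_out))
})

test_that("merge averages adjacent pairs on the midpoint grid", {
  # constant scans: mean of equal values
  out <- spectral_scan(seq(750, 350, -2), rep(0.02, 201), "outward")
  ret <- spectral_scan(seq(351, 749, 2), rep(0.02, 200), "return")
  m <- merge_scans(out, ret)
  expect_equal(length(m$wavelengths), 200L)  # 201 + 200 samples -> 200 pairs
  expect_equal(m$wavelengths, seq(350.5, 748.5, by = 2))
  expect_true(all(m$mean_absorbance == 0.02))
  # linear absorbance: merged equals the line at pair midpoints
  f <- function(wl) 0.001 * wl + 0.5
  out2 <- spectral_scan(seq(750, 350, -2), f(seq(750, 350, -2)), "outward")
  ret2 <- spectral_scan(seq(351, 749, 2), f(seq(351, 749, 2)), "return")
  m2 <- merge_scans(out2, ret2)
  expect_equal(m2$mean_absorbance, f(m2$wavelengths), tolerance = 1e-12)
  # non-interleaving grids are a format error naming wavelengths
  bad_ret <- spectral_scan(seq(352, 750, 2), rep(0.02, 200), "return")
  expect_error(merge_scans(out, bad_ret), "interleave")
})

test_that("normalisation recovers an affine template construction", {
  m <- make_merged(500, density = 0.02, baseline = 0.005,
                   peak_method = "max")
  expect_equal(m$transverse_density, 0.02, tolerance = 1e-3)
  expect_equal(max(m$fractional), 1)
  # fractional reproduces the affine construction exactly once the
  # expectation mirrors the pipeline's sampling: merged values are means of
  # adjacent 2 nm samples, and the baseline carries the template's small
  # far-red tail
  tmpl <- (mspfit:::.gov_template(500, m$wavelengths - 0.5) +
             mspfit:::.gov_template(500, m$wavelengths + 0.5)) / 2
  tail_mean <- mean(tmpl[m$wavelengths >= 730 & m$wavelengths <= 750])
  expect_equal(m$fractional, (tmpl - tail_mean) / (max(tmpl) - tail_mean),
               tolerance = 1e-9)
  expect_equal(m$fractional,
               mspfit:::.gov_template(500, m$wavelengths) /
                 max(mspfit:::.gov_template(500, m$wavelengths)),
               tolerance = 1e-3)
  # template peak fit agrees closely on noise-free input
  mt <- make_merged(500, peak_method = "template")
  expect_equal(mt$transverse_density, 0.02, tolerance = 1e-4)
  expect_equal(mt$peak_wavelength, 500, tolerance = 2)
})

test_that("flat spectra are flagged degenerate, not fatal", {
  out <- spectral_scan(seq(750, 350, -2), rep(0.01, 201), "outward")
  ret <- spectral_scan(seq(351, 749, 2), rep(0.01, 200), "return")
  expect_warning(m <- normalize_spectrum(merge_scans(out, ret),
                                         peak_method = "max"),
                 "degenerate")
  expect_true(m$degenerate)
  expect_true(all(is.na(m$fractional)))
  p <- estimate_primary(m)
  expect_false(p$ok)
  expect_equal(p$reason, "degenerate_spectrum")
})

test_that("primary estimator self-inverts and flags missing limbs", {
  m <- make_merged(563.2)
  p <- estimate_primary(m)
  expect_true(p$ok)
  expect_equal(p$lambda_max, 563.2, tolerance = 0.05)
  expect_lt(p$sd, 0.1)
  expect_equal(p$n, 20L)
  # truncated just long of the peak: no usable limb
  mtr <- make_merged(563.2)
  keep <- mtr$wavelengths <= 575
  for (fld in c("wavelengths", "mean_absorbance", "fractional"))
    mtr[[fld]] <- mtr[[fld]][keep]
  mtr$peak_index <- min(mtr$peak_index, sum(keep))
  ptr <- estimate_primary(mtr)
  expect_false(ptr$ok)
  expect_equal(ptr$reason, "insufficient_limb")
  # ultraviolet pigment: preferred window too sparse, fallback engages
  muv <- make_merged(365)
  puv <- estimate_primary(muv)
  expect_true(puv$ok)
  expect_equal(puv$window_used, "fallback")
  expect_equal(puv$lambda_max, 365, tolerance = 0.3)
})

test_that("secondary estimator agrees with primary on clean spectra", {
  for (lm in c(450, 505, 565)) {
    m <- make_merged(lm)
    s <- estimate_secondary(m)
    expect_true(s$ok)
    expect_equal(s$lambda_max, lm, tolerance = 0.5)
    p <- estimate_primary(m)
    expect_lt(abs(p$lambda_max - s$lambda_max), 0.5)
  }
})

test_that("secondary variance does not exceed primary variance", {
  set.seed(31)
  reps <- replicate(120, {
    m <- make_merged(505, noise_sd = 0.1 * 0.02)
    c(p = estimate_primary(m)$lambda_max,
      s = estimate_secondary(m)$lambda_max)
  })
  expect_lt(stats::var(reps["s", ], na.rm = TRUE),
            stats::var(reps["p", ], na.rm = TRUE))
})

test_that("bleach check walks its two clauses", {
  m <- make_merged(505)
  wo <- seq(750, 350, -2)
  # strong bleach: peak gone, short-wave photoproducts appear
  good <- spectral_scan(wo, 0.005 + 0.8 * 0.02 *
                          exp(-((wo - 400) / 35)^2), "outward")
  expect_true(check_bleach(m, good))
  # unchanged spectrum: not bleached
  same <- spectral_scan(wo, 0.005 + 0.02 *
                          mspfit:::.gov_template(505, wo), "outward")
  expect_false(check_bleach(m, same))
  # peak reduced below half with short-wave region untouched: bleached
  tm <- mspfit:::.gov_template(505, wo)
  dip <- ifelse(abs(wo - 505) < 60, 0.4, 1)
  expect_true(check_bleach(m, spectral_scan(wo, 0.005 + 0.02 * tm * dip,
                                            "outward")))
  # missing scan: unverified
  expect_true(is.na(check_bleach(m, NULL)))
})

test_that("strict QC applies the three printed thresholds strictly", {
  est <- list(transverse_density = 0.02, sd_right_limb = 5,
              method_difference = 2, lambda_max_primary = 500)
  expect_true(apply_qc(est, "rod")$passed)
  # density exactly at threshold fails the strictly-greater-than rule
  est$transverse_density <- 0.01
  v <- apply_qc(est, "LWS")
  expect_false(v$passed)
  expect_equal(v$criteria$criterion[!v$criteria$pass], "transverse_density")
  # boundary cases for the two nm criteria
  est$transverse_density <- 0.02
  est$sd_right_limb <- 12
  expect_false(apply_qc(est, "MWS")$passed)
  est$sd_right_limb <- 5
  est$method_difference <- 6
  expect_false(apply_qc(est, "rod")$passed)
})

test_that("relaxed QC retains on bleaching evidence alone", {
  bad <- list(transverse_density = 0.005, sd_right_limb = 20,
              method_difference = 8, lambda_max_primary = 452)
  expect_true(apply_qc(bad, "SWS", bleached = TRUE)$passed)
  expect_false(apply_qc(bad, "UVS", bleached = FALSE)$passed)
  expect_false(apply_qc(bad, "UVS", bleached = NA)$passed)
  # no estimate, nothing to retain
  none <- list(transverse_density = 0.02, lambda_max_primary = NA_real_)
  expect_false(apply_qc(none, "SWS", bleached = TRUE)$passed)
})

test_that("pigment classification uses boundaries and morphology", {
  expect_equal(classify_pigment(359.3), "UVS")
  expect_equal(classify_pigment(450.3), "SWS")
  expect_equal(classify_pigment(563.2), "LWS")
  expect_equal(classify_pigment(503, morphology = "rod"), "rod")
  expect_equal(classify_pigment(503, morphology = "single cone"), "MWS")
  expect_equal(classify_pigment(503), "unknown")
  expect_error(classify_pigment(700), "620")
})
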