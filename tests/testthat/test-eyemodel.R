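lmx <- c(UVS = 365, SWS = 450, MWS = 505, LWS = 565)
lct <- c(R = 569, Y = 508, C = 443)

test_that("cone sensitivity combines pigment and droplet filter", {
  spec <- eye_model_spec(lmx, lct)
  # UVS: transparent T-type droplet, curve equals the bare template
  uvs <- cone_sensitivity(spec, "UVS")
  bare <- pigment_absorbance(365, spec$grid)
  expect_equal(uvs, bare / max(bare), tolerance = 1e-12)
  # long-pass filtering never shifts the effective peak short-ward
  lws <- cone_sensitivity(spec, "LWS", normalize = "none")
  prod <- pigment_absorbance(565, spec$grid) *
    droplet_transmittance(spec$grid, lambda_cut = 569)
  expect_equal(lws, prod, tolerance = 1e-12)
  expect_gte(spec$grid[which.max(lws)], 565 - 0.5)
  # a cut far below the evaluated support reproduces the bare pigment
  # (steep edge so the filter saturates within the grid)
  spec2 <- eye_model_spec(lmx, c(R = 340, Y = 508, C = 443),
                          grid = seq(430, 700, by = 1), b_mid = 0.4)
  lws2 <- cone_sensitivity(spec2, "LWS")
  bare_l <- pigment_absorbance(565, spec2$grid)
  expect_equal(lws2, bare_l / max(bare_l), tolerance = 1e-6)
})

test_that("curves are finite, non-negative and peak-normalised", {
  spec <- eye_model_spec(lmx, lct)
  cv <- eye_model_curves(spec)
  expect_true(all(is.finite(cv$sensitivity)))
  expect_true(all(cv$sensitivity >= 0))
  for (cl in unique(cv$class))
    expect_equal(max(cv$sensitivity[cv$class == cl]), 1, tolerance = 1e-9)
})

test_that("spec constructor rejects incomplete or invalid inputs", {
  expect_error(eye_model_spec(lmx[-1], lct), "UVS")
  expect_error(eye_model_spec(lmx, lct[-1]), "R, Y and C")
  expect_error(eye_model_spec(lmx, lct, cone_ratios = c(UVS = -1, SWS = 1,
                                                        MWS = 1, LWS = 1)),
               "positive")
})

make_report_fixture <- function(shift_b = c(UVS = 6.4, SWS = -3.5,
                                            MWS = 8.8, LWS = 4.4)) {
  pig <- data.frame(pigment = c("UVS", "SWS", "MWS", "LWS"),
                    mean_a = unname(lmx), mean_b = unname(lmx + shift_b),
                    stringsAsFactors = FALSE)
  drp <- data.frame(droplet_type = c("R", "Y", "C"),
                    mean_a = unname(lct), mean_b = unname(lct + 0.5),
                    stringsAsFactors = FALSE)
  structure(list(pigments = pig, droplets = drp,
                 meta = list(populations = c("a", "b"))),
            class = "comparison_report")
}

test_that("population eye models follow the estimated means", {
  rep <- make_report_fixture()
  eye <- population_eye_models(rep)
  expect_named(eye$specs, c("a", "b"))
  # LWS contrast direction: population b peaks long-ward
  pk <- function(p) {
    cv <- eye$curves[eye$curves$population == p &
                       eye$curves$class == "LWS", ]
    cv$wavelength[which.max(cv$sensitivity)]
  }
  expect_gt(pk("b"), pk("a"))
  # identical inputs give identical models; swapped labels swap curves
  rep_same <- make_report_fixture(shift_b = c(UVS = 0, SWS = 0,
                                              MWS = 0, LWS = 0))
  rep_same$droplets$mean_b <- rep_same$droplets$mean_a
  eye_same <- population_eye_models(rep_same)
  ca <- eye_same$curves[eye_same$curves$population == "a",
                        "sensitivity"]
  cb <- eye_same$curves[eye_same$curves$population == "b",
                        "sensitivity"]
  expect_identical(ca, cb)
  # missing class: both population models skipped, one warning each
  rep_miss <- make_report_fixture()
  rep_miss$pigments <- rep_miss$pigments[-1, ]
  w <- capture_warnings(eye_m <- population_eye_models(rep_miss))
  expect_length(w, 2L)
  expect_match(w, "missing", all = TRUE)
  expect_length(eye_m$specs, 0L)
})
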