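test_that("piecewise-linear spectrum yields the analytic lambda_cut", {
  wl <- seq(350.5, 748.5, by = 2)
  a <- pmin(1, pmax(0, (580 - wl) / 80))
  sp <- list(wavelengths = wl, mean_absorbance = a)
  res <- lambda_cut(sp)
  # tangent is the limb itself; it reaches the plateau where it ends
  expect_equal(res$lambda_cut, 500, tolerance = 1e-9)
  expect_equal(res$tangent_point, 540, tolerance = 1e-9)
  expect_equal(res$slope, -1 / 80, tolerance = 1e-12)
  # lambda_cut sits short-ward of the tangent point on a falling limb
  expect_lte(res$lambda_cut, res$tangent_point)
  # scale invariance
  res2 <- lambda_cut(list(wavelengths = wl, mean_absorbance = 2 * a))
  expect_equal(res2$lambda_cut, res$lambda_cut, tolerance = 1e-9)
})

test_that("ambiguous spectra raise diagnostics instead of guessing", {
  wl <- seq(350.5, 748.5, by = 2)
  # two half-max crossings on the falling side
  bump <- exp(-((wl - 450) / 30)^2) + 0.9 * exp(-((wl - 620) / 25)^2)
  expect_error(lambda_cut(list(wavelengths = wl, mean_absorbance = bump)),
               "ambiguous")
  # monotone rising spectrum: no falling-edge crossing
  expect_error(lambda_cut(list(wavelengths = wl,
                               mean_absorbance = wl / 800)),
               "ambiguous|negative")
})

test_that("logistic cut-offs match the analytic-derivative oracle", {
  for (lcut in c(420, 500, 569)) {
    for (k in c(0.06, 0.08, 0.12)) {
      m <- make_droplet_merged(lcut, k = k)
      res <- lambda_cut(m)
      orc <- oracle_lipetz_logistic(lcut, 0.05, k, m$wavelengths)
      expect_lt(abs(res$lambda_cut - orc), 0.5)
    }
  }
})

test_that("lambda_cut is shift equivariant on grid-aligned translations", {
  wl <- seq(350.5, 748.5, by = 2)
  f <- function(w) 0.05 / (1 + exp(0.08 * (w - 480)))
  base <- lambda_cut(list(wavelengths = wl, mean_absorbance = f(wl)))
  shft <- lambda_cut(list(wavelengths = wl, mean_absorbance = f(wl - 10)))
  # exact up to the plateau content truncated at the grid edge (< 1e-3 nm)
  expect_equal(shft$lambda_cut - base$lambda_cut, 10, tolerance = 1e-3)
})

test_that("steeper slopes pull lambda_cut toward lambda_mid", {
  lh <- 500  # common half-maximum wavelength
  wl <- seq(350.5, 748.5, by = 2)
  cuts <- sapply(c(0.05, 0.08, 0.15), function(k) {
    a <- 0.05 / (1 + exp(k * (wl - lh)))
    lambda_cut(list(wavelengths = wl, mean_absorbance = a))$lambda_cut
  })
  expect_true(all(diff(cuts) > 0))     # approaching lh from below
  expect_true(all(cuts < lh))
})

test_that("measure_droplets records T-types and failures without aborting", {
  m <- make_droplet_merged(500)
  recs <- list(droplet_record("d1", "b1", "p1", "R", m),
               droplet_record("d2", "b1", "p1", "T", m))
  tab <- measure_droplets(recs)
  expect_equal(nrow(tab), 2L)
  expect_false(is.na(tab$lambda_cut[1]))
  expect_true(is.na(tab$lambda_cut[2]))
  expect_match(tab$note[2], "T-type")
})

test_that("droplet summary mirrors the per-type comparison schema", {
  set.seed(77)
  rows <- list()
  for (p in c("a", "b")) for (b in 1:4) for (i in 1:3) {
    rows[[length(rows) + 1]] <- data.frame(
      droplet_id = sprintf("%s%s%s", p, b, i),
      bird_id = paste0(p, b), population = p, droplet_type = "R",
      lambda_cut = 569 + (p == "b") * 60 + rnorm(1, 0, 1),
      tangent_point = NA, slope = NA, note = "",
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  s <- summarize_droplets(tab)
  expect_equal(s$droplet_type, "R")
  # construction: R-type groups 60 nm apart
  expect_equal(s$mean_b - s$mean_a, 60,
               tolerance = 3 * sqrt(s$se_a^2 + s$se_b^2) + 1)
  expect_true(s$significant)
  # constant single group: zero standard error
  const <- tab[tab$population == "a", ]
  const$lambda_cut <- 569
  s2 <- summarize_droplets(const)
  expect_equal(s2$se_a, 0)
})
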