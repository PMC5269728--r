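test_that("measurement_set enforces the hierarchy invariants", {
  expect_error(measurement_set(1:4, c("b1", "b1", "b1", "b1"),
                               c("a", "a", "b", "b")),
               "more than one population")
  expect_error(measurement_set(1:3, rep("b1", 3), rep("a", 3)),
               "two birds")
  expect_error(measurement_set(c(1, NaN), c("b1", "b2"), c("a", "b")),
               "non-finite")
})

test_that("REML fit matches lme4 on unbalanced hierarchical data", {
  skip_if_not_installed("lme4")
  set.seed(42)
  for (i in 1:4) {
    d <- make_measurements(cells = sample(3:7, 1), sd_bird = runif(1, 1, 3),
                           sd_resid = runif(1, 0.5, 2), delta = 6)
    f <- fit_lmm(measurement_set(d$value, d$bird_id, d$population))
    lf <- lme4::lmer(value ~ population + (1 | bird_id), data = d,
                     REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(lf))
    expect_equal(f$var_bird, vc$vcov[1], tolerance = 1e-4)
    expect_equal(f$var_resid, vc$vcov[2], tolerance = 1e-5)
    expect_equal(f$fixed_effect_estimate,
                 unname(lme4::fixef(lf)[2]), tolerance = 1e-5)
    expect_equal(f$reml_loglik, as.numeric(stats::logLik(lf)),
                 tolerance = 1e-6)
  }
})

test_that("constant bird means give the exact contrast", {
  # every cell within a bird identical; bird means differ by exactly 6
  d <- data.frame(value = rep(c(500, 500, 500, 506, 506), each = 3),
                  bird_id = rep(sprintf("b%d", 1:5), each = 3),
                  population = rep(c("a", "a", "a", "b", "b"), each = 3))
  f <- fit_lmm(measurement_set(d$value, d$bird_id, d$population))
  expect_equal(f$fixed_effect_estimate, 6, tolerance = 1e-9)
})

test_that("zero bird variance collapses to one-way ANOVA exactly", {
  # bird means identical within population: REML puts var_bird at the
  # boundary and GLS reduces to OLS
  d <- data.frame(value = c(1, 3, 1, 3, 1, 3, 5, 7, 5, 7, 5, 7),
                  bird_id = rep(sprintf("b%d", 1:6), each = 2),
                  population = rep(c("a", "b"), each = 6))
  f <- fit_lmm(measurement_set(d$value, d$bird_id, d$population))
  a <- stats::anova(stats::lm(value ~ population, d))
  expect_true(f$boundary)
  expect_equal(f$var_bird, 0)
  expect_equal(f$F, a$`F value`[1], tolerance = 1e-6)
  expect_equal(f$df_den, a$Df[2])
})

test_that("EMMs equal raw population means in balanced designs", {
  set.seed(8)
  d <- make_measurements(n_birds = c(a = 4, b = 4), cells = 5, delta = 4)
  f <- fit_lmm(measurement_set(d$value, d$bird_id, d$population))
  raw <- tapply(d$value, d$population, mean)
  expect_equal(f$emm$emm, as.numeric(raw[f$emm$population]),
               tolerance = 1e-9)
})

test_that("single population or df rule misuse raises contract errors", {
  d <- make_measurements(n_birds = c(a = 4), cells = 3)
  expect_error(fit_lmm(measurement_set(d$value, d$bird_id, d$population)),
               "two populations")
  d2 <- make_measurements()
  f <- fit_lmm(measurement_set(d2$value, d2$bird_id, d2$population),
               df_method = "containment")
  expect_equal(unname(f$df_den), 10)  # 12 birds - 2 populations
  expect_named(f$df_den_alternatives, c("satterthwaite", "containment"))
})

test_that("ICC hits its boundaries and undefined case", {
  # zero residual noise, dispersed bird means -> icc ~ 1
  d <- data.frame(value = rep(c(1, 5, 9, 13), each = 3),
                  bird_id = rep(sprintf("b%d", 1:4), each = 3),
                  population = "x")
  expect_gt(icc(d)$icc, 0.999)
  # no between-bird signal: bird means exactly equal -> boundary at 0
  d2 <- data.frame(value = rep(c(-1, 1), 6),
                   bird_id = rep(sprintf("b%d", 1:4), each = 3),
                   population = "x")
  r2 <- icc(d2)
  expect_equal(r2$icc, 0)
  expect_true(r2$boundary)
  # all singleton birds: undefined, with a reason
  d3 <- data.frame(value = rnorm(6), bird_id = sprintf("b%d", 1:6),
                   population = "x")
  r3 <- icc(d3)
  expect_true(is.na(r3$icc))
  expect_match(r3$reason, "repeated")
})

test_that("balanced ICC equals the closed-form ANOVA estimator", {
  set.seed(5)
  for (sb in c(1, 2)) {
    d <- make_measurements(n_birds = c(a = 6, b = 6), cells = 8,
                           sd_bird = sb, sd_resid = 1.5)
    r <- icc(d)
    expect_lt(abs(r$icc - oracle_icc_anova(d$value, d$bird_id)), 1e-6)
  }
})

test_that("comparison report covers the types present with counts", {
  set.seed(12)
  cells <- list()
  for (cl in c("rod", "LWS")) for (p in c("a", "b")) for (b in 1:3)
    for (i in 1:4)
      cells[[length(cells) + 1]] <- data.frame(
        cell_id = paste(cl, p, b, i), bird_id = paste0(p, b),
        population = p, pigment_class = cl,
        lambda_max_primary = 500 + (cl == "LWS") * 63 + rnorm(1),
        qc_passed = TRUE, stringsAsFactors = FALSE)
  tab <- do.call(rbind, cells)
  rep <- comparison_report(tab)
  expect_equal(nrow(rep$pigments), 2L)
  expect_equal(rep$pigments$n_a, c(12, 12))
  expect_true(all(is.finite(rep$pigments$F)))
  expect_true(all(is.finite(rep$pigments$icc)))
  # a type failing QC everywhere disappears from the table
  tab2 <- tab
  tab2$qc_passed[tab2$pigment_class == "LWS"] <- FALSE
  expect_equal(nrow(comparison_report(tab2)$pigments), 1L)
})
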