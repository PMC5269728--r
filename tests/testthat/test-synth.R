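test_that("noiseless generation round-trips every latent lambda_max", {
  d <- study_design(n_birds = c(elegans = 2L, flaveolus = 2L))
  d$pigment_classes$sd_bird <- 0
  d$pigment_classes$sd_resid <- 0
  d$pigment_classes$cells_per_bird <- c(2L, 1L, 1L, 1L, 1L)
  d$droplet_classes$per_bird <- 0L
  d$noise_sd_frac <- 0
  d$density_sd <- 0
  st <- generate_study(d, seed = 3)
  cells <- process_records(st$records)
  m <- merge(cells, st$truth_cells, by = "cell_id")
  expect_true(all(abs(m$lambda_max_primary - m$lambda_max_true) < 0.1))
})

test_that("same seed reproduces the study byte for byte", {
  d <- study_design(n_birds = c(elegans = 1L, flaveolus = 1L))
  d$pigment_classes$cells_per_bird <- c(1L, 1L, 0L, 0L, 0L)
  d$droplet_classes$per_bird <- c(1L, 0L, 0L, 0L, 1L)
  s1 <- generate_study(d, seed = 11)
  s2 <- generate_study(d, seed = 11)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth_cells, s2$truth_cells)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_study(s1, dir1)
  write_study(s2, dir2)
  f1 <- list.files(dir1, recursive = TRUE)
  expect_identical(f1, list.files(dir2, recursive = TRUE))
  expect_identical(unname(tools::md5sum(file.path(dir1, f1))),
                   unname(tools::md5sum(file.path(dir2, f1))))
  s3 <- generate_study(d, seed = 12)
  expect_false(identical(s1$records, s3$records))
})

test_that("generated hierarchy matches the design variances", {
  d <- study_design(n_birds = c(a = 60L))
  d$pigment_classes <- d$pigment_classes[d$pigment_classes$class == "rod", ]
  d$pigment_classes$cells_per_bird <- 8L
  d$droplet_classes$per_bird <- 0L
  d$noise_sd_frac <- 0
  st <- generate_study(d, seed = 21)
  tr <- st$truth_cells
  # between-bird variance of bird effects and residual variance around them
  vb <- stats::var(tapply(tr$bird_effect, tr$bird_id, mean))
  vw <- mean(tapply(tr$lambda_max_true - tr$bird_effect, tr$bird_id,
                    stats::var))
  nb <- 60; nw <- nrow(tr) - nb
  expect_gt(vb, 4 * stats::qchisq(0.005, nb - 1) / (nb - 1))
  expect_lt(vb, 4 * stats::qchisq(0.995, nb - 1) / (nb - 1))
  expect_gt(vw, d$pigment_classes$sd_resid^2 *
              stats::qchisq(0.005, nw) / nw)
  expect_lt(vw, d$pigment_classes$sd_resid^2 *
              stats::qchisq(0.995, nw) / nw)
})

test_that("failure fixtures fail exactly their intended criterion", {
  fx <- generate_failures(seed = 1)
  cells <- process_records(fx$records)
  m <- merge(cells, fx$intended, by = "cell_id")
  for (i in seq_len(nrow(m))) {
    if (m$intended_failure[i] == "none") {
      expect_true(m$qc_passed[i], label = m$cell_id[i])
    } else {
      expect_false(m$qc_passed[i], label = m$cell_id[i])
      expect_equal(m$qc_failed[i], m$intended_failure[i],
                   label = m$cell_id[i])
    }
  }
})

test_that("droplet ground truth matches the recovered lambda_cut", {
  d <- study_design(n_birds = c(a = 3L))
  d$pigment_classes$cells_per_bird <- 0L
  d$droplet_classes$per_bird <- c(2L, 2L, 1L, 1L, 1L)
  d$droplet_noise_frac <- 0
  st <- generate_study(d, seed = 5)
  tab <- measure_droplets(st$droplet_records)
  m <- merge(tab, st$truth_droplets, by = "droplet_id")
  keep <- m$droplet_type.x != "T"
  expect_true(all(abs(m$lambda_cut[keep] - m$lambda_cut_true[keep]) < 0.5))
  expect_true(all(is.na(m$lambda_cut[!keep])))
})
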