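sheet <- function(analyte, mode, conc, df = 1) {
  data.frame(sample_id = sprintf("s%02d", seq_along(conc)), analyte = analyte,
             mode = mode, conc = conc, dilution_factor = df)
}

test_that("zero-noise areas follow the measurement model exactly", {
  p <- default_method_parameters()
  cfg <- simulation_config(seed = 1, noise_cv = 0, mz_jitter_ppm = 0,
                           rt_jitter_min = 0)
  a <- "Sulfathiazole"
  i <- match(a, p$analyte)
  concs <- c(5, 50, 250)
  for (mode in c("solvent", "fortified_extract", "matrix_matched")) {
    fac <- switch(mode, solvent = 1,
                  fortified_extract = 1 + p$matrix_effect[i],
                  matrix_matched = (1 + p$matrix_effect[i]) * p$recovery[i])
    got <- simulate_peak_table(cfg, sheet(a, mode, concs))$peaks
    expect_equal(got$area, p$slope[i] * fac * concs, tolerance = 1e-12)
  }
  # dilution reduces the injected concentration
  got <- simulate_peak_table(cfg, sheet(a, "solvent", 1000, df = 10))$peaks
  expect_equal(got$area, p$slope[i] * 100, tolerance = 1e-12)
})

test_that("identical configs regenerate bit-identical tables", {
  cfg <- simulation_config(seed = 99)
  s <- sheet("Trimethoprim", "matrix_matched", c(10, 20, 40))
  expect_identical(simulate_peak_table(cfg, s)$peaks,
                   simulate_peak_table(cfg, s)$peaks)
  camp1 <- simulate_validation_campaign(cfg)
  camp2 <- simulate_validation_campaign(simulation_config(seed = 99))
  expect_identical(camp1$peaks, camp2$peaks)
  camp3 <- simulate_validation_campaign(simulation_config(seed = 100))
  expect_false(identical(camp1$peaks, camp3$peaks))
})

test_that("the pipeline recovers a known recovery fraction (MC oracle)", {
  withr::local_seed(41)
  p <- default_method_parameters()
  p <- p[p$analyte == "Sulfamethazine", ]
  p$recovery <- 0.5
  concs <- rep(c(10, 20, 40), each = 5)
  est <- replicate(200, {
    cfg <- simulation_config(seed = sample.int(2^30, 1), analytes = p,
                             noise_cv = 0.05)
    pt <- simulate_peak_table(cfg, rbind(
      sheet("Sulfamethazine", "matrix_matched", concs),
      sheet("Sulfamethazine", "fortified_extract", concs)))$peaks
    # generator-level estimate: ratio of mean responses at identical levels
    mean(pt$area[pt$mode == "matrix_matched"]) /
      mean(pt$area[pt$mode == "fortified_extract"])
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 3 * mc_se + 1e-4)
})

test_that("simulated chromatograms have the stated peak and area", {
  grid <- seq(0, 2, by = 0.002)
  clean <- simulate_chromatogram(rt = 1, height = 500, width_sd = 0.03,
                                 noise_sd = 0, grid = grid)
  expect_equal(max(clean$intensities), 500)
  expect_equal(clean$times[which.max(clean$intensities)], 1)
  num_area <- sum(clean$intensities) * 0.002
  expect_equal(num_area, 500 * 0.03 * sqrt(2 * pi), tolerance = 0.005)
  expect_error(simulate_chromatogram(1, 500, width_sd = 0.001, noise_sd = 0,
                                     grid = seq(0, 2, 0.1)), "too coarse")
})

test_that("estimate_snr on simulated peaks concentrates (MC oracle)", {
  withr::local_seed(42)
  grid <- seq(0, 2, by = 0.005)
  one_snr <- function(height, noise) {
    ch <- simulate_chromatogram(1, height, 0.02, noise, grid)
    estimate_snr(ch, c(0.9, 1.1), c(0.1, 0.7))
  }
  strong <- replicate(100, one_snr(500, 50))
  expect_gt(mean(strong), 8)
  expect_lt(mean(strong), 12)
  # near the detection limit the window-max apex estimate carries a positive
  # noise-floor bias (expected max order statistic of the window), so the
  # mean sits above the amplitude ratio 3 by up to ~2.5 S/N units
  weak <- replicate(100, one_snr(300, 100))
  expect_gt(mean(weak), 3)
  expect_lt(mean(weak), 5.5)
})

test_that("zero-noise campaigns reproduce the configured truth exactly", {
  p <- default_method_parameters()
  cfg <- simulation_config(seed = 5, noise_cv = 0, mz_jitter_ppm = 0,
                           rt_jitter_min = 0)
  res <- analyze_campaign(simulate_validation_campaign(cfg))
  for (a in p$analyte) {
    i <- match(a, p$analyte)
    r <- res$records[[a]]
    expect_equal(r$recovery$mean_recovery_pct, rep(100 * p$recovery[i], 3),
                 tolerance = 1e-8)
    expect_equal(r$matrix_effect$matrix_effect_pct,
                 rep(100 * p$matrix_effect[i], 3), tolerance = 1e-8)
    expect_equal(unname(r$r_squared), rep(1, 3), tolerance = 1e-12)
    expect_true(all(r$interday$cv == 0))
    expect_equal(r$cc_alpha, r$mrl)       # zero SD collapses CCalpha to MRL
    expect_equal(r$cc_beta, r$mrl)
    expect_equal(r$sensitivity,
                 p$slope[i] * (1 + p$matrix_effect[i]) * p$recovery[i],
                 tolerance = 1e-9)
  }
})

test_that("noisy campaigns keep interday CVs in a realistic band (MC oracle)", {
  withr::local_seed(43)
  cvs <- sapply(1:30, function(i) {
    cfg <- simulation_config(seed = 7000 + i)
    res <- analyze_campaign(simulate_validation_campaign(cfg))
    vapply(res$records, function(r) r$interday$cv, numeric(3))
  })  # 24 interday CVs (8 analytes x 3 levels) per campaign
  med <- apply(matrix(cvs, nrow = 24), 1, median)
  expect_true(all(med > 3 & med < 20))
})

test_that("diluted high-concentration samples quantify near truth", {
  withr::local_seed(44)
  cfg <- simulation_config(seed = 2024)
  camp <- simulate_validation_campaign(cfg)
  res <- analyze_campaign(camp)
  inc <- camp$peaks[camp$peaks$role == "incurred", ]
  a <- cfg$incurred$analyte
  meas <- as.numeric(quantify(inc$area, res$curves[[a]]$matrix_matched,
                              dilution_factor = inc$dilution_factor))
  expect_equal(mean(meas), cfg$incurred$conc, tolerance = 0.15)
})

test_that("the LOD/LOQ scenario crosses at 1.0 and 5.0 ng/g", {
  for (s in c(3, 1234)) {
    sc <- simulate_lod_loq_scenario(s)
    expect_equal(sc$lod, 1.0)
    expect_equal(sc$loq, 5.0)
    expect_lt(sc$snr_table$snr[sc$snr_table$nominal == 0.1], 3)
    expect_gte(sc$snr_table$snr[sc$snr_table$nominal == 1], 3)
    expect_equal(cv_percent(sc$loq_measurements[["5"]]), 18, tolerance = 1e-9)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(), "seed is mandatory")
  p <- default_method_parameters()
  p$recovery[1] <- 1.7
  expect_error(simulation_config(seed = 1, analytes = p), "recovery")
})
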