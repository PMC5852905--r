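test_that("fit_curve recovers exact and hand-derived fits", {
  exact <- fit_curve(data.frame(nominal = c(1, 2, 4), area = c(2, 4, 8)))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 0, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1)
  expect_true(exact$linearity_pass)

  # closed-form normal equations by hand: slope 1/2, intercept 7/6, R2 3/4
  tri <- fit_curve(data.frame(nominal = c(0, 1, 2), area = c(1, 2, 2)))
  expect_equal(tri$slope, 0.5)
  expect_equal(tri$intercept, 7 / 6, tolerance = 1e-12)
  expect_equal(tri$r_squared, 0.75)
  expect_false(tri$linearity_pass)
})

test_that("a curve constructed at R2 = 0.985 fails the linearity gate", {
  # residuals orthogonal to the design give R2 = Sxx / (Sxx + SSres) exactly
  x <- 1:5
  k <- sqrt(10 * (1 / 0.985 - 1) / 4)
  y <- x + k * c(1, -1, 0, -1, 1)
  fit <- fit_curve(data.frame(nominal = x, area = y))
  expect_equal(fit$r_squared, 0.985, tolerance = 1e-12)
  expect_false(fit$linearity_pass)
})

test_that("fit_curve rejects degenerate designs", {
  expect_error(fit_curve(data.frame(nominal = c(1, 2), area = c(1, 2))),
               "at least 3 distinct")
  expect_error(fit_curve(data.frame(nominal = rep(5, 4), area = 1:4)),
               "at least 3 distinct")
})

test_that("fit_curve agrees with the normal-equations oracle", {
  withr::local_seed(11)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    x <- sort(sample(seq(0.5, 300, by = 0.5), n))
    y <- runif(1, 10, 5000) * x + rnorm(n, 0, 50)
    fit <- fit_curve(data.frame(nominal = x, area = y))
    oracle <- ols_oracle(x, y)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    # the intercept's natural scale is the response; compare relative to it
    expect_lt(abs(fit$intercept - oracle$intercept),
              1e-10 * max(abs(y)) + 1e-12)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  }
})

test_that("quantify applies dilution, tissue factor and the clamp rule", {
  cv <- fit_curve(data.frame(nominal = c(10, 50, 100),
                             area = 1000 * c(10, 50, 100)))
  expect_equal(as.numeric(quantify(50000, cv)), 50)
  expect_equal(as.numeric(quantify(50000, cv, dilution_factor = 10)), 500)
  shifted <- fit_curve(data.frame(nominal = c(10, 50, 100),
                                  area = 5000 + 1000 * c(10, 50, 100)))
  low <- quantify(1000, shifted)  # area below intercept
  expect_equal(as.numeric(low), 0)
  expect_true(attr(low, "below_curve"))
  raw <- quantify(1000, shifted, clamp = FALSE)
  expect_lt(as.numeric(raw), 0)
  flat <- fit_curve(data.frame(nominal = c(1, 2, 3), area = c(5, 5, 5)))
  flat$slope <- 0  # force the exactly-singular case past lm's float residue
  expect_error(quantify(10, flat), "slope is zero")
})

test_that("quantify inverts the calibration line for any df, tf", {
  withr::local_seed(12)
  for (i in 1:50) {
    slope <- runif(1, 10, 3000); intercept <- runif(1, -100, 500)
    x <- c(5, 50, 250)
    cv <- fit_curve(data.frame(nominal = x, area = intercept + slope * x))
    conc <- runif(1, 1, 200); df <- sample(1:20, 1); tf <- runif(1, 0.2, 4)
    area <- slope * (conc * tf / df) + intercept
    expect_equal(as.numeric(quantify(area, cv, df, tf)), conc,
                 tolerance = 1e-8)
  }
})

test_that("estimate_snr matches its definition and is shift-invariant", {
  # noise window: median 0, sd k*sqrt(2.5); apex set to 3 sd above -> S/N 3
  k <- 40
  noise <- c(-2, -1, 0, 1, 2) * k
  s <- sd(noise)
  trace <- chromatogram(1:10, c(noise, 0, 0, 3 * s, 0, 0))
  expect_equal(estimate_snr(trace, c(6, 10), c(1, 5)), 3)
  shifted <- chromatogram(1:10, trace$intensities + 12345)
  expect_equal(estimate_snr(shifted, c(6, 10), c(1, 5)), 3)

  flat <- chromatogram(1:10, rep(7, 10))
  expect_error(estimate_snr(flat, c(6, 10), c(1, 5)), "zero noise variance")
  expect_error(estimate_snr(trace, c(4, 10), c(1, 5)), "disjoint")
  expect_error(estimate_snr(trace, c(9, 10), c(1, 5)), "at least 5 points")
})

test_that("assign_lod implements the inclusive S/N >= 3 rule", {
  expect_equal(assign_lod(data.frame(nominal = c(0.5, 1, 5),
                                     snr = c(1.2, 3.4, 17))), 1.0)
  expect_equal(assign_lod(data.frame(nominal = 1, snr = 3)), 1.0)
  expect_warning(got <- assign_lod(data.frame(nominal = c(1, 5),
                                              snr = c(1, 2))), "undefined")
  expect_identical(got, NA_real_)
  expect_error(assign_lod(data.frame(nominal = c(1, 1), snr = c(3, 4))),
               "distinct")
})

test_that("assign_loq implements the inclusive CV <= 20% rule", {
  withr::local_seed(13)
  meas <- list("2.5" = with_moments(5, 2.5, 2.5 * 0.25),
               "5"   = with_moments(5, 5.0, 5.0 * 0.18),
               "12.5" = with_moments(5, 12.5, 12.5 * 0.05))
  expect_equal(assign_loq(meas), 5.0)
  boundary <- list("5" = with_moments(10, 5, 5 * 0.20))
  expect_equal(assign_loq(boundary), 5.0)  # CV exactly 20 qualifies
  expect_warning(got <- assign_loq(list("5" = with_moments(5, 5, 5 * 0.5))),
                 "undefined")
  expect_identical(got, NA_real_)
  expect_error(assign_loq(list("5" = 4.9)), "at least 2")
})
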