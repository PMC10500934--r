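test_that("exponential curves from medians put S(median) = 0.5", {
  for (m in c(6.0, 6.9, 7.7, 11.1, 11.6, 13.8, 14.4, 0.5, 40)) {
    curve <- exponential_from_median(m)
    expect_equal(survival_probability(curve, m), 0.5, tolerance = 1e-12)
    expect_equal(survival_probability(curve, 0), 1.0)
  }
  expect_equal(exponential_from_median(7.7)$rate, 0.090019, tolerance = 1e-5)
  expect_equal(exponential_from_median(11.6)$rate, 0.059754, tolerance = 1e-5)
  expect_error(exponential_from_median(0), "positive")
  expect_error(exponential_from_median(-3), "positive")
})

test_that("survival_probability honours families and rejects negative times", {
  expo <- parametric_survival("exponential", rate = 0.09)
  wei1 <- parametric_survival("weibull", shape = 1, scale = 1 / 0.09)
  for (t in c(0, 0.5, 7.7, 30))
    expect_equal(survival_probability(wei1, t), survival_probability(expo, t),
                 tolerance = 1e-12)
  wei <- parametric_survival("weibull", shape = 1.4, scale = 12)
  tt <- seq(0, 60, by = 0.5)
  s <- survival_probability(wei, tt)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(diff(s) <= 0))
  expect_error(survival_probability(expo, -1), "non-negative")
  expect_error(parametric_survival("exponential", rate = -1), "positive")
  expect_error(parametric_survival("weibull", shape = 0, scale = 2), "positive")
})

test_that("hazard ratios rescale curves under proportional hazards", {
  expo <- parametric_survival("exponential", rate = 0.1)
  expect_equal(apply_hazard_ratio(expo, hazard_ratio(1))$rate, 0.1)
  expect_equal(apply_hazard_ratio(
    parametric_survival("exponential", rate = 0.059754), 0.80)$rate,
    0.047803, tolerance = 1e-5)
  # hr then 1/hr returns the original curve
  for (curve in list(expo, parametric_survival("weibull", shape = 1.3,
                                               scale = 14))) {
    back <- apply_hazard_ratio(apply_hazard_ratio(curve, 0.77), 1 / 0.77)
    for (t in c(1, 5, 20))
      expect_equal(survival_probability(back, t),
                   survival_probability(curve, t), tolerance = 1e-9)
  }
  # S_new = S^hr exactly, and hr < 1 raises survival
  wei <- parametric_survival("weibull", shape = 1.2, scale = 14)
  shifted <- apply_hazard_ratio(wei, 0.77)
  tt <- seq(0.5, 48, by = 0.5)
  expect_equal(survival_probability(shifted, tt),
               survival_probability(wei, tt)^0.77, tolerance = 1e-12)
  expect_true(all(survival_probability(shifted, tt) >=
                    survival_probability(wei, tt)))
  expect_error(apply_hazard_ratio(wei, -0.5), "positive")
})

test_that("KM point sets enforce digitization invariants", {
  t <- 0:10
  s <- exp(-0.1 * t)
  expect_s3_class(km_point_set(t, s), "km_point_set")
  expect_error(km_point_set(t[1:4], s[1:4]), "at least 5")
  expect_error(km_point_set(0, 1), "at least 5")
  expect_error(km_point_set(rev(t), s), "strictly increasing")
  expect_error(km_point_set(t, rev(s)), "non-increasing")
  expect_error(km_point_set(t + 2, s), "anchor")
  expect_error(km_point_set(t, s * 0.9), "anchor")
})

test_that("KM point sets round-trip through the CSV dialect", {
  pts <- km_point_set(0:9, exp(-0.08 * (0:9)), endpoint = "OS",
                      arm = "comparator")
  path <- withr::local_tempfile(fileext = ".csv")
  write_km_points(pts, path)
  back <- read_km_points(path, endpoint = "OS", arm = "comparator")
  expect_equal(back$points, pts$points, tolerance = 1e-12)
  expect_error(read_km_points(tempfile()), "not found")
})

test_that("least-squares fitting recovers noiseless generating parameters", {
  t <- 1:24
  pts <- km_point_set(c(0, t), c(1, exp(-0.09 * t)))
  fit <- fit_km_curve(pts, "exponential")
  expect_equal(fit$rate, 0.09, tolerance = 1e-6)
  expect_lt(attr(fit, "rss"), 1e-10)

  wei <- parametric_survival("weibull", shape = 1.2, scale = 14)
  tt <- seq(0, 40, length.out = 30)
  wpts <- km_point_set(tt, survival_probability(wei, tt))
  wfit <- fit_km_curve(wpts, "weibull")
  expect_equal(wfit$shape, 1.2, tolerance = 1e-4)
  expect_equal(wfit$scale, 14, tolerance = 1e-4)
})

test_that("Weibull fitting recovers parameters from noisy digitized points", {
  wei <- parametric_survival("weibull", shape = 1.2, scale = 14)
  pts <- generate_km_points(wei, n_points = 30, noise_sd = 0.01, seed = 11)
  fit <- fit_km_curve(pts, "weibull")
  expect_lt(abs(fit$shape / 1.2 - 1), 0.05)
  expect_lt(abs(fit$scale / 14 - 1), 0.05)
})

test_that("arm validation orders OS above PFS and names the crossing time", {
  arm <- validate_arm(exponential_from_median(7.7),
                      exponential_from_median(13.8))
  grid <- build_time_grid(model_settings())
  expect_true(all(survival_probability(arm$os, grid$cycle_mids) -
                    survival_probability(arm$pfs, grid$cycle_mids) >= -1e-9))
  expect_error(validate_arm(exponential_from_median(10),
                            exponential_from_median(8)),
               "curve crossing.*t = ")
  # identical curves are a valid boundary: PD occupancy identically zero
  same <- validate_arm(exponential_from_median(9), exponential_from_median(9))
  trace <- compute_trace(same, grid)
  expect_equal(max(abs(trace$pd)), 0)
})
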