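test_that("gamma method-of-moments round-trips the base and range", {
  p <- gamma_params_from_range(1342.11, 1073.69, 1610.53)
  expect_equal(unname(p["shape"]), 96.04, tolerance = 1e-4)
  expect_equal(unname(p["scale"]), 13.974, tolerance = 1e-3)
  # every +/-20% parameter has shape 96.04 exactly, whatever the base
  for (base in c(0.5, 117, 5937, 98942.56)) {
    q <- gamma_params_from_range(base, 0.8 * base, 1.2 * base)
    expect_equal(unname(q["shape"]), 96.04, tolerance = 1e-12)
    expect_equal(unname(q["shape"] * q["scale"]), base, tolerance = 1e-9)
    expect_equal(unname(sqrt(q["shape"]) * q["scale"]), 0.4 * base / 3.92,
                 tolerance = 1e-6)
  }
  expect_error(gamma_params_from_range(10, 12, 15), "low <= base <= high")
})

test_that("beta method-of-moments matches hand calculation and its bound", {
  p <- beta_params_from_range(0.797, 0.638, 0.956)
  expect_equal(unname(p["alpha"]), 18.79737, tolerance = 1e-4)
  expect_equal(unname(p["beta"]), 4.78782, tolerance = 1e-4)
  for (base in c(0.06, 0.15, 0.577, 0.797)) {
    q <- beta_params_from_range(base, 0.8 * base, min(1.2 * base, 1))
    m <- q["alpha"] / (q["alpha"] + q["beta"])
    v <- q["alpha"] * q["beta"] /
      ((q["alpha"] + q["beta"])^2 * (q["alpha"] + q["beta"] + 1))
    expect_equal(unname(m), base, tolerance = 1e-9)
    expect_equal(unname(sqrt(v)), (min(1.2 * base, 1) - 0.8 * base) / 3.92,
                 tolerance = 1e-6)
  }
  expect_error(beta_params_from_range(0.01, 0, 1), "infeasible moments")
  expect_error(beta_params_from_range(1.4, 0.2, 1), "in \\[0, 1\\]")
})

test_that("parameter specs validate their ranges and families", {
  expect_s3_class(param_spec("x", "utilities.u_pfs", 0.797, family = "beta"),
                  "param_spec")
  expect_error(param_spec("x", "t", base = 1, low = 2, high = 3),
               "low <= base <= high")
  expect_error(param_spec("x", "t", base = 2, family = "beta"),
               "inside \\[0, 1\\]")
})

test_that("one-way analysis brackets the base case and ranks by span", {
  cfg <- default_config("China")
  base_icer <- run_pipeline(cfg)$comparison$icer
  specs <- list(
    nivo = param_spec("Cost of nivolumab", "drug_price_multiplier.nivolumab",
                      base = 1, family = "gamma"),
    u_pfs = param_spec("Utility of PFS state", "utilities.u_pfs", 0.797,
                       0.638, 0.956, family = "beta"),
    frozen = param_spec("frozen", "unit_cost.ct_scan", 289.73, 289.73, 289.73,
                        family = "fixed"))
  tor <- owsa(cfg, specs)
  # a degenerate low = high = base parameter has span 0, ranked last,
  # and reproduces the base-case ICER exactly
  expect_identical(tor$parameter[3], "frozen")
  expect_equal(tor$span[3], 0)
  expect_equal(tor$icer_low[3], base_icer, tolerance = 1e-12)
  expect_equal(attr(tor, "icer_base"), base_icer)
  # ICER falls when the PFS utility rises
  u_row <- tor[tor$parameter == "Utility of PFS state", ]
  expect_lt(u_row$icer_high, u_row$icer_low)
  expect_true(all(diff(tor$span) <= 0))
  # unknown config paths are configuration errors
  bad <- list(param_spec("bad", "nonsense.path", 1, family = "gamma"))
  expect_error(owsa(cfg, bad), "unknown parameter target")
})

test_that("PSA draws are reproducible and match their distribution moments", {
  specs <- list(
    price = param_spec("price", "unit_cost.ct_scan", 289.73, family = "gamma"),
    u = param_spec("u", "utilities.u_pfs", 0.797, 0.638, 0.956,
                   family = "beta"))
  d1 <- sample_psa(specs, 500, seed = 99)
  d2 <- sample_psa(specs, 500, seed = 99)
  expect_identical(d1, d2)
  expect_false(identical(d1, sample_psa(specs, 500, seed = 100)))
  big <- sample_psa(specs, 10000, seed = 7)
  sd_price <- 0.4 * 289.73 / 3.92
  expect_lt(abs(mean(big$price) - 289.73), 2 * sd_price / sqrt(10000))
  expect_true(all(big$u >= 0 & big$u <= 1))
  expect_error(sample_psa(specs, 0, seed = 1), "at least 1")
})

test_that("PSA runs are bitwise reproducible under the seed", {
  cfg <- default_config("China")
  r1 <- run_psa(cfg, n = 50, seed = 12345)
  r2 <- run_psa(cfg, n = 50, seed = 12345)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$prob_cost_effective, r2$prob_cost_effective)
})

test_that("PSA means converge to the base case (model nearly linear)", {
  cfg <- default_config("US")
  base <- run_pipeline(cfg)$comparison
  res <- run_psa(cfg, n = 400, seed = 2024)
  se_c <- sd(res$draws$delta_cost) / sqrt(400)
  se_e <- sd(res$draws$delta_qaly) / sqrt(400)
  expect_lt(abs(mean(res$draws$delta_cost) - base$delta_cost), 3 * se_c)
  expect_lt(abs(mean(res$draws$delta_qaly) - base$delta_effect), 3 * se_e)
})

test_that("the acceptability curve is monotone with its limits", {
  cfg <- default_config("China")
  res <- run_psa(cfg, n = 100, seed = 5)
  expect_true(all(res$draws$delta_qaly > 0))
  grid <- c(0, 37653, 1e5, 1e6, 1e8)
  ceac <- ceac_curve(res, grid)
  expect_true(all(diff(ceac$probability) >= 0))
  expect_equal(ceac$probability[ceac$wtp == 0],
               mean(res$draws$delta_cost < 0))
  expect_equal(ceac$probability[ceac$wtp == 1e8], 1)
})
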