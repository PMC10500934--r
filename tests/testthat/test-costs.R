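test_that("BSA dosing is a plain product", {
  expect_equal(dose_from_bsa(130, 1.72), 223.6)
  expect_equal(dose_from_bsa(1000, 2.1), 2100)
  expect_equal(dose_from_bsa(42, 1), 42)
  expect_error(dose_from_bsa(-1, 1.72), "positive")
})

test_that("vial rounding finds the cheapest covering combination", {
  china <- price_table("China")$drugs$nivolumab$units
  us <- price_table("US")$drugs$nivolumab$units
  expect_equal(cheapest_vial_cost(360, china), 5345.82)  # 2x100 + 4x40
  expect_equal(cheapest_vial_cost(360, us), 11844.80)
  expect_equal(cheapest_vial_cost(100, data.frame(size_mg = 100, price = 77)),
               77)
  expect_error(cheapest_vial_cost(100, data.frame()), "empty vial list")
  expect_error(cheapest_vial_cost(0, china), "positive")
})

test_that("vial rounding equals brute-force search on random instances", {
  set.seed(401)
  sizes_pool <- c(20, 30, 40, 50, 100, 250, 500)
  for (i in 1:200) {
    k <- sample(1:3, 1)
    vials <- data.frame(size_mg = sample(sizes_pool, k),
                        price = round(runif(k, 1, 400), 2))
    dose <- runif(1, 5, 900)
    expect_equal(cheapest_vial_cost(dose, vials), brute_vial_cost(dose, vials))
  }
})

test_that("regimen cycle costs reproduce hand microcosting", {
  chn <- model_settings("China")
  usa <- model_settings("US")
  pc <- price_table("China")
  pu <- price_table("US")
  # XELOX China, BSA 1.72: oxaliplatin 223.6 mg -> 5 x 50 mg vials = 822.50;
  # capecitabine 1720 mg/dose -> 4 tablets x 28 administrations = 197.12
  expect_equal(regimen_cycle_cost(builtin_regimen("XELOX", chn), pc, chn),
               1019.62, tolerance = 1e-9)
  expect_equal(regimen_cycle_cost(builtin_regimen("nivolumab", chn), pc, chn),
               5345.82)
  # a 14-day regimen is scaled by 21/14 = 1.5 to the model cycle
  comp <- list(regimen_component("oxaliplatin", 85, "mg_m2"))
  r14 <- regimen("q2w", comp, cycle_days = 14)
  r21 <- regimen("q3w", comp, cycle_days = 21)
  expect_equal(regimen_cycle_cost(r14, pu, usa),
               1.5 * regimen_cycle_cost(r21, pu, usa))
  missing <- regimen("x", list(regimen_component("sorafenib", 400, "mg")), 21)
  expect_error(regimen_cycle_cost(missing, pc, chn), "sorafenib")
})

test_that("adverse-event burden is the incidence-weighted one-off cost", {
  pc <- price_table("China")
  prof <- ae_profile()
  expect_equal(ae_one_off_cost(prof, "intervention", pc), 159.18,
               tolerance = 1e-3)
  expect_equal(ae_one_off_cost(prof, "comparator", pc), 113.92,
               tolerance = 1e-3)
  none <- prof
  none$incidence_intervention[] <- 0
  expect_equal(ae_one_off_cost(none, "intervention", pc), 0)
})

test_that("cost streams respect the nivolumab cap and arm structure", {
  settings <- model_settings("China")
  prices <- price_table("China")
  int <- build_cost_streams("intervention", settings, prices)
  comp <- build_cost_streams("comparator", settings, prices)
  expect_identical(settings$nivo_max_cycles, 35L)
  # comparator never pays for nivolumab; its PFS stream is flat
  expect_equal(length(unique(comp$pfs_per_cycle)), 1L)
  # nivolumab is additive during the capped window only
  nivo_cost <- regimen_cycle_cost(builtin_regimen("nivolumab", settings),
                                  prices, settings)
  expect_equal(int$pfs_per_cycle[1:35], comp$pfs_per_cycle[1:35] + nivo_cost)
  expect_equal(int$pfs_per_cycle[36:174], comp$pfs_per_cycle[36:174])
  expect_equal(length(unique(int$pfs_per_cycle[36:174])), 1L)
  expect_true(all(int$pfs_per_cycle >= comp$pfs_per_cycle))
  # default China PD cycle: supportive care + follow-up + laboratory tests
  expect_equal(comp$pd_per_cycle, 117 + 51.5 + 28.99)
  expect_true(all(c(int$one_off, comp$one_off) >= 0))
})

test_that("cost streams are linear in prices", {
  settings <- model_settings("US")
  prices <- price_table("US")
  doubled <- gastricCEA:::scale_price_table(prices, 2)
  s1 <- build_cost_streams("intervention", settings, prices)
  s2 <- build_cost_streams("intervention", settings, doubled)
  expect_equal(s2$pfs_per_cycle, 2 * s1$pfs_per_cycle)
  expect_equal(s2$pd_per_cycle, 2 * s1$pd_per_cycle)
  expect_equal(s2$one_off, 2 * s1$one_off)
})

test_that("a configured post-progression regimen adds to the PD stream", {
  settings <- model_settings("US")
  prices <- price_table("US")
  doce <- regimen("pd_docetaxel",
                  list(regimen_component("docetaxel", 75, "mg_m2")),
                  cycle_days = 21)
  base <- build_cost_streams("comparator", settings, prices)
  with_pd <- build_cost_streams("comparator", settings, prices,
                                pd_regimen = doce)
  expect_equal(with_pd$pd_per_cycle - base$pd_per_cycle,
               regimen_cycle_cost(doce, prices, settings))
  expect_equal(with_pd$pfs_per_cycle, base$pfs_per_cycle)
})

test_that("cost stream CSV export has the documented columns", {
  settings <- model_settings("China")
  streams <- build_cost_streams("intervention", settings, price_table("China"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cost_streams_csv(streams, path)
  df <- read.csv(path)
  expect_named(df, c("cycle", "pfs_cost", "pd_cost"))
  expect_equal(nrow(df), 174)
})
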