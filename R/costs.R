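#' Country price table
#'
#' Unit prices of drugs (per vial or tablet), monitoring items and
#' adverse-event management, for the Chinese setting (national drug prices /
#' hospital estimates) or the US setting (wholesale acquisition costs plus
#' fee-schedule unit costs). All entries carry a +/-20% uncertainty range and
#' a Gamma distribution tag for sensitivity analysis.
#'
#' @param setting `"China"` or `"US"`.
#' @return An object of class `price_table` with elements `drugs` (each a
#'   data frame `size_mg`, `price` plus a `form` of `"vial"` or `"tablet"`),
#'   `unit_costs` and `ae_costs`.
#' @examples
#' price_table("China")$drugs$nivolumab
#' @export
price_table <- function(setting = c("China", "US")) {
  setting <- match.arg(setting)
  drug <- function(sizes, prices, form = "vial")
    list(form = form, units = data.frame(size_mg = sizes, price = prices))
  if (setting == "China") {
    drugs <- list(
      nivolumab     = drug(c(100, 40), c(1342.11, 665.40)),
      oxaliplatin   = drug(50, 164.50),
      capecitabine  = drug(500, 1.76, form = "tablet"),
      fluorouracil  = drug(250, 7.61),
      leucovorin    = drug(100, 2.22),
      paclitaxel    = drug(30, 59.25),
      docetaxel     = drug(20, 162.18),
      carboplatin   = drug(50, 4.40),
      cisplatin     = drug(30, 2.78),
      pembrolizumab = drug(100, 2596.96),
      toripalimab   = drug(2400, 304.51),
      atezolizumab  = drug(1200, 4753.90),
      ipilimumab    = drug(50, 4058.21))
    unit_costs <- c(laboratory_tests = 28.99, ct_scan = 289.73,
                    supportive_care_per_cycle = 117, follow_up_per_unit = 51.5)
    ae_costs <- c(anemia = 508.2, neutropenia = 466,
                  neutrophil_count_decreased = 534.4)
  } else {
    drugs <- list(
      nivolumab     = drug(c(100, 40), c(3290.22, 1316.09)),
      oxaliplatin   = drug(50, 98.88),
      capecitabine  = drug(500, 37.71, form = "tablet"),
      fluorouracil  = drug(250, 59.85),
      leucovorin    = drug(100, 22.80),
      paclitaxel    = drug(30, 20.16),
      docetaxel     = drug(20, 211.14),
      carboplatin   = drug(50, 12.29),
      cisplatin     = drug(30, 21.20),
      ramucirumab   = drug(100, 1427.58),
      pembrolizumab = drug(100, 5834.45),
      atezolizumab  = drug(1200, 11032.84),
      ipilimumab    = drug(50, 9273.77))
    unit_costs <- c(laboratory_tests = 315, ct_scan = 231,
                    supportive_care_per_cycle = 3049, follow_up_per_unit = 422)
    ae_costs <- c(anemia = 4368, neutropenia = 5937,
                  neutrophil_count_decreased = 5937)
  }
  structure(list(setting = setting, drugs = drugs, unit_costs = unit_costs,
                 ae_costs = ae_costs),
            class = "price_table")
}

#' Scale all monetary entries of a price table
#'
#' Used by the sensitivity module; scaling every price by `c` scales every
#' cost stream by `c` (the cost engine is linear in prices).
#'
#' @param prices A `price_table`.
#' @param factor Positive multiplier.
#' @return A new `price_table`.
#' @keywords internal
scale_price_table <- function(prices, factor) {
  stopifnot(inherits(prices, "price_table"), factor >= 0)
  prices$drugs <- lapply(prices$drugs, function(d) {
    d$units$price <- d$units$price * factor
    d
  })
  prices$unit_costs <- prices$unit_costs * factor
  prices$ae_costs <- prices$ae_costs * factor
  prices
}

#' Body-surface-area dose
#'
#' @param dose_per_m2 Dose intensity in mg/m^2.
#' @param bsa Body surface area in m^2.
#' @return Dose in mg, unrounded.
#' @examples
#' dose_from_bsa(130, 1.72) # oxaliplatin, Chinese mean BSA
#' @export
dose_from_bsa <- function(dose_per_m2, bsa) {
  if (!is.finite(dose_per_m2) || dose_per_m2 <= 0 || !is.finite(bsa) || bsa <= 0)
    stop("invalid parameter: dose and BSA must be positive", call. = FALSE)
  dose_per_m2 * bsa
}

#' Cheapest vial combination covering a dose
#'
#' Drug vials cannot be shared between patients, so a computed dose is
#' rounded up to the cheapest combination of whole vials whose total
#' milligrams cover it. The search enumerates every covering combination with
#' at most `ceiling(dose / size_i)` vials of each size.
#'
#' @param dose Dose in mg, positive.
#' @param vials Data frame with columns `size_mg` and `price`.
#' @return Minimum total price over covering combinations.
#' @examples
#' cheapest_vial_cost(360, data.frame(size_mg = c(100, 40),
#'                                    price = c(1342.11, 665.40)))
#' @export
cheapest_vial_cost <- function(dose, vials) {
  if (is.null(vials) || nrow(vials) == 0L)
    stop("configuration error: empty vial list", call. = FALSE)
  if (!is.finite(dose) || dose <= 0)
    stop("invalid parameter: 'dose' must be positive", call. = FALSE)
  counts <- lapply(vials$size_mg, function(s) 0:ceiling(dose / s))
  combos <- as.matrix(expand.grid(counts))
  mg <- combos %*% vials$size_mg
  cost <- combos %*% vials$price
  min(cost[mg >= dose])
}

#' One treatment-regimen component
#'
#' @param drug Drug name matching a `price_table` entry.
#' @param dose Dose per administration.
#' @param dose_unit `"mg_m2"` (scaled by BSA) or `"mg"` (flat).
#' @param n_admin Administrations per underlying regimen cycle.
#' @return A list describing the component.
#' @export
regimen_component <- function(drug, dose, dose_unit = c("mg_m2", "mg"),
                              n_admin = 1) {
  dose_unit <- match.arg(dose_unit)
  if (!is.finite(dose) || dose <= 0)
    stop("invalid parameter: component dose must be positive", call. = FALSE)
  if (!is.finite(n_admin) || n_admin < 1)
    stop("invalid parameter: 'n_admin' must be at least 1", call. = FALSE)
  list(drug = drug, dose = dose, dose_unit = dose_unit, n_admin = n_admin)
}

#' Treatment regimen
#'
#' @param name Regimen label.
#' @param components List of [regimen_component()]s.
#' @param cycle_days Underlying cycle length of the regimen in days.
#' @param max_model_cycles Optional cap on the number of 21-day model cycles
#'   during which the regimen is given (nivolumab's 2-year rule).
#' @return An object of class `regimen`.
#' @export
regimen <- function(name, components, cycle_days, max_model_cycles = NULL) {
  if (!is.finite(cycle_days) || cycle_days <= 0)
    stop("invalid parameter: regimen cycle length must be positive",
         call. = FALSE)
  structure(list(name = name, components = components, cycle_days = cycle_days,
                 max_model_cycles = max_model_cycles), class = "regimen")
}

#' Built-in regimens
#'
#' Dosing as administered in the underlying trial: XELOX (capecitabine
#' 1000 mg/m^2 twice daily on days 1-14 plus oxaliplatin 130 mg/m^2 on day 1,
#' every 3 weeks), FOLFOX (leucovorin 400 mg/m^2, fluorouracil 400 mg/m^2
#' bolus then 1200 mg/m^2 on days 1-2, oxaliplatin 85 mg/m^2, every 2 weeks)
#' and nivolumab 360 mg every 3 weeks for at most 2 years.
#'
#' @param name `"XELOX"`, `"FOLFOX"` or `"nivolumab"`.
#' @param settings A [model_settings()]; supplies the nivolumab cycle cap.
#' @return A [regimen()].
#' @export
builtin_regimen <- function(name = c("XELOX", "FOLFOX", "nivolumab"),
                            settings = model_settings()) {
  name <- match.arg(name)
  switch(name,
    XELOX = regimen("XELOX", list(
      regimen_component("capecitabine", 1000, "mg_m2", n_admin = 28),
      regimen_component("oxaliplatin", 130, "mg_m2", n_admin = 1)),
      cycle_days = 21),
    FOLFOX = regimen("FOLFOX", list(
      regimen_component("leucovorin", 400, "mg_m2", n_admin = 1),
      regimen_component("fluorouracil", 400, "mg_m2", n_admin = 1),
      regimen_component("fluorouracil", 1200, "mg_m2", n_admin = 2),
      regimen_component("oxaliplatin", 85, "mg_m2", n_admin = 1)),
      cycle_days = 14),
    nivolumab = regimen("nivolumab", list(
      regimen_component("nivolumab", 360, "mg", n_admin = 1)),
      cycle_days = 21, max_model_cycles = settings$nivo_max_cycles))
}

#' Drug cost of one regimen per 21-day model cycle
#'
#' Per administration, mg/m^2 doses are scaled by the setting's mean BSA;
#' intravenous drugs are rounded up to the cheapest covering vial combination
#' and oral drugs to whole tablets. The per-underlying-cycle total is then
#' normalised to the model cycle by the factor
#' `model cycle days / regimen cycle days`.
#'
#' @param regimen A [regimen()].
#' @param prices A [price_table()].
#' @param settings A [model_settings()].
#' @return Cost per model cycle.
#' @examples
#' regimen_cycle_cost(builtin_regimen("XELOX"), price_table("China"),
#'                    model_settings("China"))
#' @export
regimen_cycle_cost <- function(regimen, prices, settings) {
  stopifnot(inherits(regimen, "regimen"), inherits(prices, "price_table"),
            inherits(settings, "model_settings"))
  per_cycle <- 0
  for (comp in regimen$components) {
    entry <- prices$drugs[[comp$drug]]
    if (is.null(entry))
      stop("configuration error: no price for drug '", comp$drug,
           "' in the ", prices$setting, " price table", call. = FALSE)
    dose <- if (comp$dose_unit == "mg_m2")
      dose_from_bsa(comp$dose, settings$bsa) else comp$dose
    admin_cost <- if (entry$form == "tablet")
      ceiling(dose / entry$units$size_mg[1L]) * entry$units$price[1L]
    else
      cheapest_vial_cost(dose, entry$units)
    per_cycle <- per_cycle + admin_cost * comp$n_admin
  }
  per_cycle * settings$cycle_days / regimen$cycle_days
}

#' Grade 3-4 adverse-event profile
#'
#' Trial incidences of grade 3-4 treatment-related adverse events by arm.
#' Only events with a priced management entry in the country price table
#' (anemia, neutropenia, decreased neutrophil count) contribute to cost;
#' the rest are carried for completeness and contribute zero.
#'
#' @return A data frame with columns `name`, `incidence_intervention`,
#'   `incidence_comparator`.
#' @export
ae_profile <- function() {
  data.frame(
    name = c("nausea", "diarrhea", "peripheral_neuropathy", "vomiting",
             "fatigue", "anemia", "decreased_appetite", "thrombocytopenia",
             "platelet_count_decreased", "peripheral_sensory_neuropathy",
             "ast_increased", "wbc_count_decreased", "alt_increased",
             "palmar_plantar_erythrodysesthesia",
             "neutrophil_count_decreased", "neutropenia", "asthenia",
             "lipase_increased"),
    incidence_intervention = c(0.03, 0.04, 0.04, 0.02, 0.04, 0.06, 0.02,
                               0.02, 0.03, 0.02, 0.02, 0.03, 0.01, 0.01,
                               0.11, 0.15, 0.01, 0.06),
    incidence_comparator = c(0.02, 0.03, 0.03, 0.03, 0.02, 0.03, 0.02, 0.02,
                             0.02, 0.02, 0.01, 0.02, 0.01, 0.01, 0.08, 0.12,
                             0.01, 0.02))
}

#' One-off adverse-event management cost at model entry
#'
#' Expected cost `sum(incidence * management cost)` over the adverse events
#' with a priced management entry, charged once when the cohort enters the
#' model.
#'
#' @param profile An [ae_profile()] data frame.
#' @param arm `"intervention"` or `"comparator"`.
#' @param prices A [price_table()].
#' @return Expected one-off cost.
#' @examples
#' ae_one_off_cost(ae_profile(), "intervention", price_table("China"))
#' @export
ae_one_off_cost <- function(profile, arm = c("intervention", "comparator"),
                            prices) {
  arm <- match.arg(arm)
  stopifnot(inherits(prices, "price_table"))
  inc <- if (arm == "intervention") profile$incidence_intervention
         else profile$incidence_comparator
  if (any(inc < 0 | inc > 1))
    stop("invalid parameter: AE incidences must be in [0, 1]", call. = FALSE)
  priced <- match(profile$name, names(prices$ae_costs))
  sum(inc[!is.na(priced)] * prices$ae_costs[priced[!is.na(priced)]])
}

#' Per-cycle cost streams for one arm
#'
#' Progression-free patients receive the chemotherapy backbone (plus
#' nivolumab below the 2-year cycle cap, intervention arm only), laboratory
#' tests and a follow-up visit every cycle and a CT scan every second cycle
#' (amortised as half a scan per cycle). Progressed patients receive best
#' supportive care, follow-up and laboratory tests, plus an optional
#' configured post-progression regimen. Adverse-event management is a one-off
#' expected cost at entry.
#'
#' @param arm `"intervention"` or `"comparator"`.
#' @param settings A [model_settings()].
#' @param prices A [price_table()].
#' @param backbone Chemotherapy backbone [regimen()] (default XELOX).
#' @param nivo Nivolumab [regimen()] (used for the intervention arm).
#' @param pd_regimen Optional [regimen()] given in the progressed state.
#' @param profile Adverse-event profile, default [ae_profile()].
#' @return An object of class `cost_streams`: `one_off`, `pfs_per_cycle`
#'   (length `n_cycles`), `pd_per_cycle` (scalar).
#' @export
build_cost_streams <- function(arm = c("intervention", "comparator"),
                               settings, prices,
                               backbone = builtin_regimen("XELOX", settings),
                               nivo = builtin_regimen("nivolumab", settings),
                               pd_regimen = NULL,
                               profile = ae_profile()) {
  arm <- match.arg(arm)
  stopifnot(inherits(settings, "model_settings"), inherits(prices, "price_table"))
  grid <- build_time_grid(settings)
  uc <- prices$unit_costs
  monitoring <- uc[["laboratory_tests"]] + uc[["follow_up_per_unit"]] +
    uc[["ct_scan"]] / 2
  pfs <- rep(regimen_cycle_cost(backbone, prices, settings) + monitoring,
             grid$n_cycles)
  if (arm == "intervention") {
    cap <- if (is.null(nivo$max_model_cycles)) grid$n_cycles
           else min(nivo$max_model_cycles, grid$n_cycles)
    nivo_cost <- regimen_cycle_cost(nivo, prices, settings)
    if (cap > 0) pfs[seq_len(cap)] <- pfs[seq_len(cap)] + nivo_cost
  }
  pd <- uc[["supportive_care_per_cycle"]] + uc[["follow_up_per_unit"]] +
    uc[["laboratory_tests"]]
  if (!is.null(pd_regimen))
    pd <- pd + regimen_cycle_cost(pd_regimen, prices, settings)
  structure(list(one_off = ae_one_off_cost(profile, arm, prices),
                 pfs_per_cycle = pfs, pd_per_cycle = pd,
                 n_cycles = grid$n_cycles),
            class = "cost_streams")
}

#' Export cost streams to CSV
#'
#' Columns: `cycle,pfs_cost,pd_cost`.
#'
#' @param streams A `cost_streams`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cost_streams_csv <- function(streams, path) {
  stopifnot(inherits(streams, "cost_streams"))
  utils::write.csv(
    data.frame(cycle = seq_len(streams$n_cycles) - 1L,
               pfs_cost = streams$pfs_per_cycle,
               pd_cost = streams$pd_per_cycle),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
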