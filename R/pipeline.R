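#' Default run configuration
#'
#' A complete, declarative description of one analysis: country setting,
#' population, survival inputs (medians and hazard ratios, or digitized KM
#' coordinate files), regimen choices, utilities, uncertain-parameter
#' overrides and PSA settings. The four shipped presets are
#' `{China, US} x {all_randomized, cps5}`.
#'
#' Survival medians and hazard ratios by population (months): all randomized
#' patients — comparator PFS 6.9, OS 11.6; intervention PFS 7.7, OS 13.8;
#' HR 0.77 (PFS) and 0.80 (OS). PD-L1 CPS >= 5 — comparator PFS 6.0, OS 11.1;
#' intervention PFS 7.7, OS 14.4; HR 0.68 (PFS) and 0.71 (OS). The base case
#' builds the comparator arm from its own medians and the intervention arm by
#' applying the hazard ratios to the comparator curves
#' (`intervention_source = "hazard_ratio"`); `"medians"` uses the
#' intervention's own printed medians instead.
#'
#' @param setting `"China"` or `"US"`.
#' @param population `"all_randomized"` or `"cps5"`.
#' @param intervention_source `"hazard_ratio"` (default) or `"medians"`.
#' @param backbone `"XELOX"` (default) or `"FOLFOX"`.
#' @return A nested list of class `cea_config`.
#' @examples
#' cfg <- default_config("US", "all_randomized")
#' cfg$model$wtp
#' @export
default_config <- function(setting = c("China", "US"),
                           population = c("all_randomized", "cps5"),
                           intervention_source = c("hazard_ratio", "medians"),
                           backbone = c("XELOX", "FOLFOX")) {
  setting <- match.arg(setting)
  population <- match.arg(population)
  intervention_source <- match.arg(intervention_source)
  backbone <- match.arg(backbone)
  surv <- if (population == "all_randomized") {
    list(comparator = list(pfs_median = 6.9, os_median = 11.6),
         intervention = list(pfs_median = 7.7, os_median = 13.8),
         hr = list(pfs = 0.77, os = 0.80))
  } else {
    list(comparator = list(pfs_median = 6.0, os_median = 11.1),
         intervention = list(pfs_median = 7.7, os_median = 14.4),
         hr = list(pfs = 0.68, os = 0.71))
  }
  surv$source <- "medians"
  surv$intervention_source <- intervention_source
  surv$family <- "exponential"
  surv$km_files <- NULL
  structure(list(
    setting = setting,
    population = population,
    model = list(cycle_days = 21, horizon_years = 10, annual_discount = 0.03,
                 wtp = c(China = 37653, US = 1e5)[[setting]],
                 bsa = c(China = 1.72, US = 2.10)[[setting]],
                 nivo_max_years = 2),
    survival = surv,
    regimens = list(backbone = backbone, pd_regimen = NULL),
    utilities = list(u_pfs = 0.797, u_pd = 0.577),
    ae_incidence = list(
      intervention = list(anemia = 0.06, neutropenia = 0.15,
                          neutrophil_count_decreased = 0.11),
      comparator = list(anemia = 0.03, neutropenia = 0.12,
                        neutrophil_count_decreased = 0.08)),
    overrides = list(drug_price_multiplier = list(), unit_cost = list(),
                     ae_cost = list()),
    psa = list(n = 1000, seed = 20230913)
  ), class = "cea_config")
}

#' Validate a run configuration
#'
#' Checks the whole configuration and reports every violation found, not just
#' the first.
#'
#' @param config A configuration list.
#' @return The validated config (classed `cea_config`), or an error listing
#'   all violations.
#' @export
validate_config <- function(config) {
  bad <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  chk(is.list(config), "config must be a list")
  chk(isTRUE(config$setting %in% c("China", "US")),
      "setting: must be 'China' or 'US'")
  chk(isTRUE(config$population %in% c("all_randomized", "cps5")),
      "population: must be 'all_randomized' or 'cps5'")
  m <- config$model
  chk(isTRUE(is.numeric(m$cycle_days) && m$cycle_days > 0),
      "model.cycle_days: must be positive")
  chk(isTRUE(is.numeric(m$horizon_years) && m$horizon_years > 0),
      "model.horizon_years: must be positive")
  chk(isTRUE(is.numeric(m$annual_discount) && m$annual_discount >= 0 &&
               m$annual_discount < 1),
      "model.annual_discount: must be in [0, 1)")
  chk(isTRUE(is.numeric(m$wtp) && m$wtp > 0), "model.wtp: must be positive")
  chk(isTRUE(is.numeric(m$bsa) && m$bsa > 0), "model.bsa: must be positive")
  s <- config$survival
  chk(isTRUE(s$source %in% c("medians", "km_files")),
      "survival.source: must be 'medians' or 'km_files'")
  chk(isTRUE(s$family %in% c("exponential", "weibull")),
      "survival.family: must be 'exponential' or 'weibull'")
  if (isTRUE(s$source == "medians")) {
    for (arm in c("comparator", "intervention")) {
      a <- s[[arm]]
      ok <- is.numeric(a$pfs_median) && is.numeric(a$os_median) &&
        a$pfs_median > 0 && a$os_median > 0
      chk(isTRUE(ok), paste0("survival.", arm, ": medians must be positive"))
      if (isTRUE(ok))
        chk(a$pfs_median <= a$os_median,
            paste0("survival.", arm, ": PFS median exceeds OS median"))
    }
    chk(isTRUE(is.numeric(s$hr$pfs) && s$hr$pfs > 0 &&
                 is.numeric(s$hr$os) && s$hr$os > 0),
        "survival.hr: hazard ratios must be positive")
  } else {
    need <- c("intervention_pfs", "intervention_os", "comparator_pfs",
              "comparator_os")
    for (k in need) {
      f <- s$km_files[[k]]
      chk(isTRUE(is.character(f) && file.exists(f)),
          paste0("survival.km_files.", k, ": file missing"))
    }
  }
  u <- config$utilities
  ok_u <- is.numeric(u$u_pfs) && is.numeric(u$u_pd)
  chk(isTRUE(ok_u), "utilities: u_pfs and u_pd must be numeric")
  if (isTRUE(ok_u))
    chk(u$u_pd >= 0 && u$u_pd <= u$u_pfs && u$u_pfs <= 1,
        "utilities: need 0 <= u_pd <= u_pfs <= 1")
  chk(isTRUE(config$regimens$backbone %in% c("XELOX", "FOLFOX")),
      "regimens.backbone: must be 'XELOX' or 'FOLFOX'")
  for (arm in c("intervention", "comparator"))
    for (nm in names(config$ae_incidence[[arm]])) {
      v <- config$ae_incidence[[arm]][[nm]]
      chk(isTRUE(is.numeric(v) && v >= 0 && v <= 1),
          paste0("ae_incidence.", arm, ".", nm, ": must be in [0, 1]"))
    }
  for (nm in names(config$overrides$drug_price_multiplier))
    chk(isTRUE(config$overrides$drug_price_multiplier[[nm]] >= 0),
        paste0("overrides.drug_price_multiplier.", nm, ": must be >= 0"))
  for (grp in c("unit_cost", "ae_cost"))
    for (nm in names(config$overrides[[grp]]))
      chk(isTRUE(config$overrides[[grp]][[nm]] >= 0),
          paste0("overrides.", grp, ".", nm, ": must be >= 0"))
  if (length(bad))
    stop("invalid configuration:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  class(config) <- "cea_config"
  config
}

#' Load and validate a YAML run configuration
#'
#' @param path Path to a YAML file, e.g. one of the shipped presets (see
#'   [preset_path()]).
#' @return A validated `cea_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' Path to a shipped preset configuration
#'
#' @param setting `"China"` or `"US"`.
#' @param population `"all_randomized"` or `"cps5"`.
#' @return Path to the installed YAML preset.
#' @examples
#' load_config(preset_path("US", "all_randomized"))
#' @export
preset_path <- function(setting = c("China", "US"),
                        population = c("all_randomized", "cps5")) {
  setting <- match.arg(setting)
  population <- match.arg(population)
  system.file("extdata",
              sprintf("%s_%s.yaml", tolower(setting), population),
              package = "gastricCEA", mustWork = TRUE)
}

# Assemble the fixed (survival-side) part of the model from a config:
# settings, validated arms, grid, traces and discount weights. Survival is
# not an uncertain parameter, so sensitivity loops reuse this object.
#' @keywords internal
build_model <- function(config) {
  config <- validate_config(config)
  settings <- model_settings(config$setting,
                             cycle_days = config$model$cycle_days,
                             horizon_years = config$model$horizon_years,
                             annual_discount = config$model$annual_discount,
                             wtp = config$model$wtp, bsa = config$model$bsa,
                             nivo_max_years = config$model$nivo_max_years)
  s <- config$survival
  if (s$source == "medians") {
    comp_pfs <- exponential_from_median(s$comparator$pfs_median)
    comp_os <- exponential_from_median(s$comparator$os_median)
    if (identical(s$intervention_source, "medians")) {
      int_pfs <- exponential_from_median(s$intervention$pfs_median)
      int_os <- exponential_from_median(s$intervention$os_median)
    } else {
      int_pfs <- apply_hazard_ratio(comp_pfs, s$hr$pfs)
      int_os <- apply_hazard_ratio(comp_os, s$hr$os)
    }
  } else {
    fit1 <- function(key, endpoint, arm)
      fit_km_curve(read_km_points(s$km_files[[key]], endpoint = endpoint,
                                  arm = arm), family = s$family)
    int_pfs <- fit1("intervention_pfs", "PFS", "intervention")
    int_os <- fit1("intervention_os", "OS", "intervention")
    comp_pfs <- fit1("comparator_pfs", "PFS", "comparator")
    comp_os <- fit1("comparator_os", "OS", "comparator")
  }
  arms <- list(
    intervention = validate_arm(int_pfs, int_os,
                                label = "nivolumab + chemotherapy",
                                horizon_years = settings$horizon_years,
                                cycle_days = settings$cycle_days),
    comparator = validate_arm(comp_pfs, comp_os, label = "chemotherapy alone",
                              horizon_years = settings$horizon_years,
                              cycle_days = settings$cycle_days))
  grid <- build_time_grid(settings)
  list(settings = settings, arms = arms, grid = grid,
       traces = lapply(arms, compute_trace, grid = grid),
       weights = discount_weights(grid, settings$annual_discount))
}

# Economic (cost/utility) side, re-evaluated per sensitivity draw.
#' @keywords internal
evaluate_economics <- function(config, model) {
  prices <- price_table(config$setting)
  ov <- config$overrides
  for (nm in names(ov$drug_price_multiplier))
    prices$drugs[[nm]]$units$price <-
      prices$drugs[[nm]]$units$price * ov$drug_price_multiplier[[nm]]
  for (nm in names(ov$unit_cost)) prices$unit_costs[[nm]] <- ov$unit_cost[[nm]]
  for (nm in names(ov$ae_cost)) prices$ae_costs[[nm]] <- ov$ae_cost[[nm]]
  profile <- ae_profile()
  for (arm in c("intervention", "comparator")) {
    col <- paste0("incidence_", arm)
    for (nm in names(config$ae_incidence[[arm]]))
      profile[[col]][profile$name == nm] <- config$ae_incidence[[arm]][[nm]]
  }
  utilities <- utility_set(u_pfs = config$utilities$u_pfs,
                           u_pd = config$utilities$u_pd)
  backbone <- builtin_regimen(config$regimens$backbone, model$settings)
  nivo <- builtin_regimen("nivolumab", model$settings)
  pd_reg <- NULL
  if (!is.null(config$regimens$pd_regimen)) {
    p <- config$regimens$pd_regimen
    pd_reg <- regimen(paste0("pd_", p$drug),
                      list(regimen_component(p$drug, p$dose, p$dose_unit,
                                             n_admin = p$n_admin)),
                      cycle_days = p$cycle_days)
  }
  res <- list()
  for (arm in c("intervention", "comparator")) {
    streams <- build_cost_streams(arm, model$settings, prices,
                                  backbone = backbone, nivo = nivo,
                                  pd_regimen = pd_reg, profile = profile)
    res[[arm]] <- accumulate_arm(model$traces[[arm]], streams, utilities,
                                 model$weights,
                                 label = model$arms[[arm]]$label,
                                 setting = config$setting)
  }
  res$comparison <- compare_arms(res$intervention, res$comparator,
                                 wtp = model$settings$wtp)
  res
}

#' Run one full cost-effectiveness pipeline
#'
#' Builds survival curves, occupancy traces, cost streams and discounted
#' outcomes for both arms and compares them.
#'
#' @param config A `cea_config` (see [default_config()], [load_config()]).
#' @param model Optional prebuilt survival model (internal reuse by the
#'   sensitivity loops).
#' @return A list with `arm_result`s `intervention` and `comparator` and a
#'   `cea_comparison` `comparison`.
#' @examples
#' res <- run_pipeline(default_config("US"))
#' res$comparison
#' @export
run_pipeline <- function(config, model = NULL) {
  if (is.null(model)) model <- build_model(config)
  evaluate_economics(validate_config(config), model)
}

#' Run the base case and write a report
#'
#' Runs [run_pipeline()] and, when `out_dir` is given, writes
#' `base_case.json` (per-arm totals and incremental results), per-arm
#' `trace_*.csv`, and a
#' `manifest.json` with the config hash, seed and package version.
#'
#' @param config A `cea_config`.
#' @param out_dir Optional output directory (created if absent).
#' @return The [run_pipeline()] result, invisibly when writing files.
#' @export
run_base_case <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  model <- build_model(config)
  res <- evaluate_economics(config, model)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report <- list(
      setting = config$setting, population = config$population,
      intervention = res$intervention[c("total_cost", "total_qalys",
                                        "total_life_years")],
      comparator = res$comparator[c("total_cost", "total_qalys",
                                    "total_life_years")],
      incremental_cost = res$comparison$delta_cost,
      incremental_qalys = res$comparison$delta_effect,
      icer = res$comparison$icer, dominance = res$comparison$dominance,
      wtp = res$comparison$wtp,
      cost_effective = res$comparison$cost_effective)
    jsonlite::write_json(report, file.path(out_dir, "base_case.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    for (arm in c("intervention", "comparator"))
      write_trace_csv(model$traces[[arm]],
                      file.path(out_dir, paste0("trace_", arm, ".csv")),
                      annual_rate = model$settings$annual_discount)
    write_manifest(out_dir, config, seed = config$psa$seed)
    return(invisible(res))
  }
  res
}

# Reproducibility manifest: config md5, seed, package version.
#' @keywords internal
write_manifest <- function(out_dir, config, seed = NULL) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config), tmp)
  jsonlite::write_json(
    list(config_md5 = unname(tools::md5sum(tmp)), seed = seed,
         package = "gastricCEA",
         version = as.character(utils::packageVersion("gastricCEA")),
         r_version = as.character(getRversion())),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, null = "null",
    pretty = TRUE)
  invisible(file.path(out_dir, "manifest.json"))
}
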