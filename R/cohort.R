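#' Model settings
#'
#' Global settings of the cohort model: a 21-day cycle over a 10-year horizon
#' with 3% annual discounting, a willingness-to-pay threshold and a mean body
#' surface area per country setting (China $37,653/QALY and 1.72 m^2; US
#' $100,000/QALY and 2.10 m^2), and the nivolumab stopping rule (maximum
#' 2 years of dosing, i.e. every model cycle whose start falls before day
#' 730.5).
#'
#' @param setting `"China"` or `"US"`; fills `wtp` and `bsa` defaults.
#' @param cycle_days Model cycle length in days.
#' @param horizon_years Time horizon in years.
#' @param annual_discount Annual discount rate for costs and effects.
#' @param wtp Willingness-to-pay threshold in $/QALY (default by setting).
#' @param bsa Mean body surface area in m^2 (default by setting).
#' @param nivo_max_years Maximum duration of nivolumab dosing in years.
#' @return An object of class `model_settings`.
#' @examples
#' model_settings("US")
#' @export
model_settings <- function(setting = c("China", "US"), cycle_days = 21,
                           horizon_years = 10, annual_discount = 0.03,
                           wtp = NULL, bsa = NULL, nivo_max_years = 2) {
  setting <- match.arg(setting)
  if (!is.finite(cycle_days) || cycle_days <= 0)
    stop("'cycle_days' must be positive", call. = FALSE)
  if (!is.finite(horizon_years) || horizon_years <= 0)
    stop("'horizon_years' must be positive", call. = FALSE)
  if (!is.finite(annual_discount) || annual_discount < 0 || annual_discount >= 1)
    stop("'annual_discount' must be in [0, 1)", call. = FALSE)
  if (is.null(wtp)) wtp <- c(China = 37653, US = 1e5)[[setting]]
  if (is.null(bsa)) bsa <- c(China = 1.72, US = 2.10)[[setting]]
  nivo_max_cycles <- as.integer(ceiling(nivo_max_years * 365.25 / cycle_days))
  structure(list(setting = setting, cycle_days = cycle_days,
                 horizon_years = horizon_years,
                 annual_discount = annual_discount, wtp = wtp, bsa = bsa,
                 nivo_max_cycles = nivo_max_cycles),
            class = "model_settings")
}

#' Discrete time grid of the cohort model
#'
#' The horizon is covered by `ceiling(horizon_years * 365.25 / cycle_days)`
#' cycles (174 for the defaults). Occupancy is evaluated at cycle midpoints,
#' a built-in half-cycle correction.
#'
#' @param settings A [model_settings()] object.
#' @return An object of class `time_grid` with `n_cycles`, `cycle_starts` and
#'   `cycle_mids` (months), and `cycle_length_years`.
#' @export
build_time_grid <- function(settings) {
  stopifnot(inherits(settings, "model_settings"))
  days_per_month <- 365.25 / 12
  n <- as.integer(ceiling(settings$horizon_years * 365.25 / settings$cycle_days))
  cyc_months <- settings$cycle_days / days_per_month
  starts <- (seq_len(n) - 1L) * cyc_months
  structure(list(n_cycles = n, cycle_starts = starts,
                 cycle_mids = starts + cyc_months / 2,
                 cycle_length_years = settings$cycle_days / 365.25,
                 cycle_days = settings$cycle_days),
            class = "time_grid")
}

#' Per-cycle discount factors
#'
#' Factor for cycle k is `(1 + rate)^(-t_mid_k)` with the midpoint expressed
#' in years.
#'
#' @param grid A [build_time_grid()] grid.
#' @param annual_rate Annual discount rate in `[0, 1)`.
#' @return Numeric vector of factors in `(0, 1]`, non-increasing.
#' @export
discount_weights <- function(grid, annual_rate) {
  stopifnot(inherits(grid, "time_grid"))
  if (!is.finite(annual_rate) || annual_rate < 0 || annual_rate >= 1)
    stop("'annual_rate' must be in [0, 1)", call. = FALSE)
  (1 + annual_rate)^(-(grid$cycle_mids / 12))
}

#' Cohort occupancy trace by partitioned survival
#'
#' At each cycle midpoint t the three mutually exclusive states are occupied
#' as pfs = S_PFS(t), pd = S_OS(t) - S_PFS(t), dead = 1 - S_OS(t). The whole
#' cohort enters in the progression-free state.
#'
#' @param arm An `arm_survival` from [validate_arm()].
#' @param grid A [build_time_grid()] grid.
#' @return An object of class `cohort_trace`: a data frame with columns
#'   `cycle`, `t_mid_months`, `pfs`, `pd`, `dead` plus the grid as an
#'   attribute.
#' @export
compute_trace <- function(arm, grid) {
  stopifnot(inherits(arm, "arm_survival"), inherits(grid, "time_grid"))
  s_pfs <- survival_probability(arm$pfs, grid$cycle_mids)
  s_os <- survival_probability(arm$os, grid$cycle_mids)
  pd <- s_os - s_pfs
  bad <- which(pd < -1e-9)
  if (length(bad))
    stop(sprintf("curve crossing: negative PD occupancy at t = %.4g months",
                 grid$cycle_mids[bad[1L]]), call. = FALSE)
  pd <- pmax(pd, 0)
  trace <- data.frame(cycle = seq_len(grid$n_cycles) - 1L,
                      t_mid_months = grid$cycle_mids,
                      pfs = s_pfs, pd = pd, dead = 1 - s_os)
  structure(trace, class = c("cohort_trace", "data.frame"), grid = grid)
}

#' Export a trace with discount factors to CSV
#'
#' Columns: `cycle,t_mid_months,pfs,pd,dead,discount_factor`.
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @param annual_rate Discount rate used for the exported factors.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, annual_rate = 0.03) {
  stopifnot(inherits(trace, "cohort_trace"))
  grid <- attr(trace, "grid")
  out <- as.data.frame(trace)
  out$discount_factor <- discount_weights(grid, annual_rate)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
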