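#' Health-state utilities
#'
#' Preference weights per health state: progression-free 0.797 (range
#' 0.638-0.956), progressive disease 0.577 (range 0.462-0.692), death 0.
#'
#' @param u_pfs,u_pd,u_death Utilities in `[0, 1]` with
#'   `u_death <= u_pd <= u_pfs`.
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(u_pfs = 0.797, u_pd = 0.577, u_death = 0) {
  if (!(u_death >= 0 && u_death <= u_pd && u_pd <= u_pfs && u_pfs <= 1))
    stop("invalid utilities: need 0 <= u_death <= u_pd <= u_pfs <= 1",
         call. = FALSE)
  structure(list(u_pfs = u_pfs, u_pd = u_pd, u_death = u_death),
            class = "utility_set")
}

#' Accumulate discounted QALYs, life years and costs for one arm
#'
#' Per cycle k of length `delta` years with discount factor `d_k`:
#' QALYs add `(u_pfs * pfs_k + u_pd * pd_k) * delta * d_k`, life years the
#' same with both utilities 1, and costs add
#' `(pfs_cost_k * pfs_k + pd_cost * pd_k) * d_k` on top of the one-off
#' adverse-event cost.
#'
#' @param trace A [compute_trace()] trace.
#' @param streams A [build_cost_streams()] object on the same grid.
#' @param utilities A [utility_set()].
#' @param weights Per-cycle discount factors from [discount_weights()].
#' @param label Arm label carried into the result.
#' @param setting Country setting carried into the result.
#' @return An object of class `arm_result` with `total_cost`, `total_qalys`,
#'   `total_life_years`.
#' @export
accumulate_arm <- function(trace, streams, utilities, weights,
                           label = "arm", setting = NA_character_) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(streams, "cost_streams"),
            inherits(utilities, "utility_set"))
  grid <- attr(trace, "grid")
  if (length(weights) != grid$n_cycles ||
      length(streams$pfs_per_cycle) != grid$n_cycles)
    stop("grid mismatch: trace, cost streams and discount weights must share ",
         "the cycle grid", call. = FALSE)
  delta <- grid$cycle_length_years
  qalys <- sum((utilities$u_pfs * trace$pfs + utilities$u_pd * trace$pd) *
                 delta * weights)
  lys <- sum((trace$pfs + trace$pd) * delta * weights)
  cost <- streams$one_off +
    sum((streams$pfs_per_cycle * trace$pfs +
           streams$pd_per_cycle * trace$pd) * weights)
  structure(list(total_cost = cost, total_qalys = qalys,
                 total_life_years = lys, label = label, setting = setting),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("%s (%s): cost $%s, %.4f QALYs, %.4f life years (discounted)\n",
              x$label, x$setting,
              formatC(x$total_cost, format = "f", digits = 2, big.mark = ","),
              x$total_qalys, x$total_life_years))
  invisible(x)
}

#' Incremental cost-effectiveness comparison
#'
#' Incremental cost and effect of the intervention over the comparator. In
#' the positive-positive quadrant the ICER is `delta_cost / delta_effect`;
#' a cheaper, more effective intervention is `dominant`; a costlier, no more
#' effective one is `dominated` (the ICER is left undefined rather than
#' signed). Cost-effective means dominant or ICER at or below the
#' willingness-to-pay threshold.
#'
#' @param intervention,comparator `arm_result`s from [accumulate_arm()].
#' @param wtp Willingness-to-pay threshold in $/QALY.
#' @return An object of class `cea_comparison` with `delta_cost`,
#'   `delta_effect`, `icer` (NA under dominance), `dominance`
#'   (`"dominant"`, `"dominated"` or `NA`), `wtp`, `cost_effective`.
#' @examples
#' a <- structure(list(total_cost = 326032.70, total_qalys = 1.12,
#'                     total_life_years = 1.6, label = "a", setting = "US"),
#'                class = "arm_result")
#' b <- structure(list(total_cost = 108892.05, total_qalys = 0.89,
#'                     total_life_years = 1.4, label = "b", setting = "US"),
#'                class = "arm_result")
#' compare_arms(a, b, wtp = 1e5)
#' @export
compare_arms <- function(intervention, comparator, wtp) {
  stopifnot(inherits(intervention, "arm_result"),
            inherits(comparator, "arm_result"))
  if (!identical(intervention$setting, comparator$setting))
    stop("cannot compare arms from different settings", call. = FALSE)
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qalys - comparator$total_qalys
  icer <- NA_real_
  dominance <- NA_character_
  if (de > 1e-12 && dc > 0) {
    icer <- dc / de
  } else if (de > 1e-12 && dc <= 0) {
    dominance <- "dominant"
  } else if (de < -1e-12 && dc >= 0) {
    dominance <- "dominated"
  } else if (abs(de) <= 1e-12) {
    if (dc > 0) dominance <- "dominated" else if (dc < 0) dominance <- "dominant"
  } else {
    icer <- dc / de  # less costly, less effective: ICER of the saving
  }
  ce <- identical(dominance, "dominant") ||
    (!is.na(icer) && de > 0 && icer <= wtp)
  structure(list(delta_cost = dc, delta_effect = de, icer = icer,
                 dominance = dominance, wtp = wtp, cost_effective = ce,
                 setting = intervention$setting),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  money <- function(v) formatC(v, format = "f", digits = 2, big.mark = ",")
  cat(sprintf("Incremental cost $%s, incremental effect %.4f QALYs\n",
              money(x$delta_cost), x$delta_effect))
  if (!is.na(x$dominance)) cat("Dominance:", x$dominance, "\n")
  else cat(sprintf("ICER: $%s/QALY\n", money(x$icer)))
  cat(sprintf("Cost-effective at WTP $%s/QALY: %s\n",
              formatC(x$wtp, format = "f", digits = 0, big.mark = ","),
              x$cost_effective))
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp * delta_effect - delta_cost`; non-negative exactly when the
#' intervention is cost-effective at that threshold (for positive incremental
#' effect).
#'
#' @param comparison A [compare_arms()] result.
#' @param wtp Optional threshold overriding the one stored in `comparison`.
#' @return Net monetary benefit in money units.
#' @export
net_monetary_benefit <- function(comparison, wtp = NULL) {
  stopifnot(inherits(comparison, "cea_comparison"))
  if (is.null(wtp)) wtp <- comparison$wtp
  wtp * comparison$delta_effect - comparison$delta_cost
}
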