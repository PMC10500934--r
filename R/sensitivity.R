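#' Uncertain-parameter specification
#'
#' One uncertain model parameter: where it lives in the run configuration,
#' its base value and range, and the distribution family used for
#' probabilistic sampling (Gamma for costs, Beta for probabilities and
#' utilities). Unless a published range exists, bounds are base +/- 20%.
#'
#' @param name Display name (tornado label).
#' @param target Dot-separated path into the configuration, e.g.
#'   `"utilities.u_pfs"`, `"drug_price_multiplier.nivolumab"`,
#'   `"unit_cost.laboratory_tests"`, `"ae_cost.anemia"`,
#'   `"ae_incidence.intervention.neutropenia"`.
#' @param base,low,high Base value and bounds, `low <= base <= high`.
#' @param family `"gamma"`, `"beta"` or `"fixed"`.
#' @return An object of class `param_spec`.
#' @export
param_spec <- function(name, target, base, low = 0.8 * base,
                       high = 1.2 * base, family = c("gamma", "beta", "fixed")) {
  family <- match.arg(family)
  if (!(is.finite(base) && is.finite(low) && is.finite(high) &&
          low <= base && base <= high))
    stop("invalid parameter spec '", name, "': need low <= base <= high",
         call. = FALSE)
  if (family == "beta" && (base <= 0 || base >= 1 || low < 0 || high > 1))
    stop("invalid parameter spec '", name,
         "': beta requires values inside [0, 1]", call. = FALSE)
  structure(list(name = name, target = target, base = base, low = low,
                 high = high, family = family), class = "param_spec")
}

# Write one parameter value into a configuration by target path.
#' @keywords internal
set_config_param <- function(config, target, value) {
  parts <- strsplit(target, ".", fixed = TRUE)[[1L]]
  root <- parts[1L]
  if (root == "utilities" && length(parts) == 2L) {
    config$utilities[[parts[2L]]] <- value
  } else if (root == "drug_price_multiplier" && length(parts) == 2L) {
    config$overrides$drug_price_multiplier[[parts[2L]]] <- value
  } else if (root %in% c("unit_cost", "ae_cost") && length(parts) == 2L) {
    config$overrides[[root]][[parts[2L]]] <- value
  } else if (root == "ae_incidence" && length(parts) == 3L) {
    config$ae_incidence[[parts[2L]]][[parts[3L]]] <- value
  } else {
    stop("configuration error: unknown parameter target '", target, "'",
         call. = FALSE)
  }
  config
}

#' Default uncertain-parameter set
#'
#' The cost and utility parameters varied in the sensitivity analyses:
#' nivolumab price (one multiplier over both vial sizes), each backbone (and
#' any configured post-progression) drug price, the four monitoring/support
#' unit costs and three adverse-event management costs (all Gamma, +/-20%),
#' the two health-state utilities (Beta, published ranges) and the six
#' cost-relevant adverse-event incidences (Beta, +/-20%). Survival parameters
#' are deliberately held fixed.
#'
#' @param config A `cea_config`.
#' @return A named list of [param_spec()]s.
#' @export
default_param_specs <- function(config) {
  prices <- price_table(config$setting)
  backbone_drugs <- unique(vapply(
    builtin_regimen(config$regimens$backbone)$components,
    function(x) x$drug, character(1)))
  drugs <- c("nivolumab", backbone_drugs)
  if (!is.null(config$regimens$pd_regimen))
    drugs <- unique(c(drugs, config$regimens$pd_regimen$drug))
  specs <- list()
  for (d in drugs)
    specs[[paste0("cost_", d)]] <-
      param_spec(paste("Cost of", d), paste0("drug_price_multiplier.", d),
                 base = 1, family = "gamma")
  for (nm in names(prices$unit_costs))
    specs[[paste0("cost_", nm)]] <-
      param_spec(paste("Cost of", gsub("_", " ", nm)),
                 paste0("unit_cost.", nm), base = prices$unit_costs[[nm]],
                 family = "gamma")
  for (nm in names(prices$ae_costs))
    specs[[paste0("cost_ae_", nm)]] <-
      param_spec(paste("Cost of managing", gsub("_", " ", nm)),
                 paste0("ae_cost.", nm), base = prices$ae_costs[[nm]],
                 family = "gamma")
  specs$u_pfs <- param_spec("Utility of PFS state", "utilities.u_pfs",
                            base = config$utilities$u_pfs, low = 0.638,
                            high = 0.956, family = "beta")
  specs$u_pd <- param_spec("Utility of PD state", "utilities.u_pd",
                           base = config$utilities$u_pd, low = 0.462,
                           high = 0.692, family = "beta")
  for (arm in c("intervention", "comparator"))
    for (nm in names(config$ae_incidence[[arm]]))
      specs[[paste0("inc_", arm, "_", nm)]] <-
        param_spec(paste("Incidence of", gsub("_", " ", nm), "(", arm, ")"),
                   paste0("ae_incidence.", arm, ".", nm),
                   base = config$ae_incidence[[arm]][[nm]], family = "beta")
  specs
}

#' Gamma hyperparameters from a base value and range
#'
#' Method of moments treating `(low, high)` as a central 95% interval:
#' `mean = base`, `sd = (high - low) / (2 * 1.96)`, so
#' `shape = (mean/sd)^2` and `scale = sd^2/mean`. Every +/-20% parameter gets
#' shape 96.04 regardless of its base.
#'
#' @param base,low,high Base value and bounds, `0 < low <= base <= high`.
#' @return Named vector `c(shape, scale)`.
#' @examples
#' gamma_params_from_range(1342.11, 1073.69, 1610.53)
#' @export
gamma_params_from_range <- function(base, low, high) {
  if (!(base > 0 && low > 0 && low <= base && base <= high))
    stop("invalid range: need 0 < low <= base <= high", call. = FALSE)
  sd <- (high - low) / (2 * 1.96)
  if (sd == 0) stop("invalid range: zero width", call. = FALSE)
  c(shape = (base / sd)^2, scale = sd^2 / base)
}

#' Beta hyperparameters from a base value and range
#'
#' Method of moments with `mean = base`, `sd = (high - low) / (2 * 1.96)`:
#' `alpha = mean * (mean(1-mean)/sd^2 - 1)` and `beta` scaled so that
#' `alpha / (alpha + beta) = mean`.
#'
#' @param base Base proportion strictly inside (0, 1).
#' @param low,high Bounds in `[0, 1]`.
#' @return Named vector `c(alpha, beta)`.
#' @examples
#' beta_params_from_range(0.797, 0.638, 0.956)
#' @export
beta_params_from_range <- function(base, low, high) {
  if (!(base > 0 && base < 1 && low >= 0 && high <= 1 && low <= base &&
          base <= high))
    stop("invalid range: need bounds in [0, 1] around base in (0, 1)",
         call. = FALSE)
  sd <- (high - low) / (2 * 1.96)
  v <- sd^2
  if (v >= base * (1 - base))
    stop("infeasible moments: variance ", signif(v, 4),
         " >= mean(1-mean) = ", signif(base * (1 - base), 4), call. = FALSE)
  alpha <- base * (base * (1 - base) / v - 1)
  c(alpha = alpha, beta = alpha * (1 - base) / base)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full pipeline with each parameter at its lower and upper bound
#' in turn, all other parameters at base, and ranks parameters by the span of
#' the resulting ICERs.
#'
#' @param config A `cea_config`.
#' @param specs List of [param_spec()]s, default [default_param_specs()].
#' @return A data frame of class `tornado`: `parameter`, `icer_low`,
#'   `icer_high`, `span = |icer_high - icer_low|`, sorted by descending span.
#'   `icer_base` is attached as an attribute.
#' @export
owsa <- function(config, specs = default_param_specs(config)) {
  config <- validate_config(config)
  model <- build_model(config)
  base_icer <- evaluate_economics(config, model)$comparison$icer
  one <- function(spec, value) {
    cfg <- set_config_param(config, spec$target, value)
    evaluate_economics(validate_config(cfg), model)$comparison$icer
  }
  out <- data.frame(
    parameter = vapply(specs, function(s) s$name, character(1)),
    icer_low = vapply(specs, function(s) one(s, s$low), numeric(1)),
    icer_high = vapply(specs, function(s) one(s, s$high), numeric(1)),
    row.names = NULL)
  out$span <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tornado", "data.frame"), icer_base = base_icer)
}

#' Joint parameter draws for probabilistic sensitivity analysis
#'
#' Independent draws per parameter: Gamma or Beta with hyperparameters from
#' the method-of-moments range translation; `"fixed"` parameters stay at
#' base. Utility draws are clipped to `[0, 1]` (Beta draws already are).
#' Reproducible under the seed.
#'
#' @param specs List of [param_spec()]s.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return A data frame of `n` rows, one column per spec (named by spec
#'   list names).
#' @export
sample_psa <- function(specs, n, seed) {
  if (!is.numeric(n) || n < 1) stop("'n' must be at least 1", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- lapply(specs, draw_spec, n = n)
  out <- as.data.frame(draws)
  names(out) <- names(specs)
  out
}

#' @keywords internal
draw_spec <- function(spec, n) {
  switch(spec$family,
    fixed = rep(spec$base, n),
    gamma = {
      p <- gamma_params_from_range(spec$base, spec$low, spec$high)
      stats::rgamma(n, shape = p[["shape"]], scale = p[["scale"]])
    },
    beta = {
      p <- beta_params_from_range(spec$base, spec$low, spec$high)
      pmin(pmax(stats::rbeta(n, p[["alpha"]], p[["beta"]]), 0), 1)
    })
}

#' Probabilistic sensitivity analysis
#'
#' Runs the full pipeline once per joint parameter draw (survival curves
#' fixed, so occupancy traces are computed once). A draw producing an invalid
#' configuration (e.g. sampled utilities out of order) is rejected and
#' redrawn, up to 100 retries per iteration.
#'
#' @param config A `cea_config`.
#' @param n Iterations (default from `config$psa$n`, 1000).
#' @param seed Seed (default from `config$psa$seed`).
#' @param specs List of [param_spec()]s, default [default_param_specs()].
#' @return An object of class `psa_result`: data frame `draws` with
#'   `iteration`, `delta_cost`, `delta_qaly`; plus `n`, `seed`, `wtp`,
#'   `prob_cost_effective` (fraction of iterations with non-negative net
#'   monetary benefit at the setting's threshold) and `n_rejected`.
#' @export
run_psa <- function(config, n = NULL, seed = NULL,
                    specs = default_param_specs(config)) {
  config <- validate_config(config)
  if (is.null(n)) n <- config$psa$n
  if (is.null(seed)) seed <- config$psa$seed
  model <- build_model(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draw_row <- function() vapply(specs, function(s) draw_spec(s, 1L), numeric(1))
  dc <- de <- numeric(n)
  n_rejected <- 0L
  for (i in seq_len(n)) {
    for (try in seq_len(101L)) {
      if (try > 100L)
        stop("PSA iteration ", i, ": 100 redraws without a valid configuration",
             call. = FALSE)
      vals <- draw_row()
      cfg <- config
      for (j in seq_along(specs))
        cfg <- set_config_param(cfg, specs[[j]]$target, vals[[j]])
      res <- tryCatch(evaluate_economics(validate_config(cfg), model),
                      error = function(e) NULL)
      if (!is.null(res)) break
      n_rejected <- n_rejected + 1L
    }
    dc[i] <- res$comparison$delta_cost
    de[i] <- res$comparison$delta_effect
  }
  wtp <- model$settings$wtp
  structure(list(draws = data.frame(iteration = seq_len(n), delta_cost = dc,
                                    delta_qaly = de),
                 n = n, seed = seed, wtp = wtp,
                 prob_cost_effective = mean(wtp * de - dc >= 0),
                 n_rejected = n_rejected),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(paste0("PSA: %d iterations (seed %s), %d rejected draws\n",
                     "mean incremental cost $%s, mean incremental effect %.4f QALYs\n",
                     "P(cost-effective at WTP $%s/QALY) = %.1f%%\n"),
              x$n, format(x$seed), x$n_rejected,
              formatC(mean(x$draws$delta_cost), format = "f", digits = 2,
                      big.mark = ","),
              mean(x$draws$delta_qaly),
              formatC(x$wtp, format = "f", digits = 0, big.mark = ","),
              100 * x$prob_cost_effective))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability of cost-effectiveness (non-negative net monetary benefit)
#' across a grid of willingness-to-pay thresholds.
#'
#' @param result A [run_psa()] result.
#' @param wtp_grid Numeric vector of thresholds.
#' @return A data frame `wtp`, `probability`.
#' @export
ceac_curve <- function(result, wtp_grid) {
  stopifnot(inherits(result, "psa_result"))
  probability <- vapply(wtp_grid, function(w)
    mean(w * result$draws$delta_qaly - result$draws$delta_cost >= 0),
    numeric(1))
  data.frame(wtp = wtp_grid, probability = probability)
}

#' Run the tornado analysis and write its files
#'
#' @param config A `cea_config`.
#' @param out_dir Optional output directory for `tornado.csv`
#'   (`parameter,icer_low,icer_high,span`) and a manifest.
#' @param specs Parameter specs, default [default_param_specs()].
#' @return The [owsa()] tornado data frame, invisibly when writing files.
#' @export
run_owsa <- function(config, out_dir = NULL,
                     specs = default_param_specs(config)) {
  tor <- owsa(config, specs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(tor), file.path(out_dir, "tornado.csv"),
                     row.names = FALSE, quote = TRUE)
    write_manifest(out_dir, validate_config(config))
    return(invisible(tor))
  }
  tor
}

#' Run the PSA and write its files
#'
#' @inheritParams run_psa
#' @param out_dir Output directory for `psa.csv`
#'   (`iteration,delta_cost,delta_qaly`) and `ceac.csv` (`wtp,probability`)
#'   plus a manifest.
#' @param wtp_grid Thresholds for the CEAC (default 0 to 4x the setting's
#'   WTP in 81 steps).
#' @return The `psa_result`, invisibly.
#' @export
run_psa_files <- function(config, out_dir, n = NULL, seed = NULL,
                          specs = default_param_specs(config),
                          wtp_grid = NULL) {
  config <- validate_config(config)
  res <- run_psa(config, n = n, seed = seed, specs = specs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(wtp_grid)) wtp_grid <- seq(0, 4 * res$wtp, length.out = 81)
  utils::write.csv(res$draws, file.path(out_dir, "psa.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ceac_curve(res, wtp_grid), file.path(out_dir, "ceac.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, config, seed = res$seed)
  invisible(res)
}

#' Tornado diagram
#'
#' Horizontal-bar plot of ICER spans around the base-case ICER, widest on
#' top (base graphics).
#'
#' @param x A [owsa()] tornado data frame.
#' @param n_top Number of parameters to show.
#' @param ... Passed to [graphics::barplot()]-level par settings (unused).
#' @return `x`, invisibly.
#' @export
plot.tornado <- function(x, n_top = 10, ...) {
  d <- utils::head(as.data.frame(x), n_top)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "icer_base")
  op <- graphics::par(mar = c(5, 14, 2, 2))
  on.exit(graphics::par(op))
  plot(NULL, xlim = range(c(d$icer_low, d$icer_high, base)),
       ylim = c(0.5, nrow(d) + 0.5), yaxt = "n", xlab = "ICER ($/QALY)",
       ylab = "", main = "One-way sensitivity analysis")
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.8)
  graphics::rect(pmin(d$icer_low, d$icer_high), seq_len(nrow(d)) - 0.35,
                 pmax(d$icer_low, d$icer_high), seq_len(nrow(d)) + 0.35,
                 col = "steelblue")
  graphics::abline(v = base, lty = 2)
  invisible(x)
}
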