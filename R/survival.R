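#' Parametric survival curve
#'
#' Construct an exponential or Weibull survival function on the time scale of
#' months. These curves carry the progression-free and overall survival of
#' each treatment arm through the cohort model.
#'
#' @param family `"exponential"` or `"weibull"`.
#' @param rate Per-month hazard (exponential only), strictly positive.
#' @param shape,scale Weibull shape (dimensionless) and scale (months),
#'   strictly positive (Weibull only).
#' @return An object of class `parametric_survival`.
#' @examples
#' parametric_survival("exponential", rate = log(2) / 7.7)
#' parametric_survival("weibull", shape = 1.2, scale = 14)
#' @export
parametric_survival <- function(family = c("exponential", "weibull"),
                                rate = NULL, shape = NULL, scale = NULL) {
  family <- match.arg(family)
  if (family == "exponential") {
    if (is.null(rate) || !is.finite(rate) || rate <= 0)
      stop("invalid parameter: exponential 'rate' must be a positive number",
           call. = FALSE)
    out <- list(family = family, rate = rate)
  } else {
    if (is.null(shape) || !is.finite(shape) || shape <= 0 ||
        is.null(scale) || !is.finite(scale) || scale <= 0)
      stop("invalid parameter: weibull 'shape' and 'scale' must be positive",
           call. = FALSE)
    out <- list(family = family, shape = shape, scale = scale)
  }
  out$time_unit <- "months"
  structure(out, class = "parametric_survival")
}

#' @export
print.parametric_survival <- function(x, ...) {
  if (x$family == "exponential") {
    cat(sprintf("Exponential survival: rate %.6g per month (median %.4g months)\n",
                x$rate, log(2) / x$rate))
  } else {
    cat(sprintf("Weibull survival: shape %.6g, scale %.6g months (median %.4g months)\n",
                x$shape, x$scale, x$scale * log(2)^(1 / x$shape)))
  }
  invisible(x)
}

#' Exponential survival curve from a published median
#'
#' The one-parameter exponential family is pinned down by a single printed
#' median: S(median) = 0.5 forces the per-month hazard lambda = ln(2)/median.
#'
#' @param median Median survival in months, strictly positive.
#' @return A `parametric_survival` of family `"exponential"`.
#' @examples
#' exponential_from_median(7.7) # lambda = 0.090019 per month
#' @export
exponential_from_median <- function(median) {
  if (!is.numeric(median) || length(median) != 1L || !is.finite(median) ||
      median <= 0)
    stop("invalid parameter: 'median' must be a positive number", call. = FALSE)
  parametric_survival("exponential", rate = log(2) / median)
}

#' Evaluate a survival curve
#'
#' @param curve A `parametric_survival`.
#' @param t Time in months, non-negative (vectorised).
#' @return Survival probabilities S(t) in `[0, 1]`.
#' @examples
#' survival_probability(exponential_from_median(7.7), 7.7) # 0.5
#' @export
survival_probability <- function(curve, t) {
  stopifnot(inherits(curve, "parametric_survival"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("invalid parameter: 't' must be non-negative", call. = FALSE)
  if (curve$family == "exponential") exp(-curve$rate * t)
  else exp(-(t / curve$scale)^curve$shape)
}

#' Hazard ratio with confidence bounds
#'
#' @param value Point estimate, strictly positive.
#' @param ci_low,ci_high Optional 95% confidence bounds.
#' @return An object of class `hazard_ratio`.
#' @export
hazard_ratio <- function(value, ci_low = NA_real_, ci_high = NA_real_) {
  if (!is.numeric(value) || !is.finite(value) || value <= 0)
    stop("invalid parameter: hazard ratio must be positive", call. = FALSE)
  structure(list(value = value, ci_low = ci_low, ci_high = ci_high),
            class = "hazard_ratio")
}

#' Apply a hazard ratio to a survival curve
#'
#' Under proportional hazards S_new(t) = S(t)^hr. For the exponential family
#' this multiplies the rate; for the Weibull it rescales the scale parameter
#' by hr^(-1/shape) while the shape is unchanged.
#'
#' @param curve A `parametric_survival`.
#' @param hr A `hazard_ratio` or a positive number.
#' @return A new `parametric_survival`.
#' @examples
#' apply_hazard_ratio(exponential_from_median(11.6), hazard_ratio(0.80))
#' @export
apply_hazard_ratio <- function(curve, hr) {
  stopifnot(inherits(curve, "parametric_survival"))
  if (inherits(hr, "hazard_ratio")) hr <- hr$value
  if (!is.numeric(hr) || !is.finite(hr) || hr <= 0)
    stop("invalid parameter: hazard ratio must be positive", call. = FALSE)
  if (curve$family == "exponential")
    parametric_survival("exponential", rate = curve$rate * hr)
  else
    parametric_survival("weibull", shape = curve$shape,
                        scale = curve$scale * hr^(-1 / curve$shape))
}

#' Digitized Kaplan-Meier coordinate set
#'
#' A validated container for (time, survival) pairs read off a published
#' Kaplan-Meier curve with a plot digitizer, or generated synthetically by
#' [generate_km_points()].
#'
#' @param time Times in months, strictly increasing, first point at most 1
#'   month.
#' @param survival Survival probabilities in `[0, 1]`, non-increasing, first
#'   point at least 0.95.
#' @param endpoint `"PFS"` or `"OS"`.
#' @param arm `"intervention"` or `"comparator"`.
#' @return An object of class `km_point_set`.
#' @export
km_point_set <- function(time, survival, endpoint = c("PFS", "OS"),
                         arm = c("intervention", "comparator")) {
  endpoint <- match.arg(endpoint)
  arm <- match.arg(arm)
  if (length(time) != length(survival))
    stop("'time' and 'survival' must have equal length", call. = FALSE)
  if (length(time) < 5L)
    stop("insufficient data: a KM point set needs at least 5 points",
         call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0) || any(diff(time) <= 0))
    stop("'time' must be non-negative and strictly increasing", call. = FALSE)
  if (any(!is.finite(survival)) || any(survival < 0) || any(survival > 1) ||
      any(diff(survival) > 0))
    stop("'survival' must be non-increasing probabilities in [0, 1]",
         call. = FALSE)
  if (survival[1L] < 0.95 || time[1L] > 1)
    stop("first point must anchor the curve: survival >= 0.95 at time <= 1 month",
         call. = FALSE)
  structure(list(endpoint = endpoint, arm = arm,
                 points = data.frame(time_months = time, survival = survival)),
            class = "km_point_set")
}

#' Read digitized KM coordinates from CSV
#'
#' Expects the two-column dialect `time_months,survival` written by
#' digitization or by [generate_km_points()] export.
#'
#' @param path CSV file path.
#' @inheritParams km_point_set
#' @return A `km_point_set`.
#' @export
read_km_points <- function(path, endpoint = c("PFS", "OS"),
                           arm = c("intervention", "comparator")) {
  if (!file.exists(path))
    stop("KM coordinate file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("time_months", "survival") %in% names(df)))
    stop("KM coordinate file must have columns 'time_months' and 'survival': ",
         path, call. = FALSE)
  km_point_set(df$time_months, df$survival, endpoint = endpoint, arm = arm)
}

#' Write a KM point set to CSV
#'
#' @param points A `km_point_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_km_points <- function(points, path) {
  stopifnot(inherits(points, "km_point_set"))
  utils::write.csv(points$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit a parametric curve to digitized KM coordinates
#'
#' Least-squares fit on the survival-probability scale: parameters minimise
#' sum_i (S_family(t_i) - s_i)^2. The exponential start value is the moment
#' estimate from the mean of -log(s)/t over interior points; the Weibull start
#' comes from a linear regression of log(-log s) on log t. Optimisation is by
#' `stats::optim` on log-parameters (Brent for the exponential).
#'
#' @param points A `km_point_set`.
#' @param family `"exponential"` or `"weibull"`.
#' @return A `parametric_survival` with attributes `rss` (residual sum of
#'   squares) and `n_points`.
#' @examples
#' t <- 1:24
#' pts <- km_point_set(c(0, t), c(1, exp(-0.09 * t)))
#' fit_km_curve(pts, "exponential")
#' @export
fit_km_curve <- function(points, family = c("exponential", "weibull")) {
  stopifnot(inherits(points, "km_point_set"))
  family <- match.arg(family)
  tt <- points$points$time_months
  ss <- points$points$survival
  if (length(tt) < 5L)
    stop("insufficient data: need at least 5 points to fit", call. = FALSE)
  interior <- tt > 0 & ss > 0 & ss < 1
  if (family == "exponential") {
    lam0 <- if (any(interior)) mean(-log(ss[interior]) / tt[interior]) else 0.1
    if (!is.finite(lam0) || lam0 <= 0) lam0 <- 0.1
    obj <- function(lp) sum((exp(-exp(lp) * tt) - ss)^2)
    opt <- stats::optim(log(lam0), obj, method = "Brent",
                        lower = log(lam0) - 10, upper = log(lam0) + 10)
    if (opt$convergence != 0L)
      stop("fit failure: optimizer did not converge (code ", opt$convergence,
           ")", call. = FALSE)
    out <- parametric_survival("exponential", rate = exp(opt$par))
  } else {
    if (sum(interior) >= 2L) {
      fit0 <- stats::lm(log(-log(ss[interior])) ~ log(tt[interior]))
      shape0 <- max(unname(stats::coef(fit0)[2L]), 1e-2)
      scale0 <- exp(-unname(stats::coef(fit0)[1L]) / shape0)
    } else {
      shape0 <- 1; scale0 <- max(tt) / 2
    }
    if (!is.finite(shape0) || shape0 <= 0) shape0 <- 1
    if (!is.finite(scale0) || scale0 <= 0) scale0 <- max(tt) / 2
    obj <- function(p) {
      sh <- exp(p[1L]); sc <- exp(p[2L])
      sum((exp(-(tt / sc)^sh) - ss)^2)
    }
    opt <- stats::optim(log(c(shape0, scale0)), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (opt$convergence != 0L)
      stop("fit failure: optimizer did not converge (code ", opt$convergence,
           ")", call. = FALSE)
    out <- parametric_survival("weibull", shape = exp(opt$par[1L]),
                               scale = exp(opt$par[2L]))
  }
  attr(out, "rss") <- opt$value
  attr(out, "n_points") <- length(tt)
  out
}

#' Pair PFS and OS curves into a validated arm
#'
#' Progressive-disease occupancy is S_OS(t) - S_PFS(t); it must be
#' non-negative at every cycle midpoint of the model grid, i.e. the curves
#' must not cross. The first offending time is reported when they do.
#'
#' @param pfs,os `parametric_survival` curves for progression-free and
#'   overall survival.
#' @param label Arm label, e.g. `"nivolumab + chemotherapy"`.
#' @param horizon_years Horizon over which the ordering is checked.
#' @param cycle_days Cycle length defining the check grid.
#' @return An object of class `arm_survival`.
#' @export
validate_arm <- function(pfs, os, label = "arm", horizon_years = 10,
                         cycle_days = 21) {
  stopifnot(inherits(pfs, "parametric_survival"),
            inherits(os, "parametric_survival"))
  grid <- build_time_grid(model_settings(horizon_years = horizon_years,
                                         cycle_days = cycle_days))
  s_pfs <- survival_probability(pfs, grid$cycle_mids)
  s_os <- survival_probability(os, grid$cycle_mids)
  bad <- which(s_os - s_pfs < -1e-9)
  if (length(bad))
    stop(sprintf(
      "curve crossing: S_OS < S_PFS first at t = %.4g months (OS %.6f < PFS %.6f)",
      grid$cycle_mids[bad[1L]], s_os[bad[1L]], s_pfs[bad[1L]]), call. = FALSE)
  structure(list(pfs = pfs, os = os, label = label), class = "arm_survival")
}

#' @export
print.arm_survival <- function(x, ...) {
  cat("Arm:", x$label, "\n  PFS: ")
  print(x$pfs)
  cat("  OS:  ")
  print(x$os)
  invisible(x)
}
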