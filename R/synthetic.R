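#' Synthetic digitized Kaplan-Meier coordinates
#'
#' Emulates the coordinate sets a plot digitizer produces from a published
#' KM curve: points at evenly spaced times from 0 to the time where the true
#' curve reaches about 0.05, with additive Gaussian noise on the survival
#' scale, clipped to `[0, 1]` and repaired to be non-increasing by a running
#' minimum. The first point is anchored at (0, 1).
#'
#' @param curve True `parametric_survival`.
#' @param n_points Number of points (at least 5).
#' @param noise_sd Standard deviation of the digitization noise on the
#'   survival-probability scale (0 for exact points).
#' @param seed Integer seed; same seed, same point set.
#' @inheritParams km_point_set
#' @return A `km_point_set`.
#' @examples
#' generate_km_points(exponential_from_median(7.7), 30, 0.01, seed = 7)
#' @export
generate_km_points <- function(curve, n_points = 30, noise_sd = 0.01,
                               seed = 1, endpoint = c("PFS", "OS"),
                               arm = c("intervention", "comparator")) {
  stopifnot(inherits(curve, "parametric_survival"))
  if (n_points < 5) stop("'n_points' must be at least 5", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  t_max <- if (curve$family == "exponential") -log(0.05) / curve$rate
           else curve$scale * (-log(0.05))^(1 / curve$shape)
  tt <- seq(0, t_max, length.out = n_points)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ss <- survival_probability(curve, tt) + stats::rnorm(n_points, 0, noise_sd)
  ss <- cummin(pmin(pmax(ss, 0), 1))
  ss[1L] <- 1
  tt[1L] <- 0
  km_point_set(tt, ss, endpoint = endpoint, arm = arm)
}

#' Synthetic two-arm scenario with known ground truth
#'
#' Builds true exponential or Weibull curves for both arms from per-arm PFS
#' and OS medians, digitizes each into a KM coordinate CSV, and returns a
#' runnable configuration pointing at those files together with the truth for
#' recovery scoring. With `noise_sd = 0` the coordinate-file route reproduces
#' the medians route exactly (up to fit tolerance).
#'
#' @param medians Named list
#'   `list(intervention = c(pfs, os), comparator = c(pfs, os))` in months,
#'   PFS median strictly below OS median within each arm.
#' @param family `"exponential"` or `"weibull"`.
#' @param shape Weibull shape shared by all truth curves (family `"weibull"`
#'   only); scales are chosen so each curve keeps its stated median.
#' @param n_points,noise_sd Digitization grid size and noise level.
#' @param seed Integer seed (per-curve seeds are derived from it).
#' @param dir Directory for the four CSV files (created if needed).
#' @param setting,population Passed to [default_config()] for the economic
#'   side of the scenario.
#' @return A list of class `synthetic_scenario`: `truth` (list of
#'   `arm_survival`), `points` (list of `km_point_set`), `files`, `config`
#'   (a `cea_config` using the KM-file route) and the generation parameters.
#' @export
generate_scenario <- function(medians = list(intervention = c(7.7, 13.8),
                                             comparator = c(6.9, 11.6)),
                              family = c("exponential", "weibull"),
                              shape = 1.2, n_points = 30, noise_sd = 0.01,
                              seed = 1, dir = tempfile("scenario"),
                              setting = "China",
                              population = "all_randomized") {
  family <- match.arg(family)
  for (arm in c("intervention", "comparator")) {
    m <- medians[[arm]]
    if (is.null(m) || length(m) != 2L || any(!is.finite(m)) || any(m <= 0))
      stop("medians$", arm, " must be two positive months (PFS, OS)",
           call. = FALSE)
    if (m[1L] >= m[2L])
      stop("curve crossing: ", arm, " PFS median must be below its OS median",
           call. = FALSE)
  }
  make_curve <- function(median) {
    if (family == "exponential") exponential_from_median(median)
    else parametric_survival("weibull", shape = shape,
                             scale = median / log(2)^(1 / shape))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- points <- list()
  files <- list()
  i <- 0L
  for (arm in c("intervention", "comparator")) {
    pfs <- make_curve(medians[[arm]][1L])
    os <- make_curve(medians[[arm]][2L])
    truth[[arm]] <- validate_arm(pfs, os, label = arm)
    for (endpoint in c("PFS", "OS")) {
      i <- i + 1L
      key <- paste0(arm, "_", tolower(endpoint))
      pts <- generate_km_points(if (endpoint == "PFS") pfs else os,
                                n_points = n_points, noise_sd = noise_sd,
                                seed = seed + i, endpoint = endpoint,
                                arm = arm)
      points[[key]] <- pts
      files[[key]] <- file.path(dir, paste0(key, ".csv"))
      write_km_points(pts, files[[key]])
    }
  }
  config <- default_config(setting, population)
  config$survival$source <- "km_files"
  config$survival$family <- family
  config$survival$km_files <- files
  structure(list(truth = truth, points = points, files = files,
                 config = validate_config(config),
                 params = list(medians = medians, family = family,
                               shape = if (family == "weibull") shape,
                               n_points = n_points, noise_sd = noise_sd,
                               seed = seed)),
            class = "synthetic_scenario")
}
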