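#' Relaxation index of an incision measurement
#'
#' The dimensionless readout of stored-stress release:
#' `100 * opening_distance / diameter`.
#'
#' @param opening_distance Opening distance(s), micrometres, >= 0.
#' @param diameter Pre-cut spheroid diameter(s), micrometres, > 0.
#' @return Numeric vector, percent.
#' @examples
#' relaxation_index(45, 450)  # 10
#' @export
relaxation_index <- function(opening_distance, diameter) {
  if (any(diameter <= 0)) stop("`diameter` must be positive", call. = FALSE)
  if (any(opening_distance < 0)) {
    stop("`opening_distance` must be non-negative", call. = FALSE)
  }
  100 * opening_distance / diameter
}

#' Validate and derive an incision-observation cohort
#'
#' Takes a data frame of per-spheroid incision measurements and appends the
#' derived `depth_fraction` (incision depth / diameter) and
#' `relaxation_index` (percent) columns.
#'
#' @param data Data frame with columns `spheroid_id`, `diameter_um`,
#'   `incision_depth_um`, `opening_um`.
#' @return A tibble with the input columns plus `depth_fraction` and
#'   `relaxation_index`.
#' @export
incision_observations <- function(data) {
  needed <- c("spheroid_id", "diameter_um", "incision_depth_um", "opening_um")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (any(data$diameter_um <= 0) ||
      any(data$incision_depth_um <= 0 |
            data$incision_depth_um >= data$diameter_um) ||
      any(data$opening_um < 0)) {
    stop(paste("need 0 < incision_depth_um < diameter_um and",
               "opening_um >= 0 for every spheroid"), call. = FALSE)
  }
  dplyr::mutate(
    data,
    depth_fraction = .data$incision_depth_um / .data$diameter_um,
    relaxation_index = relaxation_index(.data$opening_um, .data$diameter_um)
  )
}

#' Read an incision cohort from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and columns
#' `spheroid_id`, `diameter_um`, `incision_depth_um`, `opening_um`.
#'
#' @param path Path to the CSV file.
#' @return A tibble as returned by [incision_observations()].
#' @export
read_incision_cohort <- function(path) {
  incision_observations(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Fraction of observations lying below one response curve
#'
#' For a response curve simulated at magnitude gamma, counts the observations
#' whose relaxation index falls at or below the curve value at their depth
#' fraction (ties count as below). The curve is interpolated linearly between
#' simulated depths; observations outside the curve's depth support are an
#' error, never extrapolated.
#'
#' @param observations A cohort from [incision_observations()] (needs columns
#'   `depth_fraction` and `relaxation_index`).
#' @param curve A `response_curve` from [simulate_response_curve()] or
#'   [surface_curve()].
#' @return A one-row tibble: `gamma`, `n_below`, `n_total`, `fraction_below`.
#' @export
fraction_below_curve <- function(observations, curve) {
  stopifnot(inherits(curve, "response_curve"))
  if (!all(c("depth_fraction", "relaxation_index") %in% names(observations))) {
    stop("observations need `depth_fraction` and `relaxation_index` columns",
         call. = FALSE)
  }
  lo <- min(curve$depth_fraction); hi <- max(curve$depth_fraction)
  out_of_support <- observations$depth_fraction < lo - 1e-12 |
    observations$depth_fraction > hi + 1e-12
  if (any(out_of_support)) {
    bad <- which(out_of_support)[1L]
    stop(sprintf(
      "observation %s (depth fraction %.3f) is outside the curve support [%.3f, %.3f]",
      if ("spheroid_id" %in% names(observations)) {
        as.character(observations$spheroid_id[bad])
      } else as.character(bad),
      observations$depth_fraction[bad], lo, hi), call. = FALSE)
  }
  curve_at <- stats::approx(curve$depth_fraction, curve$relaxation_index,
                            xout = observations$depth_fraction,
                            rule = 1)$y
  # ties count as below; the 1e-9 slack keeps exact ties stable under
  # floating-point interpolation noise
  n_below <- sum(observations$relaxation_index <= curve_at + 1e-9)
  tibble::tibble(
    gamma = attr(curve, "gamma"),
    n_below = n_below,
    n_total = nrow(observations),
    fraction_below = n_below / nrow(observations)
  )
}

#' Sample the cumulative distribution of the stored-stress magnitude
#'
#' For each magnitude gamma on the grid, the fraction of observations lying
#' below the simulated response curve at that gamma estimates
#' P(stored stress <= gamma): sweeping the grid samples the cumulative
#' distribution function of the per-spheroid stored stress. Raw counts are
#' reported; the fractions need not be monotone, the parametric cdf fit
#' absorbs that.
#'
#' @param observations A cohort from [incision_observations()].
#' @param surface A [response_surface()] covering the cohort's depth range.
#' @param gamma_grid Strictly increasing grid of magnitudes (>= 6 points)
#'   within the surface support. Default: the surface's own gamma nodes.
#' @return A tibble with one row per gamma: `gamma`, `n_below`, `n_total`,
#'   `fraction_below`.
#' @export
sample_cdf <- function(observations, surface,
                       gamma_grid = attr(surface, "gammas")) {
  stopifnot(inherits(surface, "response_surface"))
  if (nrow(observations) == 0L) {
    stop("empty cohort: the stored-stress cdf is not identifiable",
         call. = FALSE)
  }
  if (length(gamma_grid) < 6L || is.unsorted(gamma_grid, strictly = TRUE)) {
    stop("`gamma_grid` must be strictly increasing with at least 6 points",
         call. = FALSE)
  }
  purrr::map_dfr(gamma_grid, function(g) {
    curve_at <- predict_relaxation(surface, g, observations$depth_fraction)
    n_below <- sum(observations$relaxation_index <= curve_at + 1e-9)
    tibble::tibble(gamma = g, n_below = n_below,
                   n_total = nrow(observations),
                   fraction_below = n_below / nrow(observations))
  })
}

#' Fit a Gaussian cdf to sampled stored-stress fractions
#'
#' Least-squares fit of \eqn{\Phi((\gamma - \mu)/\sigma)} to the
#' (gamma, fraction) pairs of [sample_cdf()], yielding the mean stored-stress
#' magnitude and its standard deviation across the cohort.
#' Initialization: mu at the sample nearest fraction 0.5, sigma at a quarter
#' of the grid span; bounds keep mu inside the grid range and sigma in
#' `[1e-4, span]`.
#'
#' @param samples A tibble with columns `gamma` and `fraction_below`
#'   (>= 4 rows, at least one fraction strictly inside (0, 1)).
#' @return An object of class `stress_estimate` with elements `mu`, `sigma`,
#'   `rss`, `samples` (with fitted values), `gamma_grid`, `convergence`.
#' @examples
#' s <- tibble::tibble(gamma = seq(0.05, 0.45, length.out = 10))
#' s$fraction_below <- pnorm(s$gamma, 0.2, 0.05)
#' fit_gaussian_cdf(s)
#' @export
fit_gaussian_cdf <- function(samples) {
  if (!all(c("gamma", "fraction_below") %in% names(samples))) {
    stop("`samples` needs columns `gamma` and `fraction_below`",
         call. = FALSE)
  }
  if (nrow(samples) < 4L) {
    stop("need at least 4 cdf samples", call. = FALSE)
  }
  fr <- samples$fraction_below
  if (all(fr <= 0) || all(fr >= 1)) {
    stop(paste("cdf samples are all 0 or all 1: the stored-stress",
               "distribution is not identifiable on this gamma grid"),
         call. = FALSE)
  }
  gg <- samples$gamma
  span <- max(gg) - min(gg)
  # initialize mu at the (interpolated) half-crossing of the empirical cdf,
  # clamped inside the grid; sigma at a quarter of the grid span
  cross <- which(fr >= 0.5)
  mu0 <- if (length(cross) == 0L) {
    max(gg)
  } else if (cross[1L] == 1L) {
    min(gg)
  } else {
    i <- cross[1L]
    gg[i - 1L] + (0.5 - fr[i - 1L]) / (fr[i] - fr[i - 1L]) *
      (gg[i] - gg[i - 1L])
  }
  mu0 <- min(max(mu0, min(gg) + 1e-6 * span), max(gg) - 1e-6 * span)
  sigma0 <- span / 4
  lower <- c(min(gg), 1e-4)
  upper <- c(max(gg), span)
  est <- tryCatch({
    fit <- minpack.lm::nlsLM(
      fraction_below ~ stats::pnorm(gamma, mu, sigma),
      data = samples,
      start = list(mu = mu0, sigma = sigma0),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 500)
    )
    c(stats::coef(fit), conv = 0)
  }, error = function(e) {
    # near-degenerate samples (step-like cdfs) can defeat the Levenberg-
    # Marquardt start; fall back to bounded quasi-Newton on the same RSS
    opt <- stats::optim(
      c(mu0, sigma0),
      function(p) sum((fr - stats::pnorm(gg, p[1], p[2]))^2),
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(factr = 10))
    c(mu = opt$par[1], sigma = opt$par[2], conv = opt$convergence)
  })
  fitted_fr <- stats::pnorm(gg, est[["mu"]], est[["sigma"]])
  out <- list(
    mu = unname(est[["mu"]]),
    sigma = unname(est[["sigma"]]),
    rss = sum((fr - fitted_fr)^2),
    samples = dplyr::mutate(tibble::as_tibble(samples),
                            fitted_fraction = fitted_fr),
    gamma_grid = gg,
    convergence = unname(est[["conv"]])
  )
  class(out) <- "stress_estimate"
  out
}

#' @export
print.stress_estimate <- function(x, ...) {
  cat(sprintf(
    "<stress_estimate> stored stress mu = %.4f +/- %.4f (a.u.), rss = %.3g, %d cdf samples\n",
    x$mu, x$sigma, x$rss, nrow(x$samples)))
  if (!is.null(x$gamma_star)) {
    cat(sprintf("  regression-consistency gamma* = %.4f\n", x$gamma_star))
  }
  invisible(x)
}

#' Regression-consistency estimate of the stored-stress magnitude
#'
#' Fits an ordinary least-squares line to the cohort's
#' (depth fraction, relaxation index) points, then returns the candidate
#' magnitude whose response-curve points lie closest (in summed squared
#' vertical distance) to that regression line. This mirrors reading off the
#' single magnitude whose simulated curve tracks the experimental trend.
#'
#' @param observations A cohort from [incision_observations()] (>= 5 rows
#'   spanning >= 0.1 in depth fraction).
#' @param candidate_gammas Candidate magnitudes, each inside the gamma
#'   support of `surface`.
#' @param surface A [response_surface()].
#' @return The selected magnitude (scalar), with the per-candidate summed
#'   squared distances as attribute `scores`.
#' @export
regression_consistency_check <- function(observations, candidate_gammas,
                                         surface) {
  stopifnot(inherits(surface, "response_surface"))
  if (length(candidate_gammas) > 1L) {
    if (nrow(observations) < 5L ||
        diff(range(observations$depth_fraction)) < 0.1) {
      stop(paste("need >= 5 observations spanning >= 0.1 in depth fraction",
                 "for the regression check"), call. = FALSE)
    }
  }
  if (length(candidate_gammas) == 1L) {
    return(structure(candidate_gammas, scores = NA_real_))
  }
  line <- stats::lm(relaxation_index ~ depth_fraction, data = observations)
  depths <- sort(unique(surface$depth_fraction))
  line_at <- stats::predict(line,
                            newdata = data.frame(depth_fraction = depths))
  scores <- vapply(candidate_gammas, function(g) {
    sum((predict_relaxation(surface, g, depths) - line_at)^2)
  }, numeric(1L))
  structure(candidate_gammas[which.min(scores)],
            scores = stats::setNames(scores, signif(candidate_gammas, 6)))
}

#' Estimate the stored-stress distribution from an incision cohort
#'
#' End-to-end inference: samples the stored-stress cdf on the gamma grid via
#' the forward response surface, fits a Gaussian cdf to obtain the mean and
#' standard deviation of the stored-stress magnitude, and (for cohorts wide
#' enough in depth) also records the regression-consistency magnitude
#' `gamma_star`.
#'
#' @param observations A cohort data frame; passed through
#'   [incision_observations()] if the derived columns are absent.
#' @param surface A [response_surface()].
#' @param gamma_grid Grid for the cdf sampling; default the surface's gamma
#'   nodes.
#' @param regression_check Also run [regression_consistency_check()]?
#'   Default TRUE when the cohort permits it.
#' @return A `stress_estimate` (see [fit_gaussian_cdf()]) with the extra
#'   element `gamma_star` (NA if the check was not run).
#' @export
estimate_stored_stress <- function(observations, surface,
                                   gamma_grid = attr(surface, "gammas"),
                                   regression_check = TRUE) {
  if (nrow(observations) == 0L) {
    stop("empty cohort: the stored-stress cdf is not identifiable",
         call. = FALSE)
  }
  if (!all(c("depth_fraction", "relaxation_index") %in% names(observations))) {
    observations <- incision_observations(observations)
  }
  samples <- sample_cdf(observations, surface, gamma_grid)
  est <- fit_gaussian_cdf(samples)
  est$gamma_star <- NA_real_
  if (isTRUE(regression_check) && nrow(observations) >= 5L &&
      diff(range(observations$depth_fraction)) >= 0.1) {
    est$gamma_star <- as.numeric(
      regression_consistency_check(observations, attr(surface, "gammas"),
                                   surface))
  }
  est$n_observations <- nrow(observations)
  est
}
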