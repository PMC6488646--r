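#' Plot a response curve
#'
#' @param object A `response_curve` from [simulate_response_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot response_curve
#' @export
autoplot.response_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$depth_fraction,
                               y = .data$relaxation_index)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(
      x = "incision depth / diameter",
      y = "relaxation index (%)",
      title = sprintf("Simulated response curve, gamma = %.3g a.u.",
                      attr(object, "gamma"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a response surface as one curve per stored-stress magnitude
#'
#' @param object A `response_surface` from [response_surface()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot response_surface
#' @export
autoplot.response_surface <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$depth_fraction,
                               y = .data$relaxation_index,
                               group = .data$gamma,
                               colour = .data$gamma)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c(name = "gamma (a.u.)") +
    ggplot2::labs(x = "incision depth / diameter",
                  y = "relaxation index (%)",
                  title = "Forward-model response surface") +
    ggplot2::theme_minimal()
}

#' Plot the sampled stored-stress cdf and its Gaussian fit
#'
#' @param object A `stress_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stress_estimate
#' @export
autoplot.stress_estimate <- function(object, ...) {
  grid <- tibble::tibble(
    gamma = seq(min(object$gamma_grid), max(object$gamma_grid),
                length.out = 200)
  )
  grid$fraction <- stats::pnorm(grid$gamma, object$mu, object$sigma)
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$gamma, y = .data$fraction_below)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$gamma, y = .data$fraction),
                       colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "stored-stress magnitude gamma (a.u.)",
      y = "fraction of spheroids below the response curve",
      title = sprintf("Gaussian cdf fit: mu = %.3f, sigma = %.3f (a.u.)",
                      object$mu, object$sigma)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Sneddon fit over its indentation data
#'
#' @param object A `sneddon_fit` with an accepted curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sneddon_fit
#' @export
autoplot.sneddon_fit <- function(object, ...) {
  if (is.null(object$indentation)) {
    stop("this fit carries no indentation data (rejected curve)",
         call. = FALSE)
  }
  dat <- object$indentation
  dat$fitted <- sneddon_force(dat$separation_m, object$young_modulus_pa,
                              object$half_angle, object$poisson_ratio)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$separation_m * 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$force_n * 1e9),
                        alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted * 1e9),
                       colour = "firebrick") +
    ggplot2::labs(
      x = "indentation depth (um)", y = "force (nN)",
      title = sprintf("Sneddon fit: E = %.3g Pa", object$young_modulus_pa)
    ) +
    ggplot2::theme_minimal()
}

#' Dose-response plot of normalized growth
#'
#' @param normalized A [normalize_to_control()] table, or several bound
#'   together with a `condition` column.
#' @return A ggplot (log-ish x handled by pseudo-log).
#' @export
plot_dose_response <- function(normalized) {
  stopifnot(all(c("concentration_uM", "normalized_growth") %in%
                  names(normalized)))
  aes <- if ("condition" %in% names(normalized)) {
    ggplot2::aes(x = .data$concentration_uM, y = .data$normalized_growth,
                 colour = .data$condition, group = .data$condition)
  } else {
    ggplot2::aes(x = .data$concentration_uM, y = .data$normalized_growth,
                 group = 1)
  }
  ggplot2::ggplot(normalized, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = scales_pseudo_log()) +
    ggplot2::labs(x = "irinotecan (uM)",
                  y = "growth rate (fraction of untreated control)") +
    ggplot2::theme_minimal()
}

scales_pseudo_log <- function() {
  scales::pseudo_log_trans(sigma = 1, base = 10)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
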