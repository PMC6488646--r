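#' Tidy a stored-stress estimate
#'
#' @param x A `stress_estimate` from [fit_gaussian_cdf()] or
#'   [estimate_stored_stress()].
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter (`mu`, `sigma`), their
#'   estimates in arbitrary stress units.
#' @method tidy stress_estimate
#' @export
tidy.stress_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("mu", "sigma"),
    estimate = c(x$mu, x$sigma)
  )
}

#' One-row summary of a stored-stress estimate
#'
#' @inheritParams tidy.stress_estimate
#' @return A one-row tibble: `mu`, `sigma`, `rss`, `n_samples`,
#'   `n_observations`, `gamma_star`.
#' @method glance stress_estimate
#' @export
glance.stress_estimate <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, sigma = x$sigma, rss = x$rss,
    n_samples = nrow(x$samples),
    n_observations = x$n_observations %||% NA_integer_,
    gamma_star = x$gamma_star %||% NA_real_
  )
}

#' Tidy a Sneddon fit
#'
#' @param x A `sneddon_fit` from [fit_sneddon()].
#' @param ... Unused.
#' @return A tibble with rows for the fitted Young's modulus (Pa) and
#'   contact point (um).
#' @method tidy sneddon_fit
#' @export
tidy.sneddon_fit <- function(x, ...) {
  tibble::tibble(
    term = c("young_modulus_pa", "contact_point_um"),
    estimate = c(x$young_modulus_pa, x$contact_point_um)
  )
}

#' One-row summary of a Sneddon fit
#'
#' @inheritParams tidy.sneddon_fit
#' @return A one-row tibble: `young_modulus_pa`, `contact_point_um`,
#'   `residual_rms_n`, `n_points`, `qc`.
#' @method glance sneddon_fit
#' @export
glance.sneddon_fit <- function(x, ...) {
  tibble::tibble(
    young_modulus_pa = x$young_modulus_pa,
    contact_point_um = x$contact_point_um,
    residual_rms_n = x$residual_rms_n,
    n_points = x$n_points,
    qc = x$qc
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
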