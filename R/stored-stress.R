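#' Growth-induced stored-stress profile
#'
#' The stored (residual) stress left in a spheroid by proliferation is modelled
#' as a symmetric field whose radial component follows a power law vanishing at
#' the free surface,
#' \deqn{\sigma_{rr}(r) = \gamma \left(1 - (r/R)^n\right),}
#' with magnitude \eqn{\gamma} (the centerline radial stored stress, in
#' arbitrary units), exponent \eqn{n > 0} and reference radius \eqn{R}. The
#' circumferential component is not free: it is fixed by the requirement that
#' the stored field be self-equilibrated (zero divergence) in the chosen
#' symmetry, see [stored_stress_components()].
#'
#' @param magnitude Stored-stress magnitude \eqn{\gamma \ge 0} (arbitrary
#'   units; the value of \eqn{\sigma_{rr}} at the center).
#' @param exponent Power-law exponent \eqn{n > 0}. Default 2.
#' @param reference_radius Spheroid radius \eqn{R} in micrometres. Default 225
#'   (a 450 um spheroid).
#' @return An object of class `stress_profile`.
#' @examples
#' prof <- stress_profile(magnitude = 0.276)
#' stored_stress_components(c(0, 112.5, 225), prof)
#' @export
stress_profile <- function(magnitude, exponent = 2, reference_radius = 225) {
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude < 0) {
    stop("`magnitude` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent <= 0) {
    stop("`exponent` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(reference_radius) || length(reference_radius) != 1L ||
      reference_radius <= 0) {
    stop("`reference_radius` must be a single positive number", call. = FALSE)
  }
  structure(
    list(magnitude = magnitude, exponent = exponent,
         reference_radius = reference_radius),
    class = "stress_profile"
  )
}

#' @export
print.stress_profile <- function(x, ...) {
  cat(sprintf(
    "<stress_profile> sigma_rr(r) = %.4g * (1 - (r/%.4g)^%.4g)  [a.u., um]\n",
    x$magnitude, x$reference_radius, x$exponent))
  invisible(x)
}

#' Radial and circumferential stored-stress components
#'
#' Evaluates the stored-stress field at radii `r`. The radial component is the
#' power-law profile of [stress_profile()]; the circumferential (tangential)
#' component is derived from the zero-divergence identity of the chosen
#' symmetry:
#' \itemize{
#'   \item spherical: \eqn{\sigma_{\theta\theta} = \sigma_{rr} +
#'     (r/2)\, d\sigma_{rr}/dr}, so that
#'     \eqn{d\sigma_{rr}/dr + 2(\sigma_{rr}-\sigma_{\theta\theta})/r = 0};
#'   \item plane (2D disk cross-section): \eqn{\sigma_{\theta\theta} =
#'     \sigma_{rr} + r\, d\sigma_{rr}/dr}, so that
#'     \eqn{d\sigma_{rr}/dr + (\sigma_{rr}-\sigma_{\theta\theta})/r = 0}.
#' }
#' Either way the field is self-equilibrated and traction-free at \eqn{r = R}.
#'
#' @param r Vector of radii, micrometres, each in `[0, R]`.
#' @param profile A [stress_profile()].
#' @param symmetry_mode `"spherical"` or `"plane"`.
#' @return A tibble with columns `r`, `sigma_rr`, `sigma_tt` (arbitrary units).
#' @export
stored_stress_components <- function(r, profile,
                                     symmetry_mode = c("spherical", "plane")) {
  stopifnot(inherits(profile, "stress_profile"))
  symmetry_mode <- match.arg(symmetry_mode)
  R <- profile$reference_radius
  if (any(r < 0 | r > R)) {
    stop("all radii must lie in [0, reference_radius]", call. = FALSE)
  }
  g <- profile$magnitude
  n <- profile$exponent
  rho_n <- (r / R)^n
  sigma_rr <- g * (1 - rho_n)
  # r * dsigma_rr/dr = -gamma * n * (r/R)^n  (finite also at r = 0 for n > 0)
  r_dsig <- -g * n * rho_n
  sigma_tt <- switch(symmetry_mode,
    spherical = sigma_rr + r_dsig / 2,
    plane = sigma_rr + r_dsig
  )
  tibble::tibble(r = r, sigma_rr = sigma_rr, sigma_tt = sigma_tt)
}
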