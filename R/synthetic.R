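#' Generate a synthetic incision cohort
#'
#' Draws per-spheroid stored-stress magnitudes from a Gaussian (truncated to
#' non-negative values and to the response surface's gamma support), incision
#' depth fractions uniform over the experimental range, and diameters from a
#' lognormal around the nominal spheroid size; maps each (gamma, depth) pair
#' through the forward response surface to a relaxation index; adds Gaussian
#' measurement noise; and back-computes the opening distance. The generating
#' truth is kept alongside the observable columns so closed-loop recovery
#' tests can compare against it.
#'
#' @param n_spheroids Cohort size. Default 29.
#' @param stress_mean,stress_sd Gaussian parameters of the per-spheroid
#'   stored-stress magnitude (arbitrary units). Defaults 0.276 and 0.037.
#' @param surface A [response_surface()] covering the sampled gammas/depths.
#' @param depth_range Depth-fraction range, default `c(0.40, 0.65)`.
#' @param diameter_mean Nominal diameter, micrometres. Default 450.
#' @param diameter_cv Coefficient of variation of the diameter. Default 0.05.
#' @param noise_sd SD of the additive measurement noise on the relaxation
#'   index, percentage points. Default 1.
#' @param seed Optional integer seed; the output is reproducible given the
#'   seed.
#' @return A tibble with observable columns `spheroid_id`, `diameter_um`,
#'   `incision_depth_um`, `opening_um`, derived `depth_fraction`,
#'   `relaxation_index`, and ground-truth columns `gamma_true`,
#'   `relaxation_true`.
#' @export
generate_incision_cohort <- function(n_spheroids = 29,
                                     stress_mean = 0.276,
                                     stress_sd = 0.037,
                                     surface,
                                     depth_range = c(0.40, 0.65),
                                     diameter_mean = 450,
                                     diameter_cv = 0.05,
                                     noise_sd = 1,
                                     seed = NULL) {
  stopifnot(inherits(surface, "response_surface"),
            n_spheroids >= 1, stress_sd >= 0, noise_sd >= 0,
            length(depth_range) == 2L, depth_range[1] < depth_range[2],
            depth_range[1] > 0, depth_range[2] < 1)
  if (!is.null(seed)) set.seed(seed)
  gg <- attr(surface, "gammas")
  dd <- range(surface$depth_fraction)
  if (depth_range[1] < dd[1] - 1e-9 || depth_range[2] > dd[2] + 1e-9) {
    stop("depth_range is not covered by the response surface", call. = FALSE)
  }
  lo <- max(0, min(gg)); hi <- max(gg)
  if (stress_mean < lo || stress_mean > hi) {
    stop("stress_mean lies outside the surface's gamma support",
         call. = FALSE)
  }
  gamma_true <- if (stress_sd == 0) {
    rep(stress_mean, n_spheroids)
  } else {
    # rejection sampling of the truncated Gaussian; the support is many SDs
    # wide in all study regimes so this resolves in one or two rounds
    out <- numeric(0)
    while (length(out) < n_spheroids) {
      draw <- rnorm(2L * n_spheroids, stress_mean, stress_sd)
      out <- c(out, draw[draw >= lo & draw <= hi])
    }
    out[seq_len(n_spheroids)]
  }
  depth_fraction <- runif(n_spheroids, depth_range[1], depth_range[2])
  diameter <- diameter_mean * exp(rnorm(n_spheroids, 0, diameter_cv))
  ri_true <- predict_relaxation(surface, gamma_true, depth_fraction)
  ri_obs <- pmax(0, ri_true + rnorm(n_spheroids, 0, noise_sd))
  tibble::tibble(
    spheroid_id = sprintf("synth-%03d", seq_len(n_spheroids)),
    diameter_um = diameter,
    incision_depth_um = depth_fraction * diameter,
    opening_um = ri_obs / 100 * diameter,
    depth_fraction = depth_fraction,
    relaxation_index = ri_obs,
    gamma_true = gamma_true,
    relaxation_true = ri_true
  )
}

#' Generate a synthetic AFM force map
#'
#' Builds approach force curves by inverting the conical Hertz-Sneddon law:
#' beyond the contact point the cantilever deflection solves
#' \eqn{k\,d = B\,((z - z_0) - d)^2} (with \eqn{B} the Sneddon prefactor),
#' giving curves capped at the requested maximum force, with a flat
#' pre-contact baseline and additive deflection noise.
#'
#' @param n_curves Number of curves. Default 9 (a 3 x 3 force map).
#' @param young_modulus True Young's modulus, Pa. Default 3000.
#' @param spring_constant Cantilever spring constant, N/m. Default 0.15.
#' @param half_angle Tip half-angle, degrees. Default 17.5.
#' @param poisson_ratio Sample Poisson ratio. Default 0.5.
#' @param max_force Maximum applied force, N. Default 1e-9 (1 nN).
#' @param n_samples Samples per curve (>= 50). Default 400.
#' @param contact_fraction Position of the contact point along the ramp, in
#'   (0, 1). Default 0.45.
#' @param noise_sd SD of additive deflection noise, micrometres. Default
#'   3e-4 (0.3 nm, a quiet liquid-cell deflection signal).
#' @param spheroid_id,zone Metadata for the generated curves.
#' @param seed Optional integer seed.
#' @return A tibble of class `force_map` with one row per curve: `curve_id`,
#'   `spheroid_id`, `zone`, `spring_constant`, `contact_true_um`,
#'   `young_modulus_true`, and a list-column `data` of per-curve tibbles with
#'   `piezo_height_um` and `deflection_um`.
#' @export
generate_force_map <- function(n_curves = 9,
                               young_modulus = 3000,
                               spring_constant = 0.15,
                               half_angle = 17.5,
                               poisson_ratio = 0.5,
                               max_force = 1e-9,
                               n_samples = 400,
                               contact_fraction = 0.45,
                               noise_sd = 3e-4,
                               spheroid_id = "synth-spheroid",
                               zone = seq_len(n_curves),
                               seed = NULL) {
  stopifnot(young_modulus > 0, spring_constant > 0, n_samples >= 50,
            contact_fraction > 0, contact_fraction < 1, max_force > 0)
  if (!is.null(seed)) set.seed(seed)
  zone <- rep_len(zone, n_curves)
  B <- sneddon_prefactor(young_modulus, half_angle, poisson_ratio) # N/m^2
  # ramp length: enough travel past contact to reach max_force
  delta_max <- sqrt(max_force / B) * 1e6                 # um indentation
  defl_max <- max_force / spring_constant * 1e6          # um deflection
  ramp <- (delta_max + defl_max) / (1 - contact_fraction)
  beta <- B * 1e-6 / spring_constant                     # 1/um
  curves <- lapply(seq_len(n_curves), function(i) {
    z <- seq(0, ramp, length.out = n_samples)
    z0 <- contact_fraction * ramp
    s <- pmax(0, z - z0)
    defl <- ((2 * beta * s + 1) - sqrt(4 * beta * s + 1)) / (2 * beta)
    defl <- defl + rnorm(n_samples, 0, noise_sd)
    tibble::tibble(piezo_height_um = z, deflection_um = defl)
  })
  out <- tibble::tibble(
    curve_id = sprintf("curve-%03d", seq_len(n_curves)),
    spheroid_id = spheroid_id,
    zone = zone,
    spring_constant = spring_constant,
    contact_true_um = contact_fraction * ramp,
    young_modulus_true = young_modulus,
    data = curves
  )
  class(out) <- c("force_map", class(out))
  out
}

#' Rasterize a synthetic spheroid as a voxel stack
#'
#' Renders a solid ellipsoid, centred in the stack, on the microscope's voxel
#' grid, with constant interior intensity plus Gaussian noise. Ground-truth
#' shape metrics are attached as attributes for closed-loop tests.
#'
#' @param semi_axes Ellipsoid semi-axes (x, y, z), micrometres.
#' @param voxel_size Voxel pitch (x, y, z), micrometres. Default
#'   `c(0.645, 0.645, 1)`.
#' @param intensity Interior intensity. Default 100.
#' @param noise_sd SD of additive Gaussian intensity noise. Default 0.
#' @param padding Empty margin around the ellipsoid, micrometres. Default 5.
#' @param seed Optional integer seed.
#' @return A 3D array (z, y, x) of intensities with attributes
#'   `voxel_size`, `true_volume` (um^3), `true_flatness`, `true_semi_axes`.
#' @export
generate_voxel_spheroid <- function(semi_axes,
                                    voxel_size = c(0.645, 0.645, 1),
                                    intensity = 100,
                                    noise_sd = 0,
                                    padding = 5,
                                    seed = NULL) {
  stopifnot(length(semi_axes) == 3L, all(semi_axes > 0),
            length(voxel_size) == 3L, all(voxel_size > 0))
  if (any(semi_axes < voxel_size)) {
    stop("ellipsoid is smaller than one voxel along some axis",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  nx <- ceiling(2 * (semi_axes[1] + padding) / voxel_size[1])
  ny <- ceiling(2 * (semi_axes[2] + padding) / voxel_size[2])
  nz <- ceiling(2 * (semi_axes[3] + padding) / voxel_size[3])
  # voxel-centre coordinates relative to the stack centre
  x <- (seq_len(nx) - (nx + 1) / 2) * voxel_size[1]
  y <- (seq_len(ny) - (ny + 1) / 2) * voxel_size[2]
  z <- (seq_len(nz) - (nz + 1) / 2) * voxel_size[3]
  qx <- (x / semi_axes[1])^2
  qy <- (y / semi_axes[2])^2
  qz <- (z / semi_axes[3])^2
  inside <- outer(outer(qz, qy, `+`), qx, `+`) <= 1    # (z, y, x)
  stack <- array(0, dim = c(nz, ny, nx))
  stack[inside] <- intensity
  if (noise_sd > 0) {
    stack <- stack + array(rnorm(length(stack), 0, noise_sd), dim = dim(stack))
  }
  attr(stack, "voxel_size") <- voxel_size
  attr(stack, "true_volume") <- 4 / 3 * pi * prod(semi_axes)
  attr(stack, "true_flatness") <- min(semi_axes) / max(semi_axes)
  attr(stack, "true_semi_axes") <- sort(semi_axes, decreasing = TRUE)
  stack
}

#' Hill growth-inhibition factor
#'
#' Fractional growth remaining at drug concentration `conc`:
#' \deqn{g(c) = 1 - I_{max} \frac{c^h}{c^h + K^h}.}
#'
#' @param conc Concentration(s), micromolar.
#' @param i_max Maximal inhibition, in `[0, 1]`.
#' @param k Half-inhibition concentration, micromolar.
#' @param h Hill slope. Default 1.
#' @return Numeric vector in `[1 - i_max, 1]`.
#' @examples
#' hill_inhibition(4, i_max = 1, k = 4)  # 0.5 at the midpoint
#' @export
hill_inhibition <- function(conc, i_max, k, h = 1) {
  stopifnot(all(conc >= 0), i_max >= 0, i_max <= 1, k > 0, h > 0)
  1 - i_max * conc^h / (conc^h + k^h)
}

#' Generate synthetic irinotecan dose-response trajectories
#'
#' Projected-area time courses for spheroids under increasing drug
#' concentration: area grows exponentially at a baseline rate scaled by the
#' Hill inhibition factor, with multiplicative lognormal noise on each
#' measured area. Concentration 0 (untreated control) must be present so the
#' normalization step has its reference.
#'
#' @param concentrations Micromolar doses, must include 0. Default
#'   `c(0, 1, 5, 10, 25, 50)`.
#' @param n_per_dose Spheroids per dose. Default 6.
#' @param i_max,k,h Hill parameters (see [hill_inhibition()]). Defaults 0.9,
#'   4 uM, 1.
#' @param baseline_rate Exponential area growth rate, per hour. Default 0.02.
#' @param area0 Initial projected area, um^2. Default 1.6e5 (a ~450 um
#'   spheroid).
#' @param noise_sd SD of the lognormal area noise (log scale). Default 0.02.
#' @param timepoints Hours, must include 0. Default `c(0, 24, 48)`.
#' @param condition Label for the condition column. Default "synthetic".
#' @param seed Optional integer seed.
#' @return A tibble with columns `spheroid_id`, `condition`,
#'   `concentration_uM`, `t_h`, `area_um2`, plus the ground-truth
#'   `growth_factor_true` (Hill factor per spheroid).
#' @export
generate_dose_response <- function(concentrations = c(0, 1, 5, 10, 25, 50),
                                   n_per_dose = 6,
                                   i_max = 0.9, k = 4, h = 1,
                                   baseline_rate = 0.02,
                                   area0 = 1.6e5,
                                   noise_sd = 0.02,
                                   timepoints = c(0, 24, 48),
                                   condition = "synthetic",
                                   seed = NULL) {
  stopifnot(all(concentrations >= 0), 0 %in% concentrations,
            0 %in% timepoints, n_per_dose >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(
    concentration_uM = concentrations,
    replicate = seq_len(n_per_dose)
  )
  grid$spheroid_id <- sprintf("%s-c%g-r%02d", condition,
                              grid$concentration_uM, grid$replicate)
  grid$growth_factor_true <- hill_inhibition(grid$concentration_uM, i_max, k, h)
  out <- tidyr::expand_grid(grid, t_h = timepoints)
  out$area_um2 <- area0 *
    exp(baseline_rate * out$growth_factor_true * out$t_h) *
    exp(rnorm(nrow(out), 0, noise_sd))
  out$condition <- condition
  dplyr::select(out, "spheroid_id", "condition", "concentration_uM", "t_h",
                "area_um2", "growth_factor_true")
}
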