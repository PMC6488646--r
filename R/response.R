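#' Simulated relaxation-index response curve
#'
#' Runs one forward incision simulation per entry of `depths` at a fixed
#' stored-stress magnitude and collects the relaxation index, giving the
#' model's response curve (relaxation index versus incision-depth fraction).
#'
#' @param gamma Stored-stress magnitude, arbitrary units, >= 0.
#' @param depths Incision depth fractions (of the diameter), each in
#'   (0, 0.85). Default `seq(0.40, 0.65, by = 0.05)`, the experimentally
#'   probed range.
#' @param exponent Power-law exponent of the stored-stress profile. Default 2.
#' @param material A [cg_material()].
#' @param radius Spheroid radius, micrometres. Default 225.
#' @param target_edge_length Mesh resolution, micrometres. Default
#'   `radius / 15`.
#' @param config A [solver_config()].
#' @return A tibble of class `response_curve` with columns `depth_fraction`
#'   and `relaxation_index`, and the generating parameters as attributes.
#' @examples
#' \donttest{
#' rc <- simulate_response_curve(0.2, depths = c(0.45, 0.55),
#'                               target_edge_length = 45)
#' rc
#' }
#' @export
simulate_response_curve <- function(gamma,
                                    depths = seq(0.40, 0.65, by = 0.05),
                                    exponent = 2,
                                    material = cg_material(),
                                    radius = 225,
                                    target_edge_length = radius / 15,
                                    config = solver_config()) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0,
            all(depths > 0 & depths < 0.85))
  profile <- stress_profile(gamma, exponent = exponent,
                            reference_radius = radius)
  ri <- vapply(depths, function(dep) {
    mesh <- incised_disk_mesh(radius, dep,
                              target_edge_length = target_edge_length)
    sol <- tryCatch(
      solve_equilibrium(mesh, material, profile, config),
      error = function(e) {
        stop(sprintf("forward solve failed at depth fraction %.3f: %s",
                     dep, conditionMessage(e)), call. = FALSE)
      }
    )
    measure_opening(sol)$relaxation_index
  }, numeric(1L))
  out <- tibble::tibble(depth_fraction = as.numeric(depths),
                        relaxation_index = ri)
  out <- out[order(out$depth_fraction), ]
  structure(out,
            gamma = gamma, exponent = exponent,
            poisson_ratio = material$poisson_ratio,
            cg_a_prime = material$cg_a_prime,
            radius = radius, target_edge_length = target_edge_length,
            class = c("response_curve", class(out)))
}

surface_key <- function(gammas, depths, exponent, material, radius,
                        target_edge_length) {
  list(
    gammas = as.numeric(gammas), depths = as.numeric(depths),
    exponent = exponent, poisson_ratio = material$poisson_ratio,
    cg_a_prime = material$cg_a_prime, shear_modulus = material$shear_modulus,
    radius = radius, target_edge_length = target_edge_length
  )
}

#' Response surface of the forward incision model
#'
#' Solves the forward model on a (gamma, depth) grid and returns the
#' relaxation-index surface that the stored-stress inference interpolates.
#' Because each solve is deterministic, the surface can be cached to a JSON
#' file; a cache whose build parameters match is reloaded instead of
#' re-solved.
#'
#' @param gammas Increasing grid of stored-stress magnitudes. Default 12
#'   points uniform on `[0.02, 0.45]`.
#' @param depths Grid of incision depth fractions. Default
#'   `seq(0.40, 0.65, by = 0.05)`.
#' @inheritParams simulate_response_curve
#' @param cache_file Optional path to a JSON cache.
#' @param verbose Report per-gamma progress. Default FALSE.
#' @return A tibble of class `response_surface` with columns `gamma`,
#'   `depth_fraction`, `relaxation_index`; build parameters as attributes.
#' @examples
#' \donttest{
#' surf <- response_surface(gammas = c(0.1, 0.3), depths = c(0.45, 0.55),
#'                          target_edge_length = 45)
#' predict_relaxation(surf, gamma = 0.2, depth_fraction = 0.5)
#' }
#' @export
response_surface <- function(gammas = seq(0.02, 0.45, length.out = 12),
                             depths = seq(0.40, 0.65, by = 0.05),
                             exponent = 2,
                             material = cg_material(),
                             radius = 225,
                             target_edge_length = radius / 15,
                             config = solver_config(),
                             cache_file = NULL,
                             verbose = FALSE) {
  stopifnot(length(gammas) >= 2L, !is.unsorted(gammas, strictly = TRUE),
            length(depths) >= 2L, all(gammas >= 0))
  key <- surface_key(gammas, depths, exponent, material, radius,
                     target_edge_length)
  if (!is.null(cache_file) && file.exists(cache_file)) {
    cached <- jsonlite::read_json(cache_file, simplifyVector = TRUE)
    if (isTRUE(all.equal(cached$key, key, tolerance = 1e-12))) {
      return(surface_from_table(tibble::as_tibble(cached$table), key))
    }
  }
  rows <- lapply(gammas, function(g) {
    if (verbose) message(sprintf("response curve at gamma = %.4f", g))
    rc <- simulate_response_curve(g, depths = depths, exponent = exponent,
                                  material = material, radius = radius,
                                  target_edge_length = target_edge_length,
                                  config = config)
    tibble::tibble(gamma = g, depth_fraction = rc$depth_fraction,
                   relaxation_index = rc$relaxation_index)
  })
  tab <- dplyr::bind_rows(rows)
  if (!is.null(cache_file)) {
    dir.create(dirname(cache_file), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(key = key, table = tab), cache_file,
                         auto_unbox = TRUE, digits = NA)
  }
  surface_from_table(tab, key)
}

surface_from_table <- function(tab, key) {
  structure(tab,
            gammas = key$gammas, depths = key$depths,
            exponent = key$exponent, poisson_ratio = key$poisson_ratio,
            cg_a_prime = key$cg_a_prime, radius = key$radius,
            target_edge_length = key$target_edge_length,
            class = c("response_surface", class(tab)))
}

#' Extract one response curve from a response surface
#'
#' @param surface A [response_surface()].
#' @param gamma One of the surface's gamma nodes.
#' @return A `response_curve` tibble.
#' @export
surface_curve <- function(surface, gamma) {
  stopifnot(inherits(surface, "response_surface"))
  gammas <- attr(surface, "gammas")
  i <- which(abs(gammas - gamma) < 1e-12)
  if (length(i) != 1L) {
    stop("`gamma` must be one of the surface's gamma nodes", call. = FALSE)
  }
  rows <- surface[abs(surface$gamma - gammas[i]) < 1e-12, ]
  out <- tibble::tibble(depth_fraction = rows$depth_fraction,
                        relaxation_index = rows$relaxation_index)
  structure(out, gamma = gammas[i], exponent = attr(surface, "exponent"),
            radius = attr(surface, "radius"),
            class = c("response_curve", class(out)))
}

#' Interpolate the relaxation index on a response surface
#'
#' Bilinear interpolation in (gamma, depth fraction). Extrapolation outside
#' the surface's grid is an error: the inference never extrapolates the
#' forward model.
#'
#' @param surface A [response_surface()].
#' @param gamma,depth_fraction Numeric vectors (recycled to common length).
#' @return Numeric vector of relaxation indices (percent).
#' @export
predict_relaxation <- function(surface, gamma, depth_fraction) {
  stopifnot(inherits(surface, "response_surface"))
  n <- max(length(gamma), length(depth_fraction))
  gamma <- rep_len(gamma, n)
  depth_fraction <- rep_len(depth_fraction, n)
  gg <- attr(surface, "gammas")
  dd <- sort(unique(surface$depth_fraction))
  if (any(gamma < min(gg) - 1e-12 | gamma > max(gg) + 1e-12)) {
    stop(sprintf("gamma outside the surface support [%.4g, %.4g]",
                 min(gg), max(gg)), call. = FALSE)
  }
  if (any(depth_fraction < min(dd) - 1e-12 |
            depth_fraction > max(dd) + 1e-12)) {
    stop(sprintf("depth fraction outside the surface support [%.4g, %.4g]",
                 min(dd), max(dd)), call. = FALSE)
  }
  Z <- matrix(NA_real_, length(gg), length(dd))
  ig <- match(round(surface$gamma, 12), round(gg, 12))
  id <- match(round(surface$depth_fraction, 12), round(dd, 12))
  Z[cbind(ig, id)] <- surface$relaxation_index
  if (anyNA(Z)) stop("response surface grid is incomplete", call. = FALSE)
  gi <- pmin(pmax(findInterval(gamma, gg), 1L), length(gg) - 1L)
  di <- pmin(pmax(findInterval(depth_fraction, dd), 1L), length(dd) - 1L)
  tg <- (gamma - gg[gi]) / (gg[gi + 1L] - gg[gi])
  td <- (depth_fraction - dd[di]) / (dd[di + 1L] - dd[di])
  (1 - tg) * (1 - td) * Z[cbind(gi, di)] +
    tg * (1 - td) * Z[cbind(gi + 1L, di)] +
    (1 - tg) * td * Z[cbind(gi, di + 1L)] +
    tg * td * Z[cbind(gi + 1L, di + 1L)]
}
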