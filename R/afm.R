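#' Sneddon prefactor for a conical indenter
#'
#' The force-indentation law for a rigid cone of half-angle alpha pressed
#' into an incompressible-to-compressible elastic half-space is
#' \deqn{F = \frac{2}{\pi}\frac{E}{1-\nu^2}\tan(\alpha)\,\delta^2.}
#' This helper returns the prefactor \eqn{B = (2/\pi) E \tan(\alpha)/(1-\nu^2)}
#' in N/m^2, so that `F = B * delta^2` with `delta` in metres.
#'
#' @param young_modulus Young's modulus E, Pa.
#' @param half_angle Tip half-angle alpha, degrees. Default 17.5 (MLCT probe).
#' @param poisson_ratio Sample Poisson ratio, in `[0, 0.5]`. Default 0.5
#'   (incompressible, in liquid).
#' @return Prefactor in N/m^2.
#' @export
sneddon_prefactor <- function(young_modulus, half_angle = 17.5,
                              poisson_ratio = 0.5) {
  stopifnot(all(young_modulus > 0), half_angle > 0, half_angle < 90,
            poisson_ratio >= 0, poisson_ratio <= 0.5)
  2 / pi * young_modulus / (1 - poisson_ratio^2) * tan(half_angle * pi / 180)
}

#' Conical Hertz-Sneddon force at a given indentation depth
#'
#' @param delta Indentation depth(s), metres, >= 0.
#' @inheritParams sneddon_prefactor
#' @return Force(s), Newtons.
#' @examples
#' sneddon_force(1e-6, 3000)  # ~8.03e-10 N at 1 um and 3 kPa
#' @export
sneddon_force <- function(delta, young_modulus, half_angle = 17.5,
                          poisson_ratio = 0.5) {
  if (any(delta < 0)) stop("indentation depth must be non-negative",
                           call. = FALSE)
  sneddon_prefactor(young_modulus, half_angle, poisson_ratio) * delta^2
}

# Discrete Gaussian kernel, unit sum, radius 3*sigma.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Smooth the deflection signal of an approach curve
#'
#' Convolves the vertical deflection with a discrete Gaussian kernel
#' (default SD 3 samples, the instrument-software convention read as sigma,
#' not FWHM), handling the endpoints by reflection.
#'
#' @param curve Tibble with columns `piezo_height_um` and `deflection_um`.
#' @param sigma Kernel SD in samples. Default 3.
#' @return The curve with `deflection_um` replaced by its smoothed version.
#' @export
smooth_approach <- function(curve, sigma = 3) {
  stopifnot(all(c("piezo_height_um", "deflection_um") %in% names(curve)))
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  y <- curve$deflection_um
  if (length(y) <= r) {
    stop("curve shorter than the smoothing kernel support", call. = FALSE)
  }
  padded <- c(rev(y[seq_len(r) + 1L]), y, rev(y[length(y) - seq_len(r)]))
  sm <- stats::filter(padded, k, sides = 2)
  out <- tibble::as_tibble(curve)
  out$deflection_um <- as.numeric(sm[r + seq_along(y)])
  out
}

#' Convert a force curve to an indentation (force vs. separation) curve
#'
#' Subtracts the pre-contact deflection baseline, converts deflection to
#' force through the spring constant, and computes the tip-sample separation
#' \eqn{\delta = (z - z_0) - d} past the contact point `z0`; only
#' post-contact samples (`delta >= 0`) are kept.
#'
#' @param curve Tibble with `piezo_height_um` and `deflection_um`.
#' @param contact_point Contact position on the piezo axis, micrometres.
#' @param spring_constant Cantilever spring constant, N/m.
#' @param baseline_fraction Fraction of the leading samples used for the
#'   baseline median. Default 0.2.
#' @param length_scale Metres per curve length unit. Default 1e-6
#'   (micrometres).
#' @return Tibble with `separation_m` and `force_n` (post-contact samples).
#' @export
to_indentation <- function(curve, contact_point, spring_constant,
                           baseline_fraction = 0.2, length_scale = 1e-6) {
  stopifnot(all(c("piezo_height_um", "deflection_um") %in% names(curve)),
            spring_constant > 0)
  z <- curve$piezo_height_um
  if (contact_point < min(z) || contact_point > max(z)) {
    stop("contact point outside the piezo range", call. = FALSE)
  }
  n_base <- max(1L, floor(baseline_fraction * nrow(curve)))
  baseline <- stats::median(curve$deflection_um[seq_len(n_base)])
  defl <- curve$deflection_um - baseline
  sep <- (z - contact_point) - defl
  keep <- z >= contact_point & sep >= 0
  tibble::tibble(
    separation_m = sep[keep] * length_scale,
    force_n = spring_constant * defl[keep] * length_scale
  )
}

#' Fit the conical Hertz-Sneddon model to one approach curve
#'
#' Smooths the deflection, estimates the contact point, and jointly fits the
#' Young's modulus and contact point by nonlinear least squares of
#' `F = B(E) * delta^2` on the post-contact segment, restricted to forces at
#' or below `max_force`. The modulus is profiled analytically for each
#' candidate contact point (the model is linear in `B`), leaving a robust
#' one-dimensional optimization over the contact point. Curves without a
#' detectable contact, with a non-positive fitted modulus, or with a modulus
#' outside the physically plausible window `[50 Pa, 1 MPa]` are flagged and
#' excluded from summaries.
#'
#' @param curve Tibble with `piezo_height_um` and `deflection_um`.
#' @param spring_constant Cantilever spring constant, N/m.
#' @inheritParams sneddon_prefactor
#' @param max_force Maximum force used for fitting, N. Default 1e-9 (1 nN).
#' @param sigma Smoothing kernel SD in samples (see [smooth_approach()]).
#' @param length_scale Metres per curve length unit. Default 1e-6.
#' @return An object of class `sneddon_fit`: `young_modulus_pa`,
#'   `contact_point_um`, `residual_rms_n`, `n_points`, `qc` (one of `"ok"`,
#'   `"no_contact"`, `"too_few_points"`, `"negative_modulus"`,
#'   `"out_of_range"`), plus fit metadata.
#' @export
fit_sneddon <- function(curve, spring_constant, half_angle = 17.5,
                        poisson_ratio = 0.5, max_force = 1e-9, sigma = 3,
                        length_scale = 1e-6) {
  stopifnot(spring_constant > 0)
  sm <- smooth_approach(curve, sigma = sigma)
  z <- sm$piezo_height_um
  n <- length(z)
  n_base <- max(5L, floor(0.2 * n))
  baseline <- stats::median(sm$deflection_um[seq_len(n_base)])
  noise_sd <- stats::sd(sm$deflection_um[seq_len(n_base)])
  noise_sd <- max(noise_sd, 1e-9)
  force_sm <- spring_constant * (sm$deflection_um - baseline) * length_scale

  make_fit <- function(qc, E = NA_real_, z0 = NA_real_, rms = NA_real_,
                       npts = 0L, ind = NULL) {
    structure(list(
      young_modulus_pa = E, contact_point_um = z0, residual_rms_n = rms,
      n_points = npts, qc = qc, half_angle = half_angle,
      poisson_ratio = poisson_ratio, spring_constant = spring_constant,
      max_force = max_force, indentation = ind
    ), class = "sneddon_fit")
  }

  above <- which(force_sm > 5 * noise_sd * spring_constant * length_scale)
  if (length(above) == 0L) return(make_fit("no_contact"))
  z0_init <- z[above[1L]]

  C <- sneddon_prefactor(1, half_angle, poisson_ratio)  # B per unit E
  rss_profiled <- function(z0) {
    ind <- to_indentation(sm, z0, spring_constant,
                          length_scale = length_scale)
    ok <- ind$force_n <= max_force
    if (sum(ok) < 10L) return(list(rss = Inf, E = NA_real_, n = sum(ok)))
    dlt <- ind$separation_m[ok]; f <- ind$force_n[ok]
    denom <- sum(dlt^4)
    if (denom <= 0) return(list(rss = Inf, E = NA_real_, n = sum(ok)))
    Bhat <- sum(f * dlt^2) / denom
    list(rss = sum((f - Bhat * dlt^2)^2), E = Bhat / C, n = sum(ok))
  }
  span <- diff(range(z))
  lo <- max(min(z), z0_init - 0.25 * span)
  hi <- min(max(z), z0_init + 0.1 * span)
  opt <- stats::optimize(function(z0) rss_profiled(z0)$rss,
                         interval = c(lo, hi), tol = span * 1e-6)
  best <- rss_profiled(opt$minimum)
  if (!is.finite(best$rss) || best$n < 10L) {
    return(make_fit("too_few_points", npts = best$n))
  }
  if (is.na(best$E) || best$E <= 0) {
    return(make_fit("negative_modulus", z0 = opt$minimum, npts = best$n))
  }
  ind <- to_indentation(sm, opt$minimum, spring_constant,
                        length_scale = length_scale)
  ind <- ind[ind$force_n <= max_force, ]
  qc <- if (best$E < 50 || best$E > 1e6) "out_of_range" else "ok"
  make_fit(qc, E = best$E, z0 = opt$minimum,
           rms = sqrt(best$rss / best$n), npts = best$n, ind = ind)
}

#' @export
print.sneddon_fit <- function(x, ...) {
  if (x$qc %in% c("ok", "out_of_range")) {
    cat(sprintf(
      "<sneddon_fit> E = %.4g Pa, contact at %.3f um, rms %.3g N, %d points [%s]\n",
      x$young_modulus_pa, x$contact_point_um, x$residual_rms_n, x$n_points,
      x$qc))
  } else {
    cat(sprintf("<sneddon_fit> rejected curve [%s]\n", x$qc))
  }
  invisible(x)
}

#' Fit every curve of a force map
#'
#' @param force_map A [generate_force_map()] result or a tibble with columns
#'   `curve_id`, `spheroid_id`, `zone`, `spring_constant` and a list-column
#'   `data` of curves.
#' @inheritParams fit_sneddon
#' @return A tibble with one row per curve: identifiers, `young_modulus_pa`,
#'   `contact_point_um`, `residual_rms_n`, `n_points`, `qc`.
#' @export
fit_force_map <- function(force_map, half_angle = 17.5, poisson_ratio = 0.5,
                          max_force = 1e-9, sigma = 3) {
  stopifnot(all(c("curve_id", "spheroid_id", "spring_constant", "data") %in%
                  names(force_map)))
  fits <- purrr::pmap(
    list(force_map$data, force_map$spring_constant),
    function(curve, k) {
      fit_sneddon(curve, k, half_angle = half_angle,
                  poisson_ratio = poisson_ratio, max_force = max_force,
                  sigma = sigma)
    }
  )
  tibble::tibble(
    curve_id = force_map$curve_id,
    spheroid_id = force_map$spheroid_id,
    zone = if ("zone" %in% names(force_map)) force_map$zone else NA,
    young_modulus_pa = purrr::map_dbl(fits, "young_modulus_pa"),
    contact_point_um = purrr::map_dbl(fits, "contact_point_um"),
    residual_rms_n = purrr::map_dbl(fits, "residual_rms_n"),
    n_points = purrr::map_int(fits, "n_points"),
    qc = purrr::map_chr(fits, "qc")
  )
}

#' Per-spheroid stiffness summary
#'
#' Mean apparent Young's modulus per spheroid over all accepted (`qc ==
#' "ok"`) curves; rejected curves are counted but excluded.
#'
#' @param fits A [fit_force_map()] table.
#' @return A tibble: `spheroid_id`, `mean_modulus_pa`, `n_curves`,
#'   `n_rejected`.
#' @export
spheroid_stiffness_summary <- function(fits) {
  stopifnot(all(c("spheroid_id", "young_modulus_pa", "qc") %in% names(fits)))
  fits |>
    dplyr::group_by(.data$spheroid_id) |>
    dplyr::summarise(
      mean_modulus_pa = mean(.data$young_modulus_pa[.data$qc == "ok"]),
      n_curves = sum(.data$qc == "ok"),
      n_rejected = sum(.data$qc != "ok"),
      .groups = "drop"
    )
}

#' Compare per-spheroid stiffness between two conditions
#'
#' Two-sided Mann-Whitney U comparison of the per-spheroid mean moduli of
#' two groups (exact enumeration for small combined samples, normal
#' approximation with tie correction otherwise; see [mann_whitney()]).
#'
#' @param group_a,group_b Numeric vectors of per-spheroid mean moduli, or
#'   [spheroid_stiffness_summary()] tables (column `mean_modulus_pa` is
#'   used). Each group needs >= 3 spheroids.
#' @return A one-row tibble: `n_a`, `n_b`, `median_a`, `median_b`,
#'   `statistic` (U), `p_value`, `method`.
#' @export
summarize_and_compare <- function(group_a, group_b) {
  pull_means <- function(g) {
    if (is.data.frame(g)) {
      stopifnot("mean_modulus_pa" %in% names(g))
      g$mean_modulus_pa
    } else {
      as.numeric(g)
    }
  }
  a <- pull_means(group_a); b <- pull_means(group_b)
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 per-spheroid means", call. = FALSE)
  }
  mw <- mann_whitney(a, b)
  tibble::tibble(
    n_a = length(a), n_b = length(b),
    median_a = stats::median(a), median_b = stats::median(b),
    statistic = mw$statistic, p_value = mw$p_value, method = mw$method
  )
}

#' Write a force map to a directory of TSV curves with JSON sidecars
#'
#' Each curve becomes `<curve_id>.tsv` (columns `piezo_height_um`,
#' `deflection_um`) plus `<curve_id>.json` carrying `spring_constant_n_per_m`,
#' `zone` and `spheroid_id`.
#'
#' @param force_map A force-map tibble (see [fit_force_map()] for the
#'   expected columns).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_force_map <- function(force_map, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(force_map))) {
    base <- file.path(dir, force_map$curve_id[i])
    utils::write.table(force_map$data[[i]], paste0(base, ".tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(spring_constant_n_per_m = force_map$spring_constant[i],
           zone = force_map$zone[i],
           spheroid_id = force_map$spheroid_id[i]),
      paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a directory of force curves written by [write_force_map()]
#'
#' @param dir Directory containing `*.tsv` curves and matching `*.json`
#'   sidecars.
#' @return A force-map tibble with columns `curve_id`, `spheroid_id`, `zone`,
#'   `spring_constant` and list-column `data`.
#' @export
read_force_curves <- function(dir) {
  tsvs <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(tsvs) == 0L) stop("no .tsv curves found in ", dir, call. = FALSE)
  rows <- lapply(tsvs, function(tsv) {
    meta_path <- sub("\\.tsv$", ".json", tsv)
    if (!file.exists(meta_path)) {
      stop("missing JSON sidecar for ", basename(tsv), call. = FALSE)
    }
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    tibble::tibble(
      curve_id = sub("\\.tsv$", "", basename(tsv)),
      spheroid_id = meta$spheroid_id,
      zone = meta$zone,
      spring_constant = meta$spring_constant_n_per_m,
      data = list(tibble::as_tibble(
        utils::read.delim(tsv, check.names = FALSE)))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("force_map", class(out))
  out
}
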