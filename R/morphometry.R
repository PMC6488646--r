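#' Threshold a voxel stack and keep the largest connected component
#'
#' Binarizes an intensity stack at a fixed threshold (the same threshold is
#' meant to be reused across conditions) and retains only the largest
#' 6-connected component, discarding debris and disconnected bright spots.
#'
#' @param stack 3D intensity array, dimensions (z, y, x).
#' @param threshold Intensity threshold; voxels `>= threshold` are foreground.
#'   Must lie within the stack's intensity range.
#' @return A logical array of the same dimensions, with attributes copied
#'   from the input (`voxel_size` in particular, when present).
#' @export
threshold_mask <- function(stack, threshold) {
  stopifnot(length(dim(stack)) == 3L, all(dim(stack) > 0))
  rng <- range(stack)
  if (threshold < rng[1] || threshold > rng[2]) {
    stop(sprintf("threshold %g outside the intensity range [%g, %g]",
                 threshold, rng[1], rng[2]), call. = FALSE)
  }
  mask <- stack >= threshold
  if (!any(mask)) stop("empty mask after thresholding", call. = FALSE)
  lab <- label_components_3d(mask)
  sizes <- tabulate(lab[mask])
  keep <- which.max(sizes)
  out <- array(lab == keep & mask, dim = dim(mask))
  vs <- attr(stack, "voxel_size")
  if (!is.null(vs)) attr(out, "voxel_size") <- vs
  out
}

# 6-connected component labelling of a logical 3D array via union-find on
# the adjacency graph of foreground voxels.
label_components_3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- integer(length(mask))
  if (length(idx) == 0L) return(array(lab, dim = d))
  edges <- list()
  strides <- c(1L, d[1L], d[1L] * d[2L])
  coords <- arrayInd(idx, d)
  for (ax in 1:3) {
    has_next <- coords[, ax] < d[ax]
    from <- idx[has_next]
    to <- from + strides[ax]
    ok <- mask[to]
    edges[[ax]] <- cbind(from[ok], to[ok])
  }
  e <- do.call(rbind, edges)
  if (is.null(e) || nrow(e) == 0L) {
    lab[idx] <- seq_along(idx)
    return(array(lab, dim = d))
  }
  g <- igraph::graph_from_edgelist(
    cbind(match(e[, 1L], idx), match(e[, 2L], idx)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  array(lab, dim = d)
}

#' Volume, principal semi-axes and flatness of a segmented spheroid
#'
#' Volume is the voxel count times the voxel volume. The principal semi-axes
#' come from the eigenvalues of the covariance of the foreground voxel
#' coordinates (in micrometres): for a uniform solid ellipsoid the semi-axis
#' along eigenvector i is \eqn{\sqrt{5 \lambda_i}}. Flatness is the shortest
#' over the longest semi-axis, 1 for a perfect sphere.
#'
#' @param mask Logical 3D array (z, y, x), e.g. from [threshold_mask()].
#' @param voxel_size Voxel pitch (x, y, z) in micrometres; defaults to the
#'   mask's `voxel_size` attribute, then to `c(0.645, 0.645, 1)`.
#' @return A one-row tibble: `volume_um3`, `flatness`, `axis_long_um`,
#'   `axis_mid_um`, `axis_short_um`, `n_voxels`.
#' @export
shape_metrics <- function(mask, voxel_size = NULL) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  voxel_size <- voxel_size %||% attr(mask, "voxel_size") %||%
    c(0.645, 0.645, 1)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  n_vox <- sum(mask)
  if (n_vox < 2L) {
    stop("mask is degenerate (fewer than 2 voxels)", call. = FALSE)
  }
  volume <- n_vox * prod(voxel_size)
  coords <- arrayInd(which(mask), dim(mask))  # (z, y, x) indices
  # scale to micrometres; axis order (x, y, z)
  pts <- cbind(coords[, 3L] * voxel_size[1L],
               coords[, 2L] * voxel_size[2L],
               coords[, 1L] * voxel_size[3L])
  ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  semi <- sqrt(5 * ev)   # uniform-ellipsoid identity
  semi <- sort(semi, decreasing = TRUE)
  tibble::tibble(
    volume_um3 = volume,
    flatness = semi[3L] / semi[1L],
    axis_long_um = semi[1L],
    axis_mid_um = semi[2L],
    axis_short_um = semi[3L],
    n_voxels = n_vox
  )
}

#' Per-spheroid growth rate relative to treatment start
#'
#' The growth rate at a timepoint is the projected area at that time divided
#' by the area when the drug was added (`t_h == 0`); an offset convention
#' `(area(t) - area(0)) / area(0)` is available as an alternative.
#'
#' @param trajectories Tibble with columns `spheroid_id`,
#'   `concentration_uM`, `t_h`, `area_um2` (e.g. from
#'   [generate_dose_response()]).
#' @param timepoint Hours after treatment start. Default 48.
#' @param convention `"ratio"` (default) or `"offset"`.
#' @return A tibble: `spheroid_id`, `concentration_uM`, `t_h`,
#'   `growth_rate`.
#' @export
growth_rate <- function(trajectories, timepoint = 48,
                        convention = c("ratio", "offset")) {
  convention <- match.arg(convention)
  needed <- c("spheroid_id", "concentration_uM", "t_h", "area_um2")
  stopifnot(all(needed %in% names(trajectories)))
  if (any(trajectories$area_um2 <= 0)) {
    stop("projected areas must be positive", call. = FALSE)
  }
  wide <- trajectories |>
    dplyr::filter(.data$t_h %in% c(0, timepoint)) |>
    dplyr::distinct(.data$spheroid_id, .data$concentration_uM, .data$t_h,
                    .keep_all = TRUE) |>
    tidyr::pivot_wider(id_cols = c("spheroid_id", "concentration_uM"),
                       names_from = "t_h", values_from = "area_um2",
                       names_prefix = "area_t")
  a0 <- wide[["area_t0"]]
  at <- wide[[paste0("area_t", timepoint)]]
  if (is.null(a0) || is.null(at) || anyNA(a0) || anyNA(at)) {
    stop(sprintf(
      "every spheroid needs areas at t = 0 and t = %g h", timepoint),
      call. = FALSE)
  }
  rate <- switch(convention, ratio = at / a0, offset = (at - a0) / a0)
  tibble::tibble(
    spheroid_id = wide$spheroid_id,
    concentration_uM = wide$concentration_uM,
    t_h = timepoint,
    growth_rate = rate
  )
}

#' Normalize mean growth rates to the untreated control
#'
#' Averages the growth rate within each concentration and divides by the
#' mean rate of the untreated (0 uM) group, which therefore maps to exactly 1.
#'
#' @param rates A [growth_rate()] table (single timepoint), columns
#'   `concentration_uM` and `growth_rate` (and optionally `t_h`).
#' @return A tibble: `concentration_uM`, `t_h` (if present),
#'   `mean_growth_rate`, `normalized_growth`, `n`.
#' @export
normalize_to_control <- function(rates) {
  stopifnot(all(c("concentration_uM", "growth_rate") %in% names(rates)))
  if (!any(rates$concentration_uM == 0)) {
    stop("no untreated (0 uM) control group to normalize against",
         call. = FALSE)
  }
  by_conc <- rates |>
    dplyr::group_by(.data$concentration_uM) |>
    dplyr::summarise(
      t_h = if ("t_h" %in% names(rates)) unique(.data$t_h)[1L] else NA_real_,
      mean_growth_rate = mean(.data$growth_rate),
      n = dplyr::n(), .groups = "drop"
    )
  control <- by_conc$mean_growth_rate[by_conc$concentration_uM == 0]
  dplyr::mutate(by_conc,
                normalized_growth = .data$mean_growth_rate / control)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. For combined sample sizes
#' up to `exact_max` the null distribution of U is enumerated exhaustively
#' over all group assignments of the pooled midranks (so ties are handled
#' exactly); larger samples use the normal approximation with the usual tie
#' correction and no continuity correction. The statistic reported is
#' \eqn{U_A}, the number of (a, b) pairs with a > b, counting ties as 1/2.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param exact_max Combined size at or below which the exact enumeration is
#'   used. Default 16.
#' @return A one-row tibble: `statistic` (U), `p_value`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, exact_max = 16) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)   # midranks
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (N <= exact_max) {
    picks <- utils::combn(N, n1)
    Us <- colSums(matrix(r[picks], nrow = n1)) - n1 * (n1 + 1) / 2
    tol <- 1e-9
    p <- 2 * min(mean(Us <= U_obs + tol), mean(Us >= U_obs - tol))
    p <- min(1, p)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U_obs - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  tibble::tibble(statistic = U_obs, p_value = p, method = method)
}
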