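#' Triangular mesh of an incised disk
#'
#' Builds a conforming linear-triangle mesh of the circular cross-section of a
#' spheroid through the incision plane, with a straight radial slit entering
#' from the boundary along a diameter (the positive x-axis). Nodes lying on the
#' slit are duplicated into an upper and a lower face so the cut can open; the
#' slit tip is a single shared node. The mesh is a structured polar grid with
#' one ring snapped so that the slit tip lies exactly at depth
#' `depth_fraction * 2 * radius` from the entry point; depths beyond 0.5 carry
#' the slit through the center onto the opposite half-diameter.
#'
#' @param radius Disk radius, micrometres. Default 225.
#' @param depth_fraction Incision depth as a fraction of the diameter, in
#'   (0, 0.85).
#' @param slit_half_width Initial half-opening of the slit faces, micrometres.
#'   Default 0 (geometrically coincident faces).
#' @param target_edge_length Nominal element edge length, micrometres.
#'   Default `radius / 15`.
#' @return An object of class `incised_mesh`: list with `nodes` (n x 2 matrix,
#'   um), `elements` (m x 3 integer matrix, counter-clockwise), boundary tags
#'   (`boundary_outer`, `slit_pairs` upper/lower id matrix, `tip_id`,
#'   `pin_xy`, `pin_y`), the build parameters, and `min_quality` (twice
#'   inradius over circumradius, 1 for equilateral).
#' @examples
#' m <- incised_disk_mesh(225, 0.5, target_edge_length = 30)
#' m$tip_id
#' @export
incised_disk_mesh <- function(radius = 225, depth_fraction,
                              slit_half_width = 0,
                              target_edge_length = radius / 15) {
  if (!is.numeric(radius) || radius <= 0) {
    stop("`radius` must be positive", call. = FALSE)
  }
  if (!is.numeric(depth_fraction) || length(depth_fraction) != 1L ||
      depth_fraction <= 0 || depth_fraction >= 0.85) {
    stop("`depth_fraction` must be in (0, 0.85)", call. = FALSE)
  }
  if (slit_half_width < 0 || slit_half_width > radius / 10) {
    stop("`slit_half_width` must be small and non-negative", call. = FALSE)
  }
  R <- radius
  n_ring <- max(6L, as.integer(round(R / target_edge_length)))
  n_ang <- 2L * max(10L, as.integer(round(pi * R / target_edge_length)))

  radii <- R * seq_len(n_ring) / n_ring
  x_tip <- R - 2 * R * depth_fraction
  r_tip <- abs(x_tip)
  tip_at_center <- r_tip < 1e-12 * R
  if (!tip_at_center) {
    # snap the nearest interior ring onto the tip radius (outer ring is fixed)
    k <- which.min(abs(radii[-n_ring] - r_tip))
    radii[k] <- r_tip
    if (is.unsorted(radii, strictly = TRUE)) {
      stop("slit tip could not be accommodated by the ring grid", call. = FALSE)
    }
  }

  theta <- 2 * pi * (seq_len(n_ang) - 1L) / n_ang
  node_id <- function(i, j) 1L + (i - 1L) * n_ang + ((j - 1L) %% n_ang) + 1L
  xs <- c(0, as.vector(t(outer(radii, cos(theta)))))
  ys <- c(0, as.vector(t(outer(radii, sin(theta)))))
  # exact zeros on the seam line
  ys[abs(ys) < 1e-9 * R] <- 0

  # fan around the center, then quads split into two triangles
  j <- seq_len(n_ang)
  jp <- c(seq_len(n_ang)[-1L], 1L)
  tri <- rbind(
    cbind(1L, node_id(1L, j), node_id(1L, jp))
  )
  for (i in seq_len(n_ring - 1L)) {
    a <- node_id(i, j); b <- node_id(i, jp)
    c2 <- node_id(i + 1L, jp); d <- node_id(i + 1L, j)
    tri <- rbind(tri, cbind(a, c2, b), cbind(a, d, c2))
  }
  dimnames(tri) <- NULL

  # slit nodes: on the x-axis with x strictly beyond the tip
  eps <- 1e-9 * R
  on_axis <- ys == 0
  seam <- which(on_axis & xs > x_tip + eps)
  tip_id <- if (tip_at_center) 1L else {
    cand <- which(on_axis & abs(xs - x_tip) < eps)
    if (length(cand) != 1L) stop("slit tip node not found", call. = FALSE)
    cand
  }
  seam <- setdiff(seam, tip_id)
  if (length(seam) == 0L) {
    stop("incision too shallow for this resolution", call. = FALSE)
  }

  # duplicate seam nodes; originals serve the upper face (centroid y > 0)
  n_orig <- length(xs)
  copies <- n_orig + seq_along(seam)
  xs <- c(xs, xs[seam]); ys <- c(ys, ys[seam])
  cent_y <- (ys[tri[, 1L]] + ys[tri[, 2L]] + ys[tri[, 3L]]) / 3
  lower <- which(cent_y < 0)
  remap <- seq_len(n_orig)
  remap[seam] <- copies
  tri[lower, ] <- matrix(remap[tri[lower, ]], ncol = 3L)
  if (slit_half_width > 0) {
    ys[seam] <- slit_half_width
    ys[copies] <- -slit_half_width
  }

  nodes <- cbind(x = xs, y = ys)
  # orientation check: all signed areas positive
  v1x <- nodes[tri[, 2L], 1L] - nodes[tri[, 1L], 1L]
  v1y <- nodes[tri[, 2L], 2L] - nodes[tri[, 1L], 2L]
  v2x <- nodes[tri[, 3L], 1L] - nodes[tri[, 1L], 1L]
  v2y <- nodes[tri[, 3L], 2L] - nodes[tri[, 1L], 2L]
  area2 <- v1x * v2y - v1y * v2x
  if (any(area2 <= 0)) stop("degenerate or inverted element in mesh",
                            call. = FALSE)

  # quality: 2 * inradius / circumradius per triangle
  e1 <- sqrt(v1x^2 + v1y^2)
  e2 <- sqrt(v2x^2 + v2y^2)
  e3 <- sqrt((v2x - v1x)^2 + (v2y - v1y)^2)
  s <- (e1 + e2 + e3) / 2
  area <- area2 / 2
  quality <- 8 * area^2 / (s * e1 * e2 * e3) # 2 r_in / r_circ, 1 = equilateral
  min_quality <- min(quality)
  if (min_quality < 0.05) stop("mesh quality below threshold", call. = FALSE)

  outer_ids <- c(node_id(n_ring, j), copies[match(
    intersect(seam, node_id(n_ring, j)), seam)])
  outer_ids <- outer_ids[!is.na(outer_ids)]

  # rigid-body constraints: boundary node opposite the slit mouth and the
  # next x-axis node inward (neither may sit on the slit)
  pin_xy <- node_id(n_ring, n_ang / 2L + 1L)
  axis_inward <- node_id(seq(n_ring - 1L, 1L), n_ang / 2L + 1L)
  axis_inward <- axis_inward[!(axis_inward %in% seam) & axis_inward != tip_id]
  if (pin_xy %in% seam || length(axis_inward) == 0L) {
    stop("incision too deep: no free diameter left to anchor the mesh",
         call. = FALSE)
  }
  pin_y <- axis_inward[1L]

  structure(list(
    nodes = nodes, elements = tri,
    boundary_outer = outer_ids,
    slit_pairs = cbind(upper = seam, lower = copies),
    tip_id = tip_id, pin_xy = pin_xy, pin_y = pin_y,
    radius = R, depth_fraction = depth_fraction,
    slit_half_width = slit_half_width,
    target_edge_length = target_edge_length,
    n_ring = n_ring, n_ang = n_ang,
    min_quality = min_quality
  ), class = "incised_mesh")
}

#' @export
print.incised_mesh <- function(x, ...) {
  cat(sprintf(
    "<incised_mesh> R = %.4g um, depth = %.2f of diameter\n  %d nodes, %d elements, %d slit node pairs, min quality %.2f\n",
    x$radius, x$depth_fraction, nrow(x$nodes), nrow(x$elements),
    nrow(x$slit_pairs), x$min_quality))
  invisible(x)
}

#' Mesh nodes and elements as tibbles
#'
#' @param mesh An [incised_disk_mesh()].
#' @return A list of two tibbles, `nodes` (id, x, y, um) and `elements`
#'   (element id and the three node ids).
#' @export
mesh_as_tables <- function(mesh) {
  stopifnot(inherits(mesh, "incised_mesh"))
  list(
    nodes = tibble::tibble(id = seq_len(nrow(mesh$nodes)),
                           x = mesh$nodes[, 1L], y = mesh$nodes[, 2L]),
    elements = tibble::tibble(element = seq_len(nrow(mesh$elements)),
                              n1 = mesh$elements[, 1L],
                              n2 = mesh$elements[, 2L],
                              n3 = mesh$elements[, 3L])
  )
}
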