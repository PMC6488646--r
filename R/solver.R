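#' Solver configuration for the incision equilibrium problem
#'
#' @param n_load_steps Number of increments over which the stored stress is
#'   ramped from 0 to its full magnitude. Default 5.
#' @param rtol Relative residual tolerance per load step. Default 1e-8.
#' @param max_iter Maximum Newton iterations per load step. Default 30.
#' @param verbose Print per-iteration residual norms. Default FALSE.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(n_load_steps = 5, rtol = 1e-8, max_iter = 30,
                          verbose = FALSE) {
  stopifnot(n_load_steps >= 1, rtol > 0, max_iter >= 1)
  structure(list(n_load_steps = as.integer(n_load_steps), rtol = rtol,
                 max_iter = as.integer(max_iter), verbose = isTRUE(verbose)),
            class = "solver_config")
}

# Scatter-add `vals` into a vector of length `n` at (possibly repeated) `idx`.
accumulate_at <- function(idx, vals, n) {
  out <- numeric(n)
  rs <- rowsum(vals, idx)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

# Per-element P1 geometry: areas and shape-function gradients.
element_geometry <- function(mesh) {
  E <- mesh$elements
  x1 <- mesh$nodes[E[, 1L], 1L]; y1 <- mesh$nodes[E[, 1L], 2L]
  x2 <- mesh$nodes[E[, 2L], 1L]; y2 <- mesh$nodes[E[, 2L], 2L]
  x3 <- mesh$nodes[E[, 3L], 1L]; y3 <- mesh$nodes[E[, 3L], 2L]
  area2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  Bx <- cbind(y2 - y3, y3 - y1, y1 - y2) / area2
  By <- cbind(x3 - x2, x1 - x3, x2 - x1) / area2
  list(E = E, area = area2 / 2,
       Bx = Bx, By = By,
       cx = (x1 + x2 + x3) / 3, cy = (y1 + y2 + y3) / 3)
}

# Reference-configuration stored stress (plane symmetry) at element
# centroids. Growth-induced stored stress is compressive in the core: a
# magnitude gamma means sigma_rr(0) = -gamma, so the field entering the
# solver is minus the magnitude-positive profile components. This is what
# makes a partial cut gape at the mouth (and the core swell into it) rather
# than close.
element_prestress <- function(geo, profile) {
  r <- sqrt(geo$cx^2 + geo$cy^2)
  r <- pmin(r, profile$reference_radius)
  comp <- stored_stress_components(r, profile, symmetry_mode = "plane")
  ct <- geo$cx / pmax(r, 1e-12)
  st <- geo$cy / pmax(r, 1e-12)
  list(
    xx = -(comp$sigma_rr * ct^2 + comp$sigma_tt * st^2),
    yy = -(comp$sigma_rr * st^2 + comp$sigma_tt * ct^2),
    xy = -((comp$sigma_rr - comp$sigma_tt) * ct * st)
  )
}

# Deformation gradient components per element from the interleaved
# displacement vector u = (ux1, uy1, ux2, uy2, ...).
deformation_state <- function(geo, u) {
  E <- geo$E
  ux <- u[c(TRUE, FALSE)]
  uy <- u[c(FALSE, TRUE)]
  UxE <- matrix(ux[E], ncol = 3L)
  UyE <- matrix(uy[E], ncol = 3L)
  F11 <- 1 + rowSums(UxE * geo$Bx)
  F12 <- rowSums(UxE * geo$By)
  F21 <- rowSums(UyE * geo$Bx)
  F22 <- 1 + rowSums(UyE * geo$By)
  list(F11 = F11, F12 = F12, F21 = F21, F22 = F22,
       J = F11 * F22 - F12 * F21)
}

# Total potential energy: sum over elements of area * (W(F) + 0.5 F S0 : F).
# The pre-stress term is the potential whose gradient is F %*% S0.
potential_energy <- function(geo, st, material, S0) {
  # plane strain: the I2 term reduces to I1- and J^2-terms, giving
  # effective in-plane coefficients a+b and c+b
  a <- material$a + material$b; cc <- material$c + material$b
  d <- material$d
  I1 <- st$F11^2 + st$F12^2 + st$F21^2 + st$F22^2 + 1
  W <- a * (I1 - 3) + cc * (st$J^2 - 1) - d * log(st$J)
  pre <- 0.5 * (S0$xx * (st$F11^2 + st$F21^2) +
                  S0$yy * (st$F12^2 + st$F22^2) +
                  2 * S0$xy * (st$F11 * st$F12 + st$F21 * st$F22))
  sum(geo$area * (W + pre))
}

# Internal nodal force vector (length 2n) of the pre-stressed body,
# P_total(F) = P_elastic(F) + F %*% S0, plane strain, P1 elements.
internal_forces <- function(geo, st, material, S0, n_nodes) {
  # plane strain: the I2 term reduces to I1- and J^2-terms, giving
  # effective in-plane coefficients a+b and c+b
  a <- material$a + material$b; cc <- material$c + material$b
  d <- material$d
  J <- st$J
  coef <- 2 * cc * J^2 - d
  B11 <- st$F22 / J; B12 <- -st$F21 / J
  B21 <- -st$F12 / J; B22 <- st$F11 / J
  P11 <- 2 * a * st$F11 + coef * B11 + st$F11 * S0$xx + st$F12 * S0$xy
  P12 <- 2 * a * st$F12 + coef * B12 + st$F11 * S0$xy + st$F12 * S0$yy
  P21 <- 2 * a * st$F21 + coef * B21 + st$F21 * S0$xx + st$F22 * S0$xy
  P22 <- 2 * a * st$F22 + coef * B22 + st$F21 * S0$xy + st$F22 * S0$yy
  idx <- integer(0); vals <- numeric(0)
  for (aa in 1:3) {
    ids <- geo$E[, aa]
    idx <- c(idx, 2L * ids - 1L, 2L * ids)
    vals <- c(vals,
              geo$area * (P11 * geo$Bx[, aa] + P12 * geo$By[, aa]),
              geo$area * (P21 * geo$Bx[, aa] + P22 * geo$By[, aa]))
  }
  accumulate_at(idx, vals, 2L * n_nodes)
}

# Consistent tangent stiffness (sparse 2n x 2n, symmetric).
tangent_stiffness <- function(geo, st, material, S0, n_nodes) {
  # plane strain: the I2 term reduces to I1- and J^2-terms, giving
  # effective in-plane coefficients a+b and c+b
  a <- material$a + material$b; cc <- material$c + material$b
  d <- material$d
  J <- st$J
  coef <- 2 * cc * J^2 - d
  B11 <- st$F22 / J; B12 <- -st$F21 / J
  B21 <- -st$F12 / J; B22 <- st$F11 / J
  # p[[aa]] = F^{-T} grad N_aa per element (x and y components)
  px <- vector("list", 3L); py <- vector("list", 3L)
  for (aa in 1:3) {
    px[[aa]] <- B11 * geo$Bx[, aa] + B12 * geo$By[, aa]
    py[[aa]] <- B21 * geo$Bx[, aa] + B22 * geo$By[, aa]
  }
  nel <- nrow(geo$E)
  ii <- integer(36L * nel); jj <- integer(36L * nel); xx <- numeric(36L * nel)
  pos <- 0L
  for (aa in 1:3) {
    for (bb in 1:3) {
      q_ab <- geo$Bx[, aa] * geo$Bx[, bb] + geo$By[, aa] * geo$By[, bb]
      s_ab <- geo$Bx[, aa] * (S0$xx * geo$Bx[, bb] + S0$xy * geo$By[, bb]) +
        geo$By[, aa] * (S0$xy * geo$Bx[, bb] + S0$yy * geo$By[, bb])
      diag_part <- 2 * a * q_ab + s_ab
      pa <- list(px[[aa]], py[[aa]])
      pb <- list(px[[bb]], py[[bb]])
      for (i in 1:2) {
        for (k in 1:2) {
          val <- geo$area * ((i == k) * diag_part +
                               4 * cc * J^2 * pa[[i]] * pb[[k]] -
                               coef * pb[[i]] * pa[[k]])
          rng <- pos + seq_len(nel)
          ii[rng] <- 2L * geo$E[, aa] - (2L - i)
          jj[rng] <- 2L * geo$E[, bb] - (2L - k)
          xx[rng] <- val
          pos <- pos + nel
        }
      }
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(2L * n_nodes, 2L * n_nodes))
}

#' Solve the incised, pre-stressed spheroid cross-section to equilibrium
#'
#' Minimizes the total energy of a plane-strain hyperelastic disk carrying the
#' stored-stress field of `profile`, with the slit and outer boundary
#' traction-free. The stored stress enters as an additive
#' reference-configuration stress \eqn{S_0} pushed forward with the
#' deformation, \eqn{P = P_{el}(F) + F S_0}; \eqn{S_0} is ramped up in load
#' increments, each solved by Newton's method with backtracking. Rigid-body
#' modes are removed by pinning the boundary node opposite the slit mouth and
#' the vertical motion of its inward neighbour on the same diameter.
#'
#' @param mesh An [incised_disk_mesh()].
#' @param material A [cg_material()].
#' @param profile A [stress_profile()] whose `reference_radius` should equal
#'   the mesh radius.
#' @param config A [solver_config()].
#' @return An object of class `spheroid_equilibrium`: nodal displacements `U`
#'   (n x 2, um), `residual_norm`, per-step Newton iteration counts `steps`,
#'   `min_det_F`, plus the inputs.
#' @examples
#' m <- incised_disk_mesh(225, 0.5, target_edge_length = 45)
#' sol <- solve_equilibrium(m, cg_material(), stress_profile(0.2))
#' measure_opening(sol)
#' @export
solve_equilibrium <- function(mesh, material = cg_material(),
                              profile = stress_profile(0.2),
                              config = solver_config()) {
  stopifnot(inherits(mesh, "incised_mesh"), inherits(material, "cg_material"),
            inherits(profile, "stress_profile"),
            inherits(config, "solver_config"))
  if (abs(profile$reference_radius - mesh$radius) >
      1e-6 * mesh$radius) {
    stop("profile reference_radius must match the mesh radius", call. = FALSE)
  }
  n_nodes <- nrow(mesh$nodes)
  geo <- element_geometry(mesh)
  S0_full <- element_prestress(geo, profile)
  fixed <- c(2L * mesh$pin_xy - 1L, 2L * mesh$pin_xy, 2L * mesh$pin_y)
  free <- setdiff(seq_len(2L * n_nodes), fixed)

  u <- numeric(2L * n_nodes)
  history <- integer(0)
  final_norm <- 0
  # incremental loading with adaptive refinement: a target load level that
  # fails to converge is re-attempted from the last converged state at half
  # the increment
  targets <- seq_len(config$n_load_steps) / config$n_load_steps
  t_done <- 0
  u_done <- u
  n_splits <- 0L
  while (length(targets) > 0L) {
    t_load <- targets[1L]
    S0 <- list(xx = t_load * S0_full$xx, yy = t_load * S0_full$yy,
               xy = t_load * S0_full$xy)
    st <- deformation_state(geo, u)
    f <- internal_forces(geo, st, material, S0, n_nodes)
    norm0 <- sqrt(sum(f[free]^2))
    if (config$verbose) {
      message(sprintf("load level %.4f: |r0| = %.3e", t_load, norm0))
    }
    it <- 0L
    norm_cur <- norm0
    step_failed <- FALSE
    while (norm_cur > config$rtol * max(norm0, 1e-14) && norm_cur > 1e-14) {
      if (it >= config$max_iter) {
        step_failed <- TRUE
        break
      }
      K <- tangent_stiffness(geo, st, material, S0, n_nodes)
      du <- Matrix::solve(K[free, free, drop = FALSE], -f[free])
      du <- as.numeric(du)
      # Armijo backtracking on the total potential energy, whose gradient is
      # the residual; guards against element inversion (det F <= 0)
      energy_cur <- potential_energy(geo, st, material, S0)
      slope <- sum(f[free] * du)
      alpha <- 1
      repeat {
        u_try <- u
        u_try[free] <- u[free] + alpha * du
        st_try <- deformation_state(geo, u_try)
        if (min(st_try$J) > 0) {
          energy_try <- potential_energy(geo, st_try, material, S0)
          if (energy_try <= energy_cur + 1e-4 * alpha * slope ||
              alpha < 1 / 1024) break
        }
        alpha <- alpha / 2
        if (alpha < 1 / 4096) {
          step_failed <- TRUE
          break
        }
      }
      if (step_failed) break
      u <- u_try; st <- st_try
      f <- internal_forces(geo, st, material, S0, n_nodes)
      norm_cur <- sqrt(sum(f[free]^2))
      it <- it + 1L
      if (config$verbose) {
        message(sprintf("  it %d: |r| = %.3e (alpha = %.3g)", it, norm_cur,
                        alpha))
      }
    }
    if (step_failed) {
      n_splits <- n_splits + 1L
      if (n_splits > 12L) {
        stop(sprintf(
          "Newton did not converge (stuck near load level %.4f after %d subdivisions; iteration history: %s)",
          t_load, n_splits, paste(history, collapse = ", ")), call. = FALSE)
      }
      targets <- c((t_done + t_load) / 2, targets)
      u <- u_done
      next
    }
    history <- c(history, it)
    final_norm <- norm_cur
    t_done <- t_load
    u_done <- u
    targets <- targets[-1L]
  }
  st <- deformation_state(geo, u)
  U <- cbind(u[c(TRUE, FALSE)], u[c(FALSE, TRUE)])
  structure(list(
    U = U, residual_norm = final_norm, steps = history,
    min_det_F = min(st$J), mesh = mesh, material = material,
    profile = profile, config = config
  ), class = "spheroid_equilibrium")
}

#' @export
print.spheroid_equilibrium <- function(x, ...) {
  cat(sprintf(
    "<spheroid_equilibrium> gamma = %.4g, |r| = %.2e, iterations: %s, min det F = %.3f\n",
    x$profile$magnitude, x$residual_norm,
    paste(x$steps, collapse = "/"), x$min_det_F))
  invisible(x)
}

#' Opening distance and relaxation index of a solved incision
#'
#' The opening distance is the largest Euclidean separation, in the deformed
#' configuration, between corresponding node pairs on the two slit faces,
#' minus their initial separation; it is floored at zero. The relaxation index
#' is `100 * opening / diameter` with the pre-cut diameter as reference.
#'
#' @param solution A [solve_equilibrium()] result.
#' @param mesh The mesh the solution was computed on (defaults to the one
#'   carried by the solution).
#' @return A one-row tibble: `opening_um`, `diameter_um`, `relaxation_index`.
#' @export
measure_opening <- function(solution, mesh = solution$mesh) {
  stopifnot(inherits(solution, "spheroid_equilibrium"),
            inherits(mesh, "incised_mesh"))
  pairs <- mesh$slit_pairs
  def <- mesh$nodes + solution$U
  dx <- def[pairs[, 1L], 1L] - def[pairs[, 2L], 1L]
  dy <- def[pairs[, 1L], 2L] - def[pairs[, 2L], 2L]
  sep <- sqrt(dx^2 + dy^2)
  dx0 <- mesh$nodes[pairs[, 1L], 1L] - mesh$nodes[pairs[, 2L], 1L]
  dy0 <- mesh$nodes[pairs[, 1L], 2L] - mesh$nodes[pairs[, 2L], 2L]
  sep0 <- sqrt(dx0^2 + dy0^2)
  opening <- max(0, max(sep - sep0))
  diameter <- 2 * mesh$radius
  tibble::tibble(
    opening_um = opening,
    diameter_um = diameter,
    relaxation_index = 100 * opening / diameter
  )
}
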