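#' Compressible Ciarlet-Geymonat material parameters
#'
#' Builds the coefficient set of a compressible Ciarlet-Geymonat-family strain
#' energy
#' \deqn{W(F) = a\,(I_1 - 3) + b\,(I_2 - 3) + c\,(J^2 - 1) - d\,\log J,}
#' where \eqn{I_1 = \mathrm{tr}(F^T F)}, \eqn{I_2} is the second invariant of
#' \eqn{F^T F} and \eqn{J = \det F}. The family is parameterized here by the
#' small-strain Poisson ratio \eqn{\nu} and a dimensionless shape parameter
#' \eqn{a'} in (0, 1] that sets the share of the shear response carried by
#' the \eqn{I_1} term. The map used is the canonical Ciarlet-Geymonat split
#' \eqn{a = a' \mu_L / 2}, \eqn{b = (1 - a') \mu_L / 2},
#' \eqn{c = \lambda_L / 4 - b} and \eqn{d = 2a + 4b + 2c}, with \eqn{\mu_L}
#' the linearized shear modulus (normalized to 1, so all stresses are in the
#' same arbitrary units) and \eqn{\lambda_L = 2 \mu_L \nu / (1 - 2\nu)}.
#' Under this map the linearized response has exactly the Lame constants
#' \eqn{(\mu_L, \lambda_L)}, and the choice of \eqn{d} makes the first
#' Piola-Kirchhoff stress vanish exactly at \eqn{F = I}, so the unloaded
#' reference configuration is stress-free.
#'
#' @param poisson_ratio Small-strain Poisson ratio, in (0, 0.5). Default 0.46
#'   (a nearly incompressible soft tissue).
#' @param cg_a_prime Dimensionless Ciarlet-Geymonat shape parameter, > 0.
#'   Default 0.4.
#' @param shear_modulus Small-strain shear modulus \eqn{\mu_L} in arbitrary
#'   stress units. Default 1 (stress unit = shear modulus).
#'
#' @return An object of class `cg_material`: a list with elements
#'   `poisson_ratio`, `cg_a_prime`, `shear_modulus`, `lambda` and the energy
#'   coefficients `a`, `b`, `c`, `d`.
#'
#' @examples
#' mat <- cg_material(0.46, 0.4)
#' cg_stress(mat, diag(3))        # zero at the identity
#' @export
cg_material <- function(poisson_ratio = 0.46, cg_a_prime = 0.4,
                        shear_modulus = 1) {
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1L ||
      poisson_ratio <= 0 || poisson_ratio >= 0.5) {
    stop("`poisson_ratio` must be a single number in (0, 0.5)", call. = FALSE)
  }
  if (!is.numeric(cg_a_prime) || length(cg_a_prime) != 1L ||
      cg_a_prime <= 0 || cg_a_prime > 1) {
    stop("`cg_a_prime` must be a single number in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(shear_modulus) || length(shear_modulus) != 1L ||
      shear_modulus <= 0) {
    stop("`shear_modulus` must be a single positive number", call. = FALSE)
  }
  mu <- shear_modulus
  lambda <- 2 * mu * poisson_ratio / (1 - 2 * poisson_ratio)
  a <- cg_a_prime * mu / 2
  b <- (1 - cg_a_prime) * mu / 2
  c <- lambda / 4 - b
  d <- 2 * a + 4 * b + 2 * c
  out <- list(
    poisson_ratio = poisson_ratio, cg_a_prime = cg_a_prime,
    shear_modulus = mu, lambda = lambda, a = a, b = b, c = c, d = d
  )
  class(out) <- "cg_material"
  # sanity: tangent at F = I is positive definite on symmetric strains
  # (rigid rotations are energy-neutral to second order, so the full
  # 9x9 Hessian is only semi-definite)
  tang <- cg_tangent_identity(out)
  sym_basis <- list(
    c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3)
  )
  Bmat <- vapply(sym_basis, function(ij) {
    Emat <- matrix(0, 3, 3)
    Emat[ij[1], ij[2]] <- Emat[ij[2], ij[1]] <- 1
    as.vector(Emat)
  }, numeric(9L))
  tang_sym <- crossprod(Bmat, tang %*% Bmat)
  if (min(eigen(tang_sym, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("derived coefficients do not give a stable response at the identity",
         call. = FALSE)
  }
  out
}

#' @export
print.cg_material <- function(x, ...) {
  cat("<cg_material> Ciarlet-Geymonat strain energy\n")
  cat(sprintf("  nu = %.3f, a' = %.3f, mu_L = %.3g (a.u.)\n",
              x$poisson_ratio, x$cg_a_prime, x$shear_modulus))
  cat(sprintf("  W = %.4g (I1-3) + %.4g (I2-3) + %.4g (J^2-1) - %.4g log J\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Strain-energy density of a Ciarlet-Geymonat material
#'
#' @param material A [cg_material()].
#' @param F A 3x3 deformation-gradient matrix with `det(F) > 0`.
#' @return Scalar energy density (arbitrary stress units).
#' @export
cg_energy <- function(material, F) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (J <= 0) stop("deformation gradient must have positive determinant",
                   call. = FALSE)
  C <- crossprod(F)
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  material$a * (I1 - 3) + material$b * (I2 - 3) +
    material$c * (J^2 - 1) - material$d * log(J)
}

#' First Piola-Kirchhoff stress of a Ciarlet-Geymonat material
#'
#' With `b = 0` the stress is
#' \eqn{P(F) = 2 a F + (2 c J^2 - d) F^{-T}}.
#'
#' @inheritParams cg_energy
#' @return A 3x3 matrix, arbitrary stress units.
#' @export
cg_stress <- function(material, F) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (J <= 0) stop("deformation gradient must have positive determinant",
                   call. = FALSE)
  Finv <- solve(F)
  P <- 2 * material$a * F + (2 * material$c * J^2 - material$d) * t(Finv)
  if (material$b != 0) {
    C <- crossprod(F)
    I1 <- sum(diag(C))
    P <- P + 2 * material$b * (I1 * F - F %*% C)
  }
  P
}

# 9x9 tangent d2W/dF dF at F = I by central differences of cg_stress,
# rows/cols in column-major vec(F) ordering. Used as a numerical stability
# check at construction and by the small-strain tests.
cg_tangent_identity <- function(material, h = 1e-6) {
  A <- matrix(0, 9L, 9L)
  for (q in 1:9) {
    Fp <- diag(3); Fp[q] <- Fp[q] + h
    Fm <- diag(3); Fm[q] <- Fm[q] - h
    A[, q] <- (as.vector(cg_stress(material, Fp)) -
                 as.vector(cg_stress(material, Fm))) / (2 * h)
  }
  (A + t(A)) / 2
}
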