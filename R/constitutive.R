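#' Material parameter set for one tissue region
#'
#' Parameters of the fibre-reinforced hyperelastic model used for the corneal
#' and limbal tissue and, with `k1 = 0`, for the isotropic sclera. `C10`
#' governs the extracellular-matrix (ground substance) stiffness, `k1` the
#' stiffness of the collagen fibres and `k2` their exponential non-linearity.
#' Near-incompressibility is enforced through a volumetric penalty modulus
#' `bulk_penalty` that must dominate `C10` by at least three orders of
#' magnitude.
#'
#' @param C10 matrix stiffness, MPa; must be positive.
#' @param k1 fibre stiffness, MPa; zero for an unreinforced (Neo-Hookean)
#'   material.
#' @param k2 dimensionless fibre non-linearity; required positive when
#'   `k1 > 0`.
#' @param fibre_directions list of unit 3-vectors: empty for the sclera, one
#'   circumferential family for the limbus, two mutually orthogonal families
#'   (nasal-temporal and superior-inferior) for the cornea.
#' @param bulk_penalty volumetric penalty modulus, MPa; defaults to
#'   `2000 * C10`.
#' @return object of class `material_params`.
#' @examples
#' material_params(C10 = 0.045, k1 = 0.027, k2 = 180,
#'                 fibre_directions = list(c(1, 0, 0), c(0, 0, 1)))
#' @export
material_params <- function(C10, k1 = 0, k2 = NULL,
                            fibre_directions = list(),
                            bulk_penalty = 2000 * C10) {
  if (!is.numeric(C10) || length(C10) != 1L || C10 <= 0)
    stop_wiop("C10 must be a single positive stress [MPa]")
  if (k1 < 0) stop_wiop("k1 must be non-negative")
  if (k1 > 0 && (is.null(k2) || k2 <= 0))
    stop_wiop("k2 must be positive when k1 > 0")
  if (is.null(k2)) k2 <- 1
  if (bulk_penalty < 1e3 * C10)
    stop_wiop("bulk_penalty must exceed C10 by at least 1e3")
  if (length(fibre_directions) > 2L)
    stop_wiop("at most two fibre families are supported")
  fibre_directions <- lapply(fibre_directions, function(a) {
    a <- as.numeric(a)
    if (length(a) != 3L) stop_wiop("fibre directions must be 3-vectors")
    n <- sqrt(sum(a^2))
    if (n < .Machine$double.eps) stop_wiop("fibre direction has zero length")
    a / n
  })
  structure(
    list(C10 = C10, k1 = k1, k2 = k2,
         fibre_directions = fibre_directions,
         bulk_penalty = bulk_penalty),
    class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("<material_params> C10 = %g MPa, k1 = %g MPa, k2 = %g, %d fibre famil%s\n",
              x$C10, x$k1, x$k2, length(x$fibre_directions),
              if (length(x$fibre_directions) == 1L) "y" else "ies"))
  invisible(x)
}

# exponential fibre energy density per family, as a function of the (squared
# stretch) pseudo-invariant I. Tension-only: inactive for I <= 1.
# Overflow guard: exponents beyond `cap` indicate a material instability.
fibre_psi <- function(I, k1, k2, cap = 700) {
  ex <- k2 * (I - 1)^2
  if (any(ex[k1 > 0 & I > 1] > cap))
    stop_wiop("material instability: fibre exponent k2*(I-1)^2 exceeds ", cap)
  out <- k1 / (2 * k2) * (exp(ex) - 1)
  out[I <= 1] <- 0
  out
}

# d(fibre_psi)/dI
fibre_dpsi <- function(I, k1, k2, cap = 700) {
  ex <- k2 * (I - 1)^2
  if (any(ex[k1 > 0 & I > 1] > cap))
    stop_wiop("material instability: fibre exponent k2*(I-1)^2 exceeds ", cap)
  out <- k1 * (I - 1) * exp(ex)
  out[I <= 1] <- 0
  out
}

# isochoric energy density from isochoric invariants (vectorised)
hgo_psi_iso <- function(I1b, I4b, I6b, C10, k1, k2) {
  C10 * (I1b - 3) +
    fibre_psi(I4b, k1, k2) +
    fibre_psi(I6b, k1, k2)
}

#' Kinematic state at a material point
#'
#' Wraps a deformation gradient together with the derived quantities used by
#' the constitutive laws: the Jacobian `J`, the isochoric right Cauchy-Green
#' tensor and its first invariant, and the fibre pseudo-invariants (squared
#' fibre stretches) for up to two fibre families.
#'
#' @param F 3x3 deformation gradient; `det(F)` must be positive.
#' @param a4,a6 reference unit fibre directions (3-vectors) of the first and
#'   second family; `NULL` for an unreinforced material.
#' @return object of class `deformation_state` with elements `F`, `J`, `C`,
#'   `I1b`, `I4b`, `I6b`.
#' @examples
#' deformation_state(diag(3))
#' @export
deformation_state <- function(F, a4 = c(1, 0, 0), a6 = c(0, 0, 1)) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L))) stop_wiop("F must be a 3x3 matrix")
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop_wiop("non-positive Jacobian: deformation is not admissible")
  C <- crossprod(F) # t(F) %*% F
  sc <- J^(-2 / 3)
  I1b <- sc * sum(diag(C))
  I4b <- if (is.null(a4)) NA_real_ else sc * drop(crossprod(a4, C %*% a4))
  I6b <- if (is.null(a6)) NA_real_ else sc * drop(crossprod(a6, C %*% a6))
  structure(list(F = F, J = J, C = C, I1b = I1b, I4b = I4b, I6b = I6b,
                 a4 = a4, a6 = a6),
            class = "deformation_state")
}

#' @export
print.deformation_state <- function(x, ...) {
  cat(sprintf("<deformation_state> J = %.6g, I1b = %.6g, I4b = %.6g, I6b = %.6g\n",
              x$J, x$I1b, x$I4b, x$I6b))
  invisible(x)
}

#' Strain-energy densities of the tissue models
#'
#' `hgo_energy()` evaluates the isochoric fibre-reinforced energy
#' \deqn{\bar\Psi = C_{10}(\bar I_1 - 3) +
#'   \frac{k_1}{2k_2}\sum_{i=4,6}\left[e^{k_2(\bar I_i-1)^2}-1\right],}
#' with tension-only fibre terms (a family contributes only when its
#' pseudo-invariant exceeds one). `neohookean_energy()` is the isotropic
#' special case \eqn{C_{10}(\bar I_1 - 3)} used for the sclera, and
#' `volumetric_energy()` is the near-incompressibility penalty
#' \eqn{U(J) = K(J-1)^2/2}.
#'
#' @param state a [deformation_state()].
#' @param params a [material_params()].
#' @return energy density in MPa (= mJ/mm^3).
#' @examples
#' p <- material_params(0.045, 0.027, 180,
#'                      list(c(1, 0, 0), c(0, 0, 1)))
#' hgo_energy(deformation_state(diag(3)), p)  # zero at identity
#' @export
hgo_energy <- function(state, params) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(params, "material_params"))
  nf <- length(params$fibre_directions)
  I4b <- if (nf >= 1L) state$I4b else 1
  I6b <- if (nf >= 2L) state$I6b else 1
  hgo_psi_iso(state$I1b, I4b, I6b, params$C10, params$k1, params$k2)
}

#' @rdname hgo_energy
#' @export
neohookean_energy <- function(state, params) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(params, "material_params"))
  params$C10 * (state$I1b - 3)
}

#' @rdname hgo_energy
#' @param J volume ratio det(F).
#' @param bulk_penalty penalty modulus, MPa.
#' @export
volumetric_energy <- function(J, bulk_penalty) {
  bulk_penalty / 2 * (J - 1)^2
}

#' Stress of the fibre-reinforced hyperelastic model
#'
#' Analytic stress consistent with [hgo_energy()] plus the volumetric penalty
#' [volumetric_energy()]. The second Piola-Kirchhoff stress is
#' \eqn{S = 2\,\partial\Psi/\partial C}; the first Piola-Kirchhoff stress is
#' \eqn{P = FS} and the Cauchy stress \eqn{\sigma = J^{-1} F S F^T}.
#'
#' @param state a [deformation_state()]. Fibre directions are taken from the
#'   state; only as many families as `params` declares are active.
#' @param params a [material_params()].
#' @param type which stress measure to return.
#' @return 3x3 stress matrix, MPa.
#' @examples
#' p <- material_params(0.045, 0.027, 180, list(c(1, 0, 0), c(0, 0, 1)))
#' hgo_stress(deformation_state(diag(3)), p)  # zero at identity
#' @export
hgo_stress <- function(state, params, type = c("cauchy", "pk1", "pk2")) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(params, "material_params"))
  type <- match.arg(type)
  F <- state$F; J <- state$J; C <- state$C
  Cinv <- solve(C)
  sc <- J^(-2 / 3)
  I1 <- sum(diag(C))
  Id <- diag(3)

  S <- 2 * params$C10 * sc * (Id - I1 / 3 * Cinv)

  nf <- length(params$fibre_directions)
  dirs <- list(state$a4, state$a6)
  Ibs <- c(state$I4b, state$I6b)
  if (nf >= 1L) {
    for (f in seq_len(nf)) {
      a <- dirs[[f]]
      if (is.null(a)) stop_wiop("state lacks fibre direction for family ", f)
      Ib <- Ibs[f]
      dpsi <- fibre_dpsi(Ib, params$k1, params$k2)
      if (dpsi != 0) {
        A <- tcrossprod(a)          # a %o% a
        I_unbar <- drop(crossprod(a, C %*% a))
        S <- S + 2 * dpsi * sc * (A - I_unbar / 3 * Cinv)
      }
    }
  }
  # volumetric part
  S <- S + params$bulk_penalty * (J - 1) * J * Cinv

  switch(type,
         pk2 = S,
         pk1 = F %*% S,
         cauchy = (F %*% S %*% t(F)) / J)
}

#' Total strain-energy density (isochoric + volumetric)
#'
#' Convenience wrapper used in energy-stress consistency checks: the energy
#' whose gradient with respect to the deformation gradient equals the first
#' Piola-Kirchhoff stress returned by [hgo_stress()].
#'
#' @inheritParams hgo_stress
#' @return energy density, MPa.
#' @export
hgo_total_energy <- function(state, params) {
  hgo_energy(state, params) +
    volumetric_energy(state$J, params$bulk_penalty)
}
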