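test_that("energies vanish at identity and reduce correctly", {
  p_hgo <- material_params(0.045, 0.027, 180, list(c(1, 0, 0), c(0, 0, 1)))
  p_nh <- material_params(0.35)
  id <- deformation_state(diag(3))
  expect_equal(hgo_energy(id, p_hgo), 0)
  expect_equal(neohookean_energy(id, p_nh), 0)
  expect_equal(hgo_stress(id, p_hgo), matrix(0, 3, 3))

  # k1 = 0 reduces the fibre model exactly to the isotropic matrix term
  p0 <- material_params(0.045, 0, NULL, list(c(1, 0, 0), c(0, 1, 0)))
  for (i in 1:20) {
    st <- deformation_state(random_small_F())
    expect_equal(hgo_energy(st, p0), neohookean_energy(st, p0))
  }
})

test_that("equi-biaxial stretch reproduces the directly evaluated energy", {
  # independent arithmetic evaluation of the energy formula at
  # lambda = 1.05 equi-biaxial, incompressible, with the standard corneal
  # constants (C10 = 0.045 MPa, k1 = 0.027 MPa, k2 = 180):
  # I1 = 2*1.05^2 + 1.05^-4 = 3.0277025, I4 = I6 = 1.1025
  psi_expected <- 0.00209063431481465
  F <- diag(c(1.05, 1.05, 1 / 1.05^2))
  p <- material_params(0.045, 0.027, 180, list(c(1, 0, 0), c(0, 1, 0)))
  st <- deformation_state(F, a4 = c(1, 0, 0), a6 = c(0, 1, 0))
  expect_equal(hgo_energy(st, p), psi_expected, tolerance = 1e-12)
})

test_that("uniaxial isochoric stretch matches the closed form", {
  p <- material_params(0.35)
  for (lam in c(0.9, 1.02, 1.2)) {
    F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
    st <- deformation_state(F)
    expect_equal(neohookean_energy(st, p),
                 0.35 * (lam^2 + 2 / lam - 3), tolerance = 1e-12)
  }
})

test_that("analytic stress matches the numerical energy gradient", {
  set.seed(11)
  p <- material_params(0.045, 0.027, 180, list(c(1, 0, 0), c(0, 1, 0)))
  h <- 1e-6
  for (i in 1:100) {
    F <- random_small_F()
    st <- deformation_state(F, a4 = c(1, 0, 0), a6 = c(0, 1, 0))
    P <- hgo_stress(st, p, type = "pk1")
    Pnum <- matrix(0, 3, 3)
    for (a in 1:3) for (b in 1:3) {
      Fp <- F; Fp[a, b] <- Fp[a, b] + h
      Fm <- F; Fm[a, b] <- Fm[a, b] - h
      ep <- hgo_total_energy(deformation_state(Fp, c(1, 0, 0), c(0, 1, 0)), p)
      em <- hgo_total_energy(deformation_state(Fm, c(1, 0, 0), c(0, 1, 0)), p)
      Pnum[a, b] <- (ep - em) / (2 * h)
    }
    expect_lt(max(abs(P - Pnum)) / max(abs(Pnum)), 1e-4)
  }
  # Cauchy stress is symmetric
  st <- deformation_state(random_small_F(), c(1, 0, 0), c(0, 1, 0))
  sig <- hgo_stress(st, p)
  expect_equal(sig, t(sig), tolerance = 1e-10)
})

test_that("energy is frame-indifferent and monotone in the invariants", {
  set.seed(7)
  p <- material_params(0.045, 0.027, 180, list(c(1, 0, 0), c(0, 1, 0)))
  for (i in 1:20) {
    F <- random_small_F()
    qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qr_d)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    e1 <- hgo_energy(deformation_state(F, c(1, 0, 0), c(0, 1, 0)), p)
    e2 <- hgo_energy(deformation_state(Q %*% F, c(1, 0, 0), c(0, 1, 0)), p)
    expect_equal(e1, e2, tolerance = 1e-10)
  }
  # monotone growth of the matrix term in I1 and of the fibre term in I4
  lams <- seq(1.01, 1.2, length.out = 10)
  e_bi <- vapply(lams, function(l) {
    st <- deformation_state(diag(c(l, l, 1 / l^2)), c(1, 0, 0), c(0, 1, 0))
    hgo_energy(st, p)
  }, 0)
  expect_true(all(diff(e_bi) > 0))
  # convex, exponentially stiffening uniaxial fibre response
  sig <- vapply(lams, function(l) {
    st <- deformation_state(diag(c(l, 1 / sqrt(l), 1 / sqrt(l))),
                            c(1, 0, 0), c(0, 1, 0))
    hgo_stress(st, p)[1, 1]
  }, 0)
  expect_true(all(diff(sig) > 0))
  expect_true(all(diff(diff(sig)) > 0))
})

test_that("fibres are tension-only and instability is flagged", {
  p <- material_params(0.045, 0.027, 180, list(c(1, 0, 0), c(0, 1, 0)))
  # equibiaxial compression leaves only the matrix term
  F <- diag(c(0.97, 0.97, 1 / 0.97^2))
  st <- deformation_state(F, c(1, 0, 0), c(0, 1, 0))
  expect_equal(hgo_energy(st, p),
               0.045 * (st$I1b - 3), tolerance = 1e-12)
  # overflow guard
  F2 <- diag(c(4, 0.5, 0.5))
  expect_error(hgo_energy(deformation_state(F2, c(1, 0, 0), c(0, 1, 0)), p),
               "instability")
  # invalid kinematics and parameters are rejected
  expect_error(deformation_state(-diag(3)), "Jacobian")
  expect_error(material_params(-1), "C10")
  expect_error(material_params(0.05, 0.01, NULL), "k2")
  expect_error(material_params(0.05, bulk_penalty = 0.05), "bulk_penalty")
})
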