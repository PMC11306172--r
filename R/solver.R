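# Internal axisymmetric membrane solver.
#
# The globe wall is a chain of ring membrane elements in (r, y); each element
# carries the incompressible plane-stress specialisation of the regional
# strain-energy function (fibre-reinforced for cornea/limbus, Neo-Hookean for
# sclera). Thickness change follows exactly from in-plane stretches
# (lambda3 = 1/(lambda1*lambda2)), so no volumetric penalty enters the wall
# and the critical time step is governed by the in-plane tangent stiffness.
# The humor cavity couples through a follower pressure load P * grad(V),
# which makes the discrete pressure power exactly P * dV/dt.

new_sim <- function(mesh, materials) {
  stopifnot(inherits(mesh, "eye_mesh"))
  reg <- as.character(mesh$region)
  mat_of <- function(region) materials[[region]]
  C10e <- unname(vapply(reg, function(g) mat_of(g)$C10, 0))
  k1e  <- unname(vapply(reg, function(g) mat_of(g)$k1, 0))
  k2e  <- unname(vapply(reg, function(g) mat_of(g)$k2, 0))
  fam  <- ifelse(reg == "cornea", 2L, ifelse(reg == "limbus", 1L, 0L))

  r0 <- mesh$nodes[, 1L]; y0 <- mesh$nodes[, 2L]
  i1 <- mesh$elements[, 1L]; i2 <- mesh$elements[, 2L]
  L0 <- sqrt((r0[i2] - r0[i1])^2 + (y0[i2] - y0[i1])^2)
  RmSum0 <- r0[i1] + r0[i2]
  A0e <- pi * RmSum0 * L0               # frustum lateral area
  V0e <- A0e * mesh$thickness           # reference material volume

  me <- .TISSUE_DENSITY * V0e
  n <- length(r0)
  m <- c(me / 2, 0) + c(0, me / 2)      # lumped nodal masses (chain)

  # rotation-free bending sites: one per node from the apex (mirror-symmetric
  # virtual neighbour across the axis) to the penultimate node. Flexural
  # rigidity D = E t^3 / (12 (1 - nu^2)) from the matrix modulus E = 6 C10
  # (incompressible), lumped with the reference nodal area.
  A_node <- lumped_ring_areas(r0, y0, mesh$elements)
  t_node <- c(mesh$thickness[1L],
              (mesh$thickness[-length(mesh$thickness)] +
                 mesh$thickness[-1L]) / 2,
              mesh$thickness[length(mesh$thickness)])
  C10_node <- c(C10e[1L], (C10e[-length(C10e)] + C10e[-1L]) / 2,
                C10e[length(C10e)])
  D_node <- 6 * C10_node * t_node^3 / (12 * 0.75)
  lbar0 <- c(L0[1L], (L0[-length(L0)] + L0[-1L]) / 2, L0[length(L0)])
  c_bend <- D_node * A_node / lbar0^2
  cornea_node <- rep(FALSE, n)
  cornea_node[unique(as.integer(mesh$elements[reg == "cornea", ]))] <- TRUE
  psi0 <- bending_angles(r0, y0, n)

  list(mesh = mesh, n = n, i1 = i1, i2 = i2,
       L0 = L0, RmSum0 = RmSum0, V0e = V0e,
       C10e = C10e, k1e = k1e, k2e = k2e, fam = fam,
       cornea_el = which(reg == "cornea"),
       c_bend = c_bend, psi0 = psi0, cornea_node = cornea_node,
       m = m, fixed = mesh$fixed,
       r = r0, y = y0, vr = numeric(n), vy = numeric(n),
       t = 0,
       cavity = list(mode = "off", P0 = 0, V0 = NA_real_, Kf = 5),
       contact = NULL, puff = NULL)
}

# enclosed cavity volume of the revolved meridian (signed; positive for the
# apex-to-pole ordering used by build_eye_mesh)
cavity_volume <- function(r, y, i1, i2) {
  Q <- r[i1]^2 + r[i1] * r[i2] + r[i2]^2
  sum(pi * Q * (y[i1] - y[i2])) / 3
}

# gradient of the enclosed volume w.r.t. nodal coordinates; also the nodal
# outward vector areas. `subset` restricts to a patch of elements.
volume_gradient <- function(r, y, i1, i2, n, subset = NULL) {
  if (!is.null(subset)) { i1 <- i1[subset]; i2 <- i2[subset] }
  dy <- y[i1] - y[i2]
  g_r1 <- pi * (2 * r[i1] + r[i2]) * dy / 3
  g_r2 <- pi * (r[i1] + 2 * r[i2]) * dy / 3
  Q3 <- pi * (r[i1]^2 + r[i1] * r[i2] + r[i2]^2) / 3
  gr <- numeric(n); gy <- numeric(n)
  # chain connectivity: element k joins nodes k and k+1 within the subset
  gr[i1] <- gr[i1] + g_r1; gy[i1] <- gy[i1] + Q3
  gr[i2] <- gr[i2] + g_r2; gy[i2] <- gy[i2] - Q3
  list(r = gr, y = gy)
}

# signed turn angles of the meridian polyline at bending sites 1..n-1
# (site 1 is the apex, whose previous neighbour is the mirror image of node 2
# across the symmetry axis)
bending_angles <- function(r, y, n) {
  pr_r <- c(-r[2L], r[seq_len(n - 2L)])
  pr_y <- c(y[2L], y[seq_len(n - 2L)])
  cu <- seq_len(n - 1L)
  nx <- cu + 1L
  ur <- r[cu] - pr_r; uy <- y[cu] - pr_y
  vr <- r[nx] - r[cu]; vy <- y[nx] - y[cu]
  atan2(ur * vy - uy * vr, ur * vr + uy * vy)
}

# bending forces and per-site energies of the rotation-free shell hinge
bending_forces <- function(r, y, n, c_bend, psi0) {
  pr_r <- c(-r[2L], r[seq_len(n - 2L)])
  pr_y <- c(y[2L], y[seq_len(n - 2L)])
  cu <- seq_len(n - 1L)
  nx <- cu + 1L
  ur <- r[cu] - pr_r; uy <- y[cu] - pr_y
  vr <- r[nx] - r[cu]; vy <- y[nx] - y[cu]
  u2 <- ur^2 + uy^2; v2 <- vr^2 + vy^2
  psi <- atan2(ur * vy - uy * vr, ur * vr + uy * vy)
  cb <- c_bend[cu]
  dpsi <- psi - psi0
  mom <- cb * dpsi
  # grad(angle(a)) = perp(a)/|a|^2 with perp((x,y)) = (-y, x)
  Pu_r <- -uy / u2; Pu_y <- ur / u2
  Pv_r <- -vy / v2; Pv_y <- vr / v2
  fr <- numeric(n); fy <- numeric(n)
  # F_cur = + mom (P_u + P_v); F_next = - mom P_v; F_prev = - mom P_u
  fr[cu] <- fr[cu] + mom * (Pu_r + Pv_r)
  fy[cu] <- fy[cu] + mom * (Pu_y + Pv_y)
  fr[nx] <- fr[nx] - mom * Pv_r
  fy[nx] <- fy[nx] - mom * Pv_y
  # prev nodes: sites 2..n-1 map to nodes 1..n-2; the apex site's "previous"
  # node is the mirror of node 2 (r-component sign flips through the mirror)
  pi2 <- 2:(n - 1L)
  fr[pi2 - 1L] <- fr[pi2 - 1L] - mom[pi2] * Pu_r[pi2]
  fy[pi2 - 1L] <- fy[pi2 - 1L] - mom[pi2] * Pu_y[pi2]
  fr[2L] <- fr[2L] + mom[1L] * Pu_r[1L]     # mirrored: dprev_r/dr_2 = -1
  fy[2L] <- fy[2L] - mom[1L] * Pu_y[1L]
  list(fr = fr, fy = fy, energy = cb * dpsi^2 / 2)
}

# in-plane stretch measures of every element in the current configuration
element_stretches <- function(sim, r = sim$r, y = sim$y) {
  dr <- r[sim$i2] - r[sim$i1]
  dy <- y[sim$i2] - y[sim$i1]
  l <- sqrt(dr^2 + dy^2)
  list(lam1 = l / sim$L0,
       lam2 = (r[sim$i1] + r[sim$i2]) / sim$RmSum0,
       l = l, ur = dr / l, uy = dy / l)
}

# dPsi/dlam1, dPsi/dlam2 of the plane-stress incompressible wall energy
membrane_dpsi <- function(lam1, lam2, C10e, k1e, k2e, fam, cap = 80) {
  inv12 <- 1 / (lam1^2 * lam2^2)
  if (any(!is.finite(lam1)) || any(!is.finite(lam2)) ||
      any(lam1 > 2.5) || any(lam2 > 2.5) ||
      any(lam1 < 0.3) || any(lam2 < 0.3))
    stop_wiop("membrane instability: element stretch left the admissible range")
  dP1 <- C10e * (2 * lam1 - 2 * inv12 / lam1)
  dP2 <- C10e * (2 * lam2 - 2 * inv12 / lam2)
  mer <- fam == 2L
  circ <- fam >= 1L
  if (any(mer)) {
    I4 <- lam1[mer]^2
    dP1[mer] <- dP1[mer] +
      2 * lam1[mer] * fibre_dpsi(I4, k1e[mer], k2e[mer], cap = cap)
  }
  if (any(circ)) {
    I6 <- lam2[circ]^2
    dP2[circ] <- dP2[circ] +
      2 * lam2[circ] * fibre_dpsi(I6, k1e[circ], k2e[circ], cap = cap)
  }
  list(dP1 = dP1, dP2 = dP2)
}

# wall strain-energy density per element
membrane_psi <- function(lam1, lam2, C10e, k1e, k2e, fam, cap = 80) {
  I1 <- lam1^2 + lam2^2 + 1 / (lam1^2 * lam2^2)
  psi <- C10e * (I1 - 3)
  mer <- fam == 2L
  circ <- fam >= 1L
  if (any(mer))
    psi[mer] <- psi[mer] + fibre_psi(lam1[mer]^2, k1e[mer], k2e[mer], cap = cap)
  if (any(circ))
    psi[circ] <- psi[circ] + fibre_psi(lam2[circ]^2, k1e[circ], k2e[circ], cap = cap)
  psi
}

# air-puff pressure field (MPa) on the anterior corneal nodes
puff_pressure <- function(puff, r_ant, recession, t) {
  pr <- puff$profile
  tau <- (t - puff$onset_abs) / pr$duration
  if (tau <= 0 || tau >= 1) return(numeric(length(r_ant)))
  s <- switch(pr$shape,
              sin2 = sin(pi * tau)^2,
              triangle = 1 - abs(2 * tau - 1),
              stop_wiop("unknown puff waveform: ", pr$shape))
  g <- exp(-(r_ant / pr$footprint_radius)^2)
  p <- mmhg_to_mpa(pr$peak_pressure) * s * g
  if (pr$coupling > 0)
    p <- p / (1 + pr$coupling * pmax(recession, 0))
  p
}

# assemble nodal forces; returns forces, cavity pressure, per-node air
# pressure and the mass force (if a contact scenario is active)
sim_forces <- function(sim, r = sim$r, y = sim$y, t = sim$t,
                       ym = if (!is.null(sim$contact)) sim$contact$ym else NA) {
  st <- element_stretches(sim, r, y)
  dp <- membrane_dpsi(st$lam1, st$lam2, sim$C10e, sim$k1e, sim$k2e, sim$fam)
  c1 <- sim$V0e * dp$dP1 / sim$L0
  c2 <- sim$V0e * dp$dP2 / sim$RmSum0
  lo_r <- c1 * st$ur - c2
  hi_r <- -c1 * st$ur - c2
  lo_y <- c1 * st$uy
  hi_y <- -c1 * st$uy
  fr <- c(lo_r, 0) + c(0, hi_r)
  fy <- c(lo_y, 0) + c(0, hi_y)

  bf <- bending_forces(r, y, sim$n, sim$c_bend, sim$psi0)
  fr <- fr + bf$fr
  fy <- fy + bf$fy

  # cavity follower load
  cav <- sim$cavity
  V <- cavity_volume(r, y, sim$i1, sim$i2)
  P <- switch(cav$mode,
              off = 0,
              ramp = cav$P_fun(t),
              coupled = cav$P0 + cav$Kf * (cav$V0 - V) / cav$V0)
  if (P != 0) {
    gV <- volume_gradient(r, y, sim$i1, sim$i2, sim$n)
    fr <- fr + P * gV$r
    fy <- fy + P * gV$y
  }

  # prescribed air-puff pressure on the anterior corneal patch
  p_air <- NULL
  if (!is.null(sim$puff)) {
    ant <- sim$mesh$anterior
    recession <- sim$mesh$nodes[ant, 2L] - y[ant]
    p_ant <- puff_pressure(sim$puff, r[ant], recession, t)
    p_air <- numeric(sim$n)
    p_air[ant] <- p_ant
    if (any(p_ant != 0)) {
      gVc <- volume_gradient(r, y, sim$i1, sim$i2, sim$n,
                             subset = sim$cornea_el)
      fr <- fr - p_air * gVc$r
      fy <- fy - p_air * gVc$y
    }
  }

  # penalty contact against the flat lower face of the falling mass
  f_mass <- NA_real_
  contact_energy <- 0
  if (!is.null(sim$contact)) {
    ct <- sim$contact
    pen <- pmax(y - ym, 0)
    pen[-sim$mesh$anterior] <- 0
    pen[r > ct$rc] <- 0
    kA <- ct$kpen * ct$A_contact
    fy <- fy - kA * pen
    f_mass <- -ct$M * ct$g + sum(kA * pen)
    contact_energy <- sum(kA * pen^2) / 2
    if (any(pen > 0.1 * sim$mesh$config$CCT / 1000))
      stop_wiop("contact penetration exceeded 10% of CCT; ",
                "reduce the time step or increase the contact penalty")
  }

  list(fr = fr, fy = fy, P = P, V = V, p_air = p_air,
       f_mass = f_mass, contact_energy = contact_energy)
}

# conservative estimate of the stable explicit time step from the current
# tangent stiffness (numerical second derivative of the wall energy) plus the
# contact penalty
stable_dt <- function(sim, safety = 0.35) {
  st <- element_stretches(sim)
  h <- 1e-4
  d1p <- membrane_dpsi(st$lam1 + h, st$lam2, sim$C10e, sim$k1e, sim$k2e, sim$fam)
  d1m <- membrane_dpsi(st$lam1 - h, st$lam2, sim$C10e, sim$k1e, sim$k2e, sim$fam)
  d2p <- membrane_dpsi(st$lam1, st$lam2 + h, sim$C10e, sim$k1e, sim$k2e, sim$fam)
  d2m <- membrane_dpsi(st$lam1, st$lam2 - h, sim$C10e, sim$k1e, sim$k2e, sim$fam)
  E1 <- pmax(abs((d1p$dP1 - d1m$dP1) / (2 * h)), 1e-6)
  E2 <- pmax(abs((d2p$dP2 - d2m$dP2) / (2 * h)), 1e-6)
  k_ax <- sim$V0e * E1 / sim$L0^2
  k_hp <- sim$V0e * E2 / sim$RmSum0^2
  k_lo <- k_ax + k_hp
  kappa <- c(k_lo, 0) + c(0, k_lo)
  # bending hinge stiffness ~ c_b * |grad psi|^2 spread over the three nodes
  Lmin <- pmin(c(sim$L0[1L], sim$L0), c(sim$L0, sim$L0[length(sim$L0)]))
  kappa <- kappa + 6 * sim$c_bend / Lmin^2
  if (!is.null(sim$contact))
    kappa <- kappa + sim$contact$kpen * sim$contact$A_contact
  omega <- sqrt(max(kappa / sim$m))
  safety * 2 / omega
}

# energies of the current state (velocities must be time-centred)
sim_energies <- function(sim, vr, vy, contact_energy = 0) {
  st <- element_stretches(sim)
  psi <- membrane_psi(st$lam1, st$lam2, sim$C10e, sim$k1e, sim$k2e, sim$fam)
  strain_el <- sim$V0e * psi
  bf <- bending_forces(sim$r, sim$y, sim$n, sim$c_bend, sim$psi0)
  e_bend <- sum(bf$energy)
  e_bend_cornea <- sum(bf$energy[sim$cornea_node[seq_len(sim$n - 1L)]])
  cav <- sim$cavity
  e_cav <- 0
  if (cav$mode == "coupled") {
    V <- cavity_volume(sim$r, sim$y, sim$i1, sim$i2)
    dV <- cav$V0 - V
    e_cav <- cav$P0 * dV + cav$Kf * dV^2 / (2 * cav$V0)
  }
  ke <- sum(sim$m * (vr^2 + vy^2)) / 2
  list(strain = sum(strain_el) + e_bend,
       cornea_strain = sum(strain_el[sim$cornea_el]) + e_bend_cornea,
       cavity = e_cav,
       contact = contact_energy,
       kinetic = ke)
}

# advance the simulation to t_end, recording every dt_out; returns the
# updated sim and the recorded block
advance_phase <- function(sim, t_end, dt_out, damping = 0) {
  n_out <- max(1L, round((t_end - sim$t) / dt_out))
  n <- sim$n
  ant <- sim$mesh$anterior
  has_mass <- !is.null(sim$contact)
  has_puff <- !is.null(sim$puff)

  time <- numeric(n_out)
  apex_y <- numeric(n_out); apex_vy <- numeric(n_out)
  cav_P <- numeric(n_out)
  pos_r <- matrix(0, n, n_out); pos_y <- matrix(0, n, n_out)
  air_p <- if (has_puff) matrix(0, length(ant), n_out) else NULL
  mass_y <- mass_v <- if (has_mass) numeric(n_out) else NULL
  en <- matrix(0, n_out, 5,
               dimnames = list(NULL, c("strain", "cornea_strain", "cavity",
                                       "contact", "kinetic")))

  r <- sim$r; y <- sim$y; vr <- sim$vr; vy <- sim$vy
  free <- !sim$fixed
  free_r <- free; free_r[sim$mesh$apex] <- FALSE  # apex stays on the axis
  mask_r <- as.numeric(free_r)
  mask_y <- as.numeric(free)
  t <- sim$t
  ct <- sim$contact

  for (k in seq_len(n_out)) {
    sim$r <- r; sim$y <- y
    dt <- stable_dt(sim)
    nsub <- ceiling(dt_out / dt)
    dt <- dt_out / nsub
    fac1 <- 1 - damping * dt / 2
    fac2 <- 1 + damping * dt / 2
    for (s in seq_len(nsub)) {
      f <- sim_forces(sim, r, y, t, ym = if (has_mass) ct$ym else NA)
      ar <- f$fr / sim$m
      ay <- f$fy / sim$m
      vr <- mask_r * (vr * fac1 + ar * dt) / fac2
      vy <- mask_y * (vy * fac1 + ay * dt) / fac2
      r <- r + vr * dt
      y <- y + vy * dt
      if (has_mass) {
        am <- f$f_mass / ct$M
        ct$vm <- ct$vm + am * dt
        ct$ym <- ct$ym + ct$vm * dt
        if (is.na(ct$t_contact) && f$f_mass > -ct$M * ct$g + 1e-12)
          ct$t_contact <- t
      }
      t <- t + dt
    }
    # time-centred velocities for recording
    sim$r <- r; sim$y <- y
    f <- sim_forces(sim, r, y, t, ym = if (has_mass) ct$ym else NA)
    vcr <- mask_r * (vr + (f$fr / sim$m) * dt / 2)
    vcy <- mask_y * (vy + (f$fy / sim$m) * dt / 2)

    time[k] <- t
    apex_y[k] <- y[sim$mesh$apex]
    apex_vy[k] <- vcy[sim$mesh$apex]
    cav_P[k] <- mpa_to_mmhg(f$P)
    pos_r[, k] <- r; pos_y[, k] <- y
    if (has_puff) air_p[, k] <- f$p_air[ant]
    if (has_mass) {
      vcm <- ct$vm + (f$f_mass / ct$M) * dt / 2
      mass_y[k] <- ct$ym; mass_v[k] <- vcm
    }
    e <- sim_energies(sim, vcr, vcy, f$contact_energy)
    en[k, ] <- c(e$strain, e$cornea_strain, e$cavity, e$contact, e$kinetic)
  }

  sim$r <- r; sim$y <- y; sim$vr <- vr; sim$vy <- vy; sim$t <- t
  sim$contact <- ct

  list(sim = sim,
       block = list(time = time, apex_y = apex_y, apex_vy = apex_vy,
                    cavity_mmHg = cav_P, pos_r = pos_r, pos_y = pos_y,
                    air_p = air_p, mass_y = mass_y, mass_v = mass_v,
                    energies = en))
}

# stack recorded blocks into one trajectory object
make_trajectory <- function(blocks, sim, scenario, load_onset, dt_out,
                            t_contact = NA_real_) {
  cat_field <- function(f) do.call(c, lapply(blocks, `[[`, f))
  # optional per-increment fields: pad blocks that lack them with NA
  cat_pad <- function(f) {
    vals <- lapply(blocks, function(b)
      if (is.null(b[[f]])) rep(NA_real_, length(b$time)) else b[[f]])
    out <- do.call(c, vals)
    if (all(is.na(out))) NULL else out
  }
  cat_mat <- function(f, nr) {
    ms <- lapply(blocks, function(b)
      if (is.null(b[[f]])) matrix(NA_real_, nr, length(b$time)) else b[[f]])
    out <- do.call(cbind, ms)
    if (all(is.na(out))) NULL else out
  }
  en <- do.call(rbind, lapply(blocks, `[[`, "energies"))
  structure(
    list(time = cat_field("time"),
         apex_y = cat_field("apex_y"),
         apex_vy = cat_field("apex_vy"),
         cavity_mmHg = cat_field("cavity_mmHg"),
         pos_r = cat_mat("pos_r", sim$n), pos_y = cat_mat("pos_y", sim$n),
         air_p = cat_mat("air_p", length(sim$mesh$anterior)),
         mass_y = cat_pad("mass_y"),
         mass_v = cat_pad("mass_v"),
         energies = as.data.frame(en),
         mesh = sim$mesh, anterior = sim$mesh$anterior,
         scenario = scenario, load_onset = load_onset,
         dt_out = dt_out, t_contact = t_contact),
    class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf("<sim_trajectory> scenario '%s': %d increments, t = [%.2f, %.2f] ms (dt_out %.3g ms)\n",
              x$scenario, length(x$time), x$time[1L], x$time[length(x$time)],
              x$dt_out))
  cat(sprintf("  load onset %.2f ms; apex y from %.3f to %.3f mm; cavity P %.2f -> %.2f mmHg\n",
              x$load_onset, x$apex_y[1L], x$apex_y[length(x$time)],
              x$cavity_mmHg[1L], x$cavity_mmHg[length(x$time)]))
  invisible(x)
}
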