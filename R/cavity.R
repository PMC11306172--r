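#' Humor cavity state
#'
#' The aqueous/vitreous humors are treated as an incompressible fluid filling
#' the globe. In the reduced-order model "incompressible" is realised as a
#' stiff linear pressure-volume law
#' \deqn{P = P_0 + K_f (V_0 - V) / V_0,}
#' spatially uniform (hydrostatic): the pressure rises when the enclosed
#' volume is driven below its reference by an external indentation. `bulk` is
#' chosen large enough that the relative volume change during loading stays
#' well below 0.5%.
#'
#' @param reference_volume cavity volume at baseline, mm^3.
#' @param baseline_iop baseline intraocular pressure, mmHg.
#' @param bulk cavity bulk stiffness `K_f`, MPa.
#' @return object of class `cavity_state`.
#' @examples
#' cs <- cavity_state(7000, 15)
#' cavity_pressure(7000, cs)          # baseline
#' cavity_pressure(6990, cs) > 15     # indentation raises the pressure
#' @export
cavity_state <- function(reference_volume, baseline_iop, bulk = 5) {
  if (reference_volume <= 0) stop_wiop("reference_volume must be positive")
  if (baseline_iop < 0) stop_wiop("baseline_iop must be non-negative")
  if (bulk <= 0) stop_wiop("bulk stiffness must be positive")
  structure(list(reference_volume = reference_volume,
                 baseline_iop = baseline_iop, bulk = bulk),
            class = "cavity_state")
}

#' Cavity pressure from the current enclosed volume
#'
#' @param volume current cavity volume, mm^3; must be positive.
#' @param state a [cavity_state()].
#' @return pressure in mmHg.
#' @export
cavity_pressure <- function(volume, state) {
  stopifnot(inherits(state, "cavity_state"))
  if (any(volume <= 0)) stop_wiop("volume must be positive")
  state$baseline_iop +
    mpa_to_mmhg(state$bulk * (state$reference_volume - volume) /
                  state$reference_volume)
}

# single-increment record of the current (static) simulator state, used to
# anchor trajectories at their true initial configuration
record_block <- function(sim) {
  f <- sim_forces(sim)
  e <- sim_energies(sim, sim$vr, sim$vy, f$contact_energy)
  list(time = sim$t,
       apex_y = sim$y[sim$mesh$apex],
       apex_vy = sim$vy[sim$mesh$apex],
       cavity_mmHg = mpa_to_mmhg(f$P),
       pos_r = matrix(sim$r, ncol = 1L),
       pos_y = matrix(sim$y, ncol = 1L),
       air_p = if (is.null(sim$puff)) NULL else
         matrix(f$p_air[sim$mesh$anterior], ncol = 1L),
       mass_y = if (is.null(sim$contact)) NULL else sim$contact$ym,
       mass_v = if (is.null(sim$contact)) NULL else sim$contact$vm,
       energies = matrix(c(e$strain, e$cornea_strain, e$cavity, e$contact,
                           e$kinetic), 1, 5,
                         dimnames = list(NULL, c("strain", "cornea_strain",
                                                 "cavity", "contact",
                                                 "kinetic"))))
}

#' Pressurise the eye to a target intraocular pressure
#'
#' Inflates the (zero-pressure) mesh by ramping the cavity pressure smoothly
#' over `ramp_time` and then holding it with mass-proportional damping until
#' the structure reaches quasi-static equilibrium (dynamic relaxation). At
#' the end of the hold the cavity is locked: its current volume becomes the
#' reference of the stiff pressure-volume law, so that subsequent external
#' loads raise the pressure as they indent the cornea.
#'
#' @param mesh an [build_eye_mesh()] mesh in its stress-free configuration.
#' @param materials named list with `material_params` entries `cornea`,
#'   `limbus` and `sclera`.
#' @param target_IOP target intraocular pressure, mmHg.
#' @param ramp_time pressure ramp duration, ms.
#' @param hold_time minimum stabilisation hold, ms.
#' @param dt_out output increment, ms.
#' @param max_hold maximum stabilisation time before the routine gives up, ms.
#' @param settle_ke_frac equilibrium threshold: residual kinetic energy as a
#'   fraction of the internal (strain) energy.
#' @param cavity_bulk locked-cavity bulk stiffness, MPa.
#' @param damping mass-proportional damping coefficient used during the ramp
#'   and hold, 1/ms. Damping is never applied during external loading.
#' @return an object of class `eye_state`: the equilibrated simulator state
#'   together with the recorded pressurisation trajectory.
#' @export
pressurize <- function(mesh, materials, target_IOP,
                       ramp_time = 10, hold_time = 10, dt_out = 0.25,
                       max_hold = 80, settle_ke_frac = 1e-4,
                       cavity_bulk = 5, damping = 1.2) {
  stopifnot(inherits(mesh, "eye_mesh"))
  if (target_IOP < 0) stop_wiop("target_IOP must be non-negative")
  sim <- new_sim(mesh, materials)
  P_mpa <- mmhg_to_mpa(target_IOP)
  blocks <- list(record_block(sim))

  sim$cavity <- list(mode = "ramp",
                     P_fun = function(t) P_mpa * smoothstep(t / ramp_time),
                     P0 = 0, V0 = NA_real_, Kf = cavity_bulk)
  ph <- advance_phase(sim, ramp_time, dt_out, damping = damping)
  sim <- ph$sim; blocks <- c(blocks, list(ph$block))

  # stabilisation hold at constant pressure until kinetic energy dies out
  sim$cavity$P_fun <- function(t) P_mpa
  ke_hist <- numeric(0)
  ke_frac <- 0
  t_hold_end <- sim$t + hold_time
  repeat {
    ph <- advance_phase(sim, sim$t + max(hold_time / 2, 2), dt_out,
                        damping = 2 * damping)
    sim <- ph$sim; blocks <- c(blocks, list(ph$block))
    last <- nrow(ph$block$energies)
    ke <- ph$block$energies[last, "kinetic"]
    strain <- ph$block$energies[last, "strain"]
    ke_hist <- c(ke_hist, ke)
    ke_frac <- ke / max(strain, 1e-12)
    settled <- ke <= settle_ke_frac * max(strain, 1e-12) || strain < 1e-12
    if (settled && sim$t >= t_hold_end) break
    if (sim$t > ramp_time + max_hold)
      stop_wiop("pressurization failed to reach quasi-static equilibrium ",
                "within ", max_hold, " ms; residual KE history: ",
                paste(signif(ke_hist, 3), collapse = ", "))
  }

  # lock the cavity: stiff pressure-volume law about the settled volume
  V_now <- cavity_volume(sim$r, sim$y, sim$i1, sim$i2)
  sim$cavity <- list(mode = "coupled", P0 = P_mpa, V0 = V_now,
                     Kf = cavity_bulk)
  sim$vr[] <- 0; sim$vy[] <- 0   # discard residual settling motion

  traj <- make_trajectory(blocks, sim, scenario = "pressurization",
                          load_onset = sim$t, dt_out = dt_out)
  structure(list(sim = sim, blocks = blocks, trajectory = traj,
                 mesh = mesh, iop = target_IOP,
                 cavity = cavity_state(V_now, target_IOP, cavity_bulk),
                 ke_fraction = ke_frac),
            class = "eye_state")
}

#' @export
print.eye_state <- function(x, ...) {
  cat(sprintf("<eye_state> pressurized at %.3g mmHg, t = %.2f ms, apex y = %.4f mm\n",
              x$iop, x$sim$t, x$sim$y[x$mesh$apex]))
  cat(sprintf("  cavity volume %.1f mm^3, bulk %.3g MPa\n",
              x$cavity$reference_volume, x$cavity$bulk))
  invisible(x)
}

#' Recover the zero-pressure (stress-free) configuration
#'
#' The imaged/in-vivo geometry corresponds to the eye already pressurised at
#' the intraocular pressure; the stress-free geometry that inflates onto it
#' is found by the classic fixed-point pull-back iteration
#' \deqn{X_0^{(k+1)} = X_0^{(k)} - (x_\mathrm{inflated}^{(k)} - X_\mathrm{ref}).}
#' Iteration stops once the maximum nodal distance between the re-inflated
#' and the reference configuration falls below `tol`.
#'
#' @param reference_mesh the target (pressurised, in-vivo) [build_eye_mesh()]
#'   geometry.
#' @param materials regional material list as in [pressurize()].
#' @param IOP intraocular pressure at which the reference was imaged, mmHg.
#' @param tol convergence tolerance on the round-trip nodal distance, mm.
#' @param max_iter maximum number of pull-back iterations.
#' @param relax under-relaxation factor on the pull-back update; the
#'   iteration halves it adaptively whenever the residual grows.
#' @param ... further arguments forwarded to [pressurize()].
#' @return the zero-pressure `eye_mesh`, with attributes
#'   `residual_history` (mm per iteration) and `pressurized_state` (the
#'   [pressurize()] result of the final iterate, ready for loading runs).
#' @export
recover_zero_pressure <- function(reference_mesh, materials, IOP,
                                  tol = 1e-3, max_iter = 25, relax = 1,
                                  ...) {
  stopifnot(inherits(reference_mesh, "eye_mesh"))
  if (IOP < 0) stop_wiop("IOP must be non-negative")
  X_ref <- reference_mesh$nodes
  X0 <- X_ref
  X0_best <- X0
  best <- Inf
  history <- numeric(0)
  n_grow <- 0L
  omega <- relax
  for (k in seq_len(max_iter)) {
    mesh_k <- remesh_nodes(reference_mesh, X0)
    st <- pressurize(mesh_k, materials, IOP, ...)
    x_inf <- cbind(st$sim$r, st$sim$y)
    d <- x_inf - X_ref
    res <- max(sqrt(d[, 1L]^2 + d[, 2L]^2))
    history <- c(history, res)
    if (res <= tol) {
      out <- mesh_k
      attr(out, "residual_history") <- history
      attr(out, "pressurized_state") <- st
      return(out)
    }
    if (res < best) { best <- res; X0_best <- X0 }
    if (k > 1L && res > history[k - 1L]) {
      n_grow <- n_grow + 1L
      omega <- omega / 2           # expansive mode: damp the update
      X0 <- X0_best                # restart from the best iterate
      if (n_grow >= 4L)
        stop_wiop("zero-pressure iteration diverged (residual grew for 4 ",
                  "consecutive iterations); history [mm]: ",
                  paste(signif(history, 4), collapse = ", "))
      mesh_k <- remesh_nodes(reference_mesh, X0)
      st <- pressurize(mesh_k, materials, IOP, ...)
      d <- cbind(st$sim$r, st$sim$y) - X_ref
    } else n_grow <- 0L
    X0 <- X0 - omega * d
    X0[reference_mesh$apex, 1L] <- 0        # apex stays on the axis
    X0[reference_mesh$fixed, ] <- X_ref[reference_mesh$fixed, ]
  }
  stop_wiop("zero-pressure iteration did not converge in ", max_iter,
            " iterations; residual history [mm]: ",
            paste(signif(history, 4), collapse = ", "))
}
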