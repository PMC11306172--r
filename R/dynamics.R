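#' Falling-mass loading scenario configuration
#'
#' A rigid cube of mass 2.02 g and side 1.5 mm dropped from 8 mm above the
#' corneal apex; it transfers a known, easily book-kept mechanical energy
#' (kinetic plus potential) to the anterior corneal surface. Contact against
#' the cube's flat lower face is modelled with a frictionless nodal penalty
#' over an area-equivalent circular footprint.
#'
#' @param mass mass of the cube, g.
#' @param cube_side side length of the cube, mm.
#' @param drop_height initial gap between the cube's lower face and the
#'   corneal apex, mm.
#' @param gravity gravitational acceleration, mm/ms^2.
#' @param penalty contact penalty stiffness per unit area, MPa/mm.
#' @return object of class `falling_mass_config`.
#' @examples
#' falling_mass_config()
#' @export
falling_mass_config <- function(mass = 2.02, cube_side = 1.5,
                                drop_height = 8, gravity = 9.81e-3,
                                penalty = 30) {
  vals <- c(mass, cube_side, drop_height, gravity, penalty)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_wiop("all falling-mass parameters must be positive")
  structure(list(mass = mass, cube_side = cube_side,
                 drop_height = drop_height, gravity = gravity,
                 penalty = penalty,
                 contact_radius = cube_side / sqrt(pi)),
            class = "falling_mass_config")
}

#' Air-puff load profile
#'
#' Reduced-order replacement for the jet of the non-contact tonometer: a
#' prescribed pressure field on the anterior corneal surface with a Gaussian
#' spatial footprint \eqn{\exp(-(r/r_f)^2)} (below 1e-4 of the peak beyond
#' three footprint radii) and a smooth temporal pulse over the 30 ms test
#' window. An optional deformation-coupling coefficient attenuates the local
#' pressure as the surface recedes, mimicking the deformation-dependent air
#' pressure of a true fluid-structure simulation.
#'
#' @param onset delay between the start of the run and the pulse, ms.
#' @param duration pulse duration, ms.
#' @param peak_pressure peak stagnation pressure at the apex, mmHg. The
#'   default is the package convention, chosen once so that the pulse
#'   applanates the cornea and the two work curves cross over the whole
#'   clinical 10-30 mmHg pressure range (deformation amplitude on the order
#'   of 1-2 mm at physiological pressure).
#' @param footprint_radius Gaussian footprint radius, mm.
#' @param shape temporal waveform, `"sin2"` (default) or `"triangle"`.
#' @param coupling deformation-coupling coefficient, 1/mm; 0 disables.
#' @return object of class `air_puff_profile`.
#' @examples
#' air_puff_profile()
#' @export
air_puff_profile <- function(onset = 2, duration = 30,
                             peak_pressure = 80, footprint_radius = 1.5,
                             shape = c("sin2", "triangle"), coupling = 0) {
  shape <- match.arg(shape)
  if (duration <= 0) stop_wiop("duration must be positive")
  if (peak_pressure < 0) stop_wiop("peak_pressure must be non-negative")
  if (footprint_radius <= 0) stop_wiop("footprint_radius must be positive")
  if (coupling < 0) stop_wiop("coupling must be non-negative")
  structure(list(onset = onset, duration = duration,
                 peak_pressure = peak_pressure,
                 footprint_radius = footprint_radius,
                 shape = shape, coupling = coupling),
            class = "air_puff_profile")
}

#' Run the falling-mass impact scenario
#'
#' Releases the rigid cube from rest above the apex of a pressurised eye and
#' integrates the coupled system without damping, so that the mechanical
#' energy lost by the mass is stored elastically in the eye (wall strain,
#' cavity compression and contact interface). The returned trajectory
#' includes the pressurisation history of `state`, so work bookkeeping is
#' continuous from the stress-free configuration.
#'
#' @param state an [pressurize()] / `eye_state` object.
#' @param config a [falling_mass_config()].
#' @param t_end end time of the impact phase measured from the release, ms;
#'   defaults to the free-fall time plus 25 ms.
#' @param dt_out output increment, ms.
#' @return a `sim_trajectory`; its `t_contact` field holds the detected
#'   first-contact time and `load_onset` equals it.
#' @export
run_falling_mass <- function(state, config = falling_mass_config(),
                             t_end = NULL, dt_out = 0.25) {
  stopifnot(inherits(state, "eye_state"),
            inherits(config, "falling_mass_config"))
  sim <- state$sim
  apex_y <- sim$y[sim$mesh$apex]
  # reference contact areas, frozen at release so the penalty is conservative
  A_ref <- lumped_ring_areas(sim$r, sim$y, sim$mesh$elements,
                             which(sim$mesh$region == "cornea"))
  sim$contact <- list(M = config$mass, g = config$gravity,
                      ym = apex_y + config$drop_height, vm = 0,
                      rc = config$contact_radius,
                      kpen = config$penalty, A_contact = A_ref,
                      t_contact = NA_real_)
  fall_time <- if (config$gravity > 0)
    sqrt(2 * config$drop_height / config$gravity) else Inf
  if (is.null(t_end)) {
    if (!is.finite(fall_time))
      stop_wiop("t_end must be given when gravity is zero")
    t_end <- fall_time + 25
  }
  ph <- advance_phase(sim, sim$t + t_end, dt_out, damping = 0)
  blocks <- c(state$blocks, list(ph$block))
  sim <- ph$sim
  t_contact <- sim$contact$t_contact
  make_trajectory(blocks, sim, scenario = "falling_mass",
                  load_onset = if (is.na(t_contact)) state$sim$t + fall_time
                               else t_contact,
                  dt_out = dt_out, t_contact = t_contact)
}

#' Run the air-puff scenario
#'
#' Applies the prescribed air-puff pressure field to the anterior corneal
#' surface of a pressurised eye and integrates without damping. The apex
#' moves inward, reaches its maximum inward velocity, decelerates to zero at
#' highest concavity and rebounds, while the cavity pressure rises above the
#' baseline intraocular pressure.
#'
#' @param state an [pressurize()] / `eye_state` object.
#' @param profile an [air_puff_profile()].
#' @param t_end end time measured from the start of the puff phase, ms;
#'   defaults to `onset + duration + 3`.
#' @param dt_out output increment, ms.
#' @return a `sim_trajectory` with `load_onset` at the pulse onset.
#' @export
run_air_puff <- function(state, profile = air_puff_profile(),
                         t_end = NULL, dt_out = 0.25) {
  stopifnot(inherits(state, "eye_state"),
            inherits(profile, "air_puff_profile"))
  sim <- state$sim
  onset_abs <- sim$t + profile$onset
  sim$puff <- list(profile = profile, onset_abs = onset_abs)
  if (is.null(t_end)) t_end <- profile$onset + profile$duration + 3
  ph <- advance_phase(sim, sim$t + t_end, dt_out, damping = 0)
  blocks <- c(state$blocks, list(ph$block))
  make_trajectory(blocks, ph$sim, scenario = "air_puff",
                  load_onset = onset_abs, dt_out = dt_out)
}

#' Apex kinematics of a simulated trajectory
#'
#' Differentiates the recorded apex position by central differences on the
#' output time base and returns a device-style velocity trace: time measured
#' from the load onset, velocity positive toward the interior of the eye
#' (the direction of the air puff), in mm/ms.
#'
#' @param trajectory a `sim_trajectory`.
#' @return a [velocity_trace()] with provenance `"simulated"`; the outward
#'   apex position is kept in the `displacement` column (mm, relative to the
#'   configuration at load onset).
#' @export
apex_kinematics <- function(trajectory) {
  stopifnot(inherits(trajectory, "sim_trajectory"))
  tt <- trajectory$time
  y <- trajectory$apex_y
  K <- length(tt)
  if (K < 3L) stop_wiop("trajectory must have at least 3 increments")
  v <- numeric(K)
  v[2:(K - 1L)] <- (y[3:K] - y[1:(K - 2L)]) / (tt[3:K] - tt[1:(K - 2L)])
  v[1L] <- (y[2L] - y[1L]) / (tt[2L] - tt[1L])
  v[K] <- (y[K] - y[K - 1L]) / (tt[K] - tt[K - 1L])
  y_onset <- stats::approx(tt, y, xout = trajectory$load_onset, rule = 2)$y
  velocity_trace(time = tt - trajectory$load_onset,
                 velocity = -v,
                 displacement = y - y_onset,
                 provenance = "simulated")
}
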