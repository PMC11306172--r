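# trapezoidal accumulation of nodal pressure work along y:
# increment j contributes sum_i (F_ij + F_i,j-1)/2 * (y_ij - y_i,j-1),
# with F_ij = P_ij * A_ij the y-projected nodal force
trapezoidal_surface_work <- function(F, Y) {
  stopifnot(is.matrix(F), is.matrix(Y), all(dim(F) == dim(Y)))
  K <- ncol(F)
  if (K < 2L) return(numeric(K))
  Fm <- (F[, -1L, drop = FALSE] + F[, -K, drop = FALSE]) / 2
  dY <- Y[, -1L, drop = FALSE] - Y[, -K, drop = FALSE]
  c(0, cumsum(colSums(Fm * dY)))
}

# per-increment y-projected nodal areas of the anterior corneal patch
anterior_projected_matrix <- function(trajectory) {
  mesh <- trajectory$mesh
  sel <- which(mesh$region == "cornea")
  ant <- trajectory$anterior
  K <- length(trajectory$time)
  A <- matrix(0, length(ant), K)
  for (k in seq_len(K))
    A[, k] <- projected_ring_areas_y(trajectory$pos_r[, k],
                                     mesh$elements, sel)[ant]
  A
}

#' Work of the intraocular pressure on the anterior corneal surface
#'
#' Accumulates, with the trapezoidal rule over output increments, the signed
#' work done along the anterior-posterior axis by the (spatially uniform)
#' cavity pressure through the y-projected nodal areas of the anterior
#' corneal surface, recomputed in the current configuration at every
#' increment. The work rises during pressurisation (the fluid expands its
#' walls) and falls while an external load indents the cornea against the
#' pressure.
#'
#' @param trajectory a `sim_trajectory`.
#' @return numeric vector (mJ) on the trajectory time base, starting at 0.
#' @export
work_iop <- function(trajectory) {
  stopifnot(inherits(trajectory, "sim_trajectory"))
  if (length(trajectory$time) < 2L)
    stop_wiop("trajectory has too few increments for work accumulation")
  A <- anterior_projected_matrix(trajectory)
  P <- mmhg_to_mpa(trajectory$cavity_mmHg)
  F <- sweep(A, 2L, P, `*`)
  Y <- trajectory$pos_y[trajectory$anterior, , drop = FALSE]
  trapezoidal_surface_work(F, Y)
}

#' Work of the air-puff pressure on the anterior corneal surface
#'
#' As [work_iop()], but with the (non-uniform, deformation-tracking) applied
#' air-pressure field recorded during the puff. Zero whenever no air load is
#' applied.
#'
#' @param trajectory a `sim_trajectory` from [run_air_puff()].
#' @return numeric vector (mJ) on the trajectory time base.
#' @export
work_air <- function(trajectory) {
  stopifnot(inherits(trajectory, "sim_trajectory"))
  if (is.null(trajectory$air_p))
    stop_wiop("trajectory has no applied air-pressure history")
  A <- anterior_projected_matrix(trajectory)
  Pa <- trajectory$air_p
  Pa[is.na(Pa)] <- 0
  F <- Pa * A
  Y <- trajectory$pos_y[trajectory$anterior, , drop = FALSE]
  # the air pushes inward (toward -y): its y-force is -P * A_y
  -trapezoidal_surface_work(F, Y)
}

#' Mechanical energies of the falling mass
#'
#' Kinetic, potential and total mechanical energy of the rigid mass along
#' the trajectory. Potential energy is measured from the height of the
#' cube's lower face at first contact, so the total mechanical energy at
#' contact equals the impact kinetic energy `m g h`.
#'
#' @param trajectory a `sim_trajectory` from [run_falling_mass()].
#' @param config the [falling_mass_config()] used for the run.
#' @return data frame with columns `time`, `kinetic`, `potential`, `total`
#'   (ms, mJ); `NA` during phases without the mass.
#' @export
mass_energies <- function(trajectory, config = falling_mass_config()) {
  stopifnot(inherits(trajectory, "sim_trajectory"))
  if (is.null(trajectory$mass_y))
    stop_wiop("trajectory has no falling-mass history")
  tt <- trajectory$time
  ke <- config$mass * trajectory$mass_v^2 / 2
  y_ref <- if (!is.na(trajectory$t_contact))
    stats::approx(tt, trajectory$mass_y, xout = trajectory$t_contact,
                  rule = 2)$y
  else min(trajectory$mass_y, na.rm = TRUE)
  pe <- config$mass * config$gravity * (trajectory$mass_y - y_ref)
  data.frame(time = tt, kinetic = ke, potential = pe, total = ke + pe)
}

#' Assemble the work/energy ledger of a loading run
#'
#' Collects on the common output time base the work of the intraocular
#' pressure (internal side of the anterior corneal surface) and the external
#' energy channel of the scenario: the cumulative work of the air puff, or
#' the mechanical energy given up by the falling mass. Eye strain, cavity,
#' contact-interface and kinetic energies are carried along.
#'
#' @param trajectory a `sim_trajectory`.
#' @param config the [falling_mass_config()] for mass runs.
#' @return a data frame of class `work_ledger` with attributes `load_onset`
#'   (ms), `initial_work` (Work_IOP plateau at load onset, mJ) and
#'   `scenario`. Columns: `time`, `work_iop`, `work_ext`, `strain`,
#'   `cornea_strain`, `cavity`, `contact`, `kinetic`, `cavity_mmHg`,
#'   `apex_y` (ms, mJ, mmHg, mm).
#' @export
work_ledger <- function(trajectory, config = falling_mass_config()) {
  stopifnot(inherits(trajectory, "sim_trajectory"))
  w_iop <- work_iop(trajectory)
  w_ext <- switch(trajectory$scenario,
    air_puff = work_air(trajectory),
    falling_mass = {
      me <- mass_energies(trajectory, config)
      e0 <- if (!is.na(trajectory$t_contact))
        stats::approx(me$time, me$total, xout = trajectory$t_contact,
                      rule = 2)$y
      else me$total[which(!is.na(me$total))[1L]]
      transferred <- e0 - me$total
      transferred[is.na(transferred)] <- 0
      pmax(transferred, 0)
    },
    pressurization = rep(0, length(trajectory$time)),
    stop_wiop("unknown scenario: ", trajectory$scenario))
  out <- data.frame(time = trajectory$time,
                    work_iop = w_iop, work_ext = w_ext,
                    trajectory$energies,
                    cavity_mmHg = trajectory$cavity_mmHg,
                    apex_y = trajectory$apex_y)
  attr(out, "load_onset") <- trajectory$load_onset
  attr(out, "initial_work") <-
    stats::approx(out$time, out$work_iop, xout = trajectory$load_onset,
                  rule = 2)$y
  attr(out, "scenario") <- trajectory$scenario
  class(out) <- c("work_ledger", "data.frame")
  out
}

#' Intersection of the internal and external work curves
#'
#' Finds the instants after the load onset at which the work of the
#' intraocular pressure equals the external work/energy channel, by linear
#' interpolation between output increments. During an air puff the two
#' curves cross twice (inward phase and rebound); the first crossing is the
#' primary one used by the pressure estimator.
#'
#' @param ledger a [work_ledger()] (or any data frame with `time`,
#'   `work_iop`, `work_ext` columns).
#' @param load_onset load onset time on the ledger time base, ms; defaults
#'   to the ledger attribute (0 if absent).
#' @return object of class `intersection_result` with fields `times` (ms
#'   after load onset, possibly empty), `values` (mJ), `time` and
#'   `work_at_intersection` (primary crossing), `initial_work`, `ratio`
#'   (work at crossing / initial work) and `crossed`.
#' @export
find_intersection <- function(ledger, load_onset = NULL) {
  if (is.null(load_onset)) {
    load_onset <- attr(ledger, "load_onset")
    if (is.null(load_onset)) load_onset <- 0
  }
  stopifnot(all(c("time", "work_iop", "work_ext") %in% names(ledger)))
  sel <- which(ledger$time >= load_onset)
  if (length(sel) < 2L) stop_wiop("ledger does not cover the load window")
  tt <- ledger$time[sel]
  d <- ledger$work_iop[sel] - ledger$work_ext[sel]
  s <- sign(d)
  idx <- which(s[-1L] * s[-length(s)] < 0 |
                 (s[-length(s)] != 0 & s[-1L] == 0))
  times <- values <- numeric(0)
  for (i in idx) {
    f <- d[i] / (d[i] - d[i + 1L])
    times <- c(times, tt[i] + f * (tt[i + 1L] - tt[i]))
    wi <- ledger$work_iop[sel][i]
    wi1 <- ledger$work_iop[sel][i + 1L]
    values <- c(values, wi + f * (wi1 - wi))
  }
  iw <- attr(ledger, "initial_work")
  if (is.null(iw)) iw <- ledger$work_iop[sel][1L]
  crossed <- length(times) > 0L
  structure(list(times = times - load_onset, values = values,
                 time = if (crossed) times[1L] - load_onset else NA_real_,
                 work_at_intersection = if (crossed) values[1L] else NA_real_,
                 initial_work = iw,
                 ratio = if (crossed) values[1L] / iw else NA_real_,
                 crossed = crossed, load_onset = load_onset),
            class = "intersection_result")
}

#' @export
print.intersection_result <- function(x, ...) {
  if (!x$crossed) {
    cat("<intersection_result> no intersection of the work curves in the load window\n")
  } else {
    cat(sprintf("<intersection_result> primary crossing %.3f ms after load onset (work %.4g mJ)\n",
                x$time, x$work_at_intersection))
    cat(sprintf("  initial work of the IOP %.4g mJ; ratio %.3f; %d crossing(s): %s ms\n",
                x$initial_work, x$ratio, length(x$times),
                paste(signif(x$times, 4), collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.work_ledger <- function(x, ...) {
  graphics::plot(x$time, x$work_iop, type = "l", col = "darkorange",
                 xlab = "time [ms]", ylab = "work [mJ]",
                 ylim = range(c(x$work_iop, x$work_ext), finite = TRUE), ...)
  graphics::lines(x$time, x$work_ext, col = "steelblue")
  graphics::abline(v = attr(x, "load_onset"), lty = 3)
  graphics::legend("topleft", c("Work IOP", "external"), lty = 1,
                   col = c("darkorange", "steelblue"), bty = "n")
  invisible(x)
}
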