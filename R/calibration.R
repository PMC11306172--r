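#' The sixteen-case parameter sweep design
#'
#' Material parameters of the corneal tissue (`C10` matrix stiffness in MPa,
#' `k1` fibre stiffness in MPa, `k2` dimensionless fibre non-linearity),
#' intraocular pressure and central corneal thickness for the sensitivity
#' sweep: cases 1-5 vary the IOP at fixed material and geometry, cases 6-13
#' vary the material at 15 mmHg, cases 14-16 vary the thickness.
#'
#' @return data frame with columns `simulation`, `C10`, `k1`, `k2`, `IOP`,
#'   `CCT` (MPa, MPa, -, mmHg, um).
#' @export
sweep_cases <- function() {
  data.frame(
    simulation = 1:16,
    C10 = c(0.045, 0.045, 0.045, 0.045, 0.045, 0.0675, 0.0225, 0.045,
            0.045, 0.045, 0.045, 0.035, 0.01, 0.045, 0.045, 0.045),
    k1 = c(0.027, 0.027, 0.027, 0.027, 0.027, 0.027, 0.027, 0.0405,
           0.0135, 0.027, 0.027, 0.13, 0.015, 0.027, 0.027, 0.027),
    k2 = c(180, 180, 180, 180, 180, 180, 180, 180,
           180, 270, 90, 1000, 100, 180, 180, 180),
    IOP = c(10, 15, 20, 25, 30, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15, 15),
    CCT = c(558, 558, 558, 558, 558, 558, 558, 558, 558, 558, 558, 558,
            558, 484, 525, 600))
}

#' Regional material set for a sweep case
#'
#' Builds the cornea/limbus/sclera material list from one row of the sweep
#' design. The sweep varies the CORNEAL tissue constants only: the limbal
#' band keeps its own (fixed, convention) constants with a single
#' circumferential fibre family, and the sclera is Neo-Hookean with a
#' conventional matrix stiffness (stiffer than the cornea).
#'
#' @param C10,k1,k2 corneal constants (MPa, MPa, -).
#' @param scleral_C10 scleral matrix stiffness, MPa.
#' @param limbus_C10,limbus_k1,limbus_k2 limbal constants, held fixed across
#'   sweep cases (the healthy-cornea defaults).
#' @return named list of [material_params()] for `cornea`, `limbus`,
#'   `sclera`.
#' @export
eye_materials <- function(C10 = 0.045, k1 = 0.027, k2 = 180,
                          scleral_C10 = 0.35,
                          limbus_C10 = 0.045, limbus_k1 = 0.027,
                          limbus_k2 = 180) {
  list(cornea = material_params(C10, k1, k2,
                                list(c(1, 0, 0), c(0, 0, 1))),
       limbus = material_params(limbus_C10, limbus_k1, limbus_k2,
                                list(c(0, 0, 1))),
       sclera = material_params(scleral_C10))
}

#' Run the air-puff sweep over a set of parameter cases
#'
#' For every case: builds the reference geometry at the case thickness,
#' recovers the zero-pressure configuration at the case pressure, inflates,
#' runs the air puff, and records the energetic and kinematic outputs
#' (initial work of the IOP, work-curve intersection, maximum-velocity and
#' first-applanation times). Per-case failures are recorded, not raised.
#'
#' @param cases data frame as [sweep_cases()].
#' @param profile an [air_puff_profile()] shared by all cases.
#' @param geometry base [eye_geometry_config()]; the case CCT overrides.
#' @param scleral_C10 scleral stiffness, MPa.
#' @param dt_out output increment, ms.
#' @param zp_tol zero-pressure recovery tolerance, mm.
#' @param verbose print one line per case.
#' @return data frame of class `sweep_result`: one row per case with
#'   `initial_work` (mJ), `apex_disp_pressurization` (mm),
#'   `t_intersection`, `t_maxvel`, `t_applanation`, `lag` (ms after load
#'   onset), `work_at_intersection` (mJ), `ratio`,
#'   `max_apex_displacement` (mm), `cavity_peak_mmHg`, `ok`, `message`.
#' @export
run_sweep <- function(cases = sweep_cases(), profile = air_puff_profile(),
                      geometry = eye_geometry_config(),
                      scleral_C10 = 0.35, dt_out = 0.25, zp_tol = 1e-3,
                      verbose = interactive()) {
  stopifnot(is.data.frame(cases),
            all(c("C10", "k1", "k2", "IOP", "CCT") %in% names(cases)))
  n <- nrow(cases)
  out <- data.frame(cases,
                    initial_work = NA_real_,
                    apex_disp_pressurization = NA_real_,
                    t_intersection = NA_real_,
                    work_at_intersection = NA_real_,
                    ratio = NA_real_,
                    t_maxvel = NA_real_,
                    t_applanation = NA_real_,
                    lag = NA_real_,
                    max_apex_displacement = NA_real_,
                    cavity_peak_mmHg = NA_real_,
                    ok = FALSE, message = "")
  for (i in seq_len(n)) {
    res <- tryCatch({
      geo <- geometry
      geo$CCT <- cases$CCT[i]
      mesh <- build_eye_mesh(geo)
      mats <- eye_materials(cases$C10[i], cases$k1[i], cases$k2[i],
                            scleral_C10)
      mesh0 <- recover_zero_pressure(mesh, mats, cases$IOP[i], tol = zp_tol)
      state <- attr(mesh0, "pressurized_state")
      apex_disp <- state$sim$y[mesh$apex] - mesh0$nodes[mesh$apex, 2L]
      traj <- run_air_puff(state, profile, dt_out = dt_out)
      led <- work_ledger(traj)
      xi <- find_intersection(led)
      trace <- apex_kinematics(traj)
      t_mv <- max_velocity_time(trace)
      t_ap <- first_applanation_time(traj)
      list(initial_work = attr(led, "initial_work"),
           apex_disp = apex_disp,
           t_int = xi$time, w_int = xi$work_at_intersection,
           ratio = xi$ratio,
           t_mv = t_mv, t_ap = as.numeric(t_ap),
           max_disp = stats::approx(traj$time, traj$apex_y,
                                    xout = traj$load_onset, rule = 2)$y -
             min(traj$apex_y),
           p_peak = max(led$cavity_mmHg))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$message[i] <- conditionMessage(res)
      if (verbose) message(sprintf("case %d: FAILED (%s)", i, out$message[i]))
      next
    }
    out$initial_work[i] <- res$initial_work
    out$apex_disp_pressurization[i] <- res$apex_disp
    out$t_intersection[i] <- res$t_int
    out$work_at_intersection[i] <- res$w_int
    out$ratio[i] <- res$ratio
    out$t_maxvel[i] <- res$t_mv
    out$t_applanation[i] <- res$t_ap
    out$lag[i] <- res$t_mv - res$t_ap
    out$max_apex_displacement[i] <- res$max_disp
    out$cavity_peak_mmHg[i] <- res$p_peak
    out$ok[i] <- TRUE
    if (verbose)
      message(sprintf(
        "case %2d: W0 = %.4f mJ, t_int = %.2f ms, t_maxvel = %.2f ms, t_app = %.2f ms",
        i, res$initial_work, res$t_int, res$t_mv, res$t_ap))
  }
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Ordinary least-squares quadratic fit
#'
#' Fits `y = a x^2 + b x + c` and reports the coefficient of determination
#' `R^2 = 1 - SS_res/SS_tot`.
#'
#' @param x,y numeric vectors (at least three distinct `x`).
#' @return object of class `quad_fit` with `coefficients` (quadratic,
#'   linear, constant), `r_squared`, `n`.
#' @examples
#' f <- fit_quadratic(1:5, (1:5)^2)
#' f$coefficients
#' @export
fit_quadratic <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_wiop("at least 3 points are required")
  if (length(unique(x)) < 3L)
    stop_wiop("rank-deficient design: fewer than 3 distinct x values")
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  if (any(is.na(cf))) stop_wiop("rank-deficient design")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < .Machine$double.eps) NA_real_ else 1 - ss_res / ss_tot
  structure(list(coefficients = c(quadratic = unname(cf[3L]),
                                  linear = unname(cf[2L]),
                                  constant = unname(cf[1L])),
                 r_squared = r2, n = length(x)),
            class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf("<quad_fit> y = %.4g x^2 + %.4g x + %.4g  (R^2 = %.4f, n = %d)\n",
              x$coefficients[1L], x$coefficients[2L], x$coefficients[3L],
              if (is.na(x$r_squared)) NaN else x$r_squared, x$n))
  invisible(x)
}

#' Evaluate a polynomial given in descending-power order
#'
#' @param coefficients numeric vector, highest power first.
#' @param x evaluation points.
#' @return numeric vector.
#' @export
polynomial_value <- function(coefficients, x) {
  out <- rep(0, length(x))
  for (c_k in coefficients) out <- out * x + c_k
  out
}

#' Compose the two quadratic calibrations into the quartic pressure map
#'
#' The pressurisation calibration maps the initial work of the IOP to the
#' IOP, `IOP = A w^2 + B w + C`; the air-jet calibration maps the
#' maximum-velocity time to the initial work, `w = a t^2 + b t + c`.
#' Their exact algebraic composition is the quartic
#' `wIOP(t) = q4 t^4 + q3 t^3 + q2 t^2 + q1 t + q0` with
#' `q4 = A a^2`, `q3 = 2 A a b`, `q2 = A (2 a c + b^2) + B a`,
#' `q1 = 2 A b c + B b`, `q0 = A c^2 + B c + C`.
#'
#' @param work_to_iop pressurisation calibration: a [fit_quadratic()] result or a
#'   numeric triple (quadratic, linear, constant) mapping mJ to mmHg.
#' @param time_to_work time calibration: same form, mapping ms to mJ.
#' @return named numeric vector of class `wiop_quartic` (t^4 ... constant),
#'   mmHg as a function of ms.
#' @examples
#' compose_wiop(c(0, 1, 0), c(0, 1, 0))  # identity composition
#' @export
compose_wiop <- function(work_to_iop, time_to_work) {
  get3 <- function(q, nm) {
    v <- if (inherits(q, "quad_fit")) q$coefficients else as.numeric(q)
    if (length(v) != 3L) stop_wiop(nm, " must have 3 coefficients")
    unname(v)
  }
  outer <- get3(work_to_iop, "work_to_iop")
  inner <- get3(time_to_work, "time_to_work")
  A <- outer[1L]; B <- outer[2L]; C <- outer[3L]
  a <- inner[1L]; b <- inner[2L]; c <- inner[3L]
  structure(c(t4 = A * a^2,
              t3 = 2 * A * a * b,
              t2 = A * (2 * a * c + b^2) + B * a,
              t1 = 2 * A * b * c + B * b,
              t0 = A * c^2 + B * c + C),
            class = "wiop_quartic")
}

#' Calibrate the work-based pressure estimator from a sweep
#'
#' Fits the pressurisation calibration (IOP versus initial work of the IOP)
#' and the time calibration (initial work versus maximum-velocity time) on
#' the pressure-varying cases of a [run_sweep()] result, and composes them
#' into the quartic pressure map.
#'
#' @param sweep a `sweep_result`.
#' @param fit_cases row indices used for the two fits; by default the
#'   pressure series (the sweep rows whose IOP is unique to the series,
#'   cases 1-5 of the standard design).
#' @return object of class `calibration_fit` with fields `work_to_iop`, `time_to_work`
#'   ([fit_quadratic()] results), `quartic` and `time_range` (range of
#'   maximum-velocity times over all successful cases, ms).
#' @export
calibrate_wiop <- function(sweep, fit_cases = 1:5) {
  stopifnot(inherits(sweep, "sweep_result"))
  rows <- sweep[fit_cases, ]
  rows <- rows[rows$ok, ]
  if (nrow(rows) < 3L) stop_wiop("not enough successful cases to calibrate")
  work_to_iop <- fit_quadratic(rows$initial_work, rows$IOP)
  time_to_work <- fit_quadratic(rows$t_maxvel, rows$initial_work)
  structure(list(work_to_iop = work_to_iop, time_to_work = time_to_work,
                 quartic = compose_wiop(work_to_iop, time_to_work),
                 time_range = range(sweep$t_maxvel[sweep$ok]),
                 source = "reproduction sweep"),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>", x$source, "\n")
  cat("  pressurisation (mJ -> mmHg): ")
  print(x$work_to_iop)
  cat("  time (ms -> mJ): ")
  print(x$time_to_work)
  q <- signif(unclass(x$quartic), 3)
  cat(sprintf("  wIOP(t) = %.3g t^4 + %.3g t^3 + %.3g t^2 + %.3g t + %.4g  [mmHg]\n",
              q[1L], q[2L], q[3L], q[4L], signif(x$quartic[5L], 4)))
  cat(sprintf("  fitted time range [%.2f, %.2f] ms\n",
              x$time_range[1L], x$time_range[2L]))
  invisible(x)
}
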