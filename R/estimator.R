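#' Shipped default calibration of the work-based pressure estimator
#'
#' The published quadratic calibrations relating (i) the intraocular
#' pressure to the initial work of the IOP at the end of pressurisation,
#' `IOP = -1.69e3 w^2 + 4.21e2 w + 6.18` (both reported with R^2 = 0.98),
#' and (ii) the initial work to the maximum-apex-velocity time,
#' `w = 1.09e-3 t^2 - 8.28e-3 t + 1.19e-2`, together with their published
#' quartic composition
#' `wIOP(t) = -2.01e-3 t^4 + 3.05e-2 t^3 + 2.99e-1 t^2 - 3.15 t + 10.95`.
#' These constants come from full fluid-structure simulations of the
#' device; [calibrate_wiop()] re-derives reduced-order analogues. The fitted
#' validity interval is not published; the stored default is the
#' maximum-velocity-time span of the published pressure series (obtained by
#' inverting the two quadratics at 10 and 30 mmHg) and is configurable --
#' outside it the estimate is flagged as extrapolated, not refused.
#'
#' @param time_range validity interval for the maximum-velocity time, ms.
#' @return a `calibration_fit`.
#' @export
default_calibration <- function(time_range = c(6.8, 12.9)) {
  work_to_iop <- structure(
    list(coefficients = c(quadratic = -1.69e3, linear = 4.21e2,
                          constant = 6.18),
         r_squared = 0.98, n = 5L),
    class = "quad_fit")
  time_to_work <- structure(
    list(coefficients = c(quadratic = 1.09e-3, linear = -8.28e-3,
                          constant = 1.19e-2),
         r_squared = 0.98, n = 5L),
    class = "quad_fit")
  structure(list(work_to_iop = work_to_iop, time_to_work = time_to_work,
                 quartic = structure(c(t4 = -2.01e-3, t3 = 3.05e-2,
                                       t2 = 2.99e-1, t1 = -3.15,
                                       t0 = 10.95),
                                     class = "wiop_quartic"),
                 time_range = time_range,
                 source = "published device calibration"),
            class = "calibration_fit")
}

#' Estimate the work-based intraocular pressure from a velocity trace
#'
#' Detects the maximum-apex-velocity time -- the instant at which the works
#' acting on the anterior corneal surface are equal, independent of the
#' corneal material and thickness -- and evaluates the quartic calibration
#' at it.
#'
#' @param trace a [velocity_trace()].
#' @param calibration a `calibration_fit`; defaults to the shipped
#'   published calibration.
#' @param smooth_window forwarded to [max_velocity_time()].
#' @return object of class `wiop_estimate` with fields `wIOP` (mmHg),
#'   `t_maxvel`, `t_applanation`, `lag` (ms; applanation entries `NA` when
#'   the trace carries no applanation information) and `extrapolated`.
#' @examples
#' tr <- generate_trace("healthy", t_app = 7, lag = 2, seed = 1)
#' estimate_wiop(tr)
#' @export
estimate_wiop <- function(trace, calibration = default_calibration(),
                          smooth_window = NULL) {
  stopifnot(inherits(trace, "velocity_trace"),
            inherits(calibration, "calibration_fit"))
  t_mv <- max_velocity_time(trace, smooth_window = smooth_window)
  wiop <- polynomial_value(unclass(calibration$quartic), t_mv)
  t_app <- attr(trace, "t_applanation")
  if (is.null(t_app)) t_app <- NA_real_
  structure(list(wIOP = wiop,
                 t_maxvel = t_mv,
                 t_applanation = t_app,
                 lag = t_mv - t_app,
                 extrapolated = t_mv < calibration$time_range[1L] ||
                   t_mv > calibration$time_range[2L],
                 calibration_source = calibration$source),
            class = "wiop_estimate")
}

#' @export
print.wiop_estimate <- function(x, ...) {
  cat(sprintf("<wiop_estimate> wIOP = %.2f mmHg at t_maxvel = %.2f ms%s\n",
              x$wIOP, x$t_maxvel,
              if (x$extrapolated) " [EXTRAPOLATED beyond the fitted range]"
              else ""))
  if (!is.na(x$t_applanation))
    cat(sprintf("  first applanation %.2f ms; lag to peak velocity %.2f ms\n",
                x$t_applanation, x$lag))
  cat("  calibration:", x$calibration_source, "\n")
  invisible(x)
}

#' Compare the first-applanation and maximum-velocity instants of a trace
#'
#' Classical non-contact tonometry reads the pressure at the first
#' applanation; the work-based analysis shows the energetically meaningful
#' instant is the (later) maximum-velocity time. This report quantifies the
#' per-trace difference.
#'
#' @param trace a [velocity_trace()].
#' @param t_applanation first-applanation time, ms; defaults to the value
#'   carried by the trace. When unavailable a partial report (with `NA`
#'   applanation fields) is returned.
#' @return object of class `applanation_comparison` with fields
#'   `t_applanation`, `t_maxvel`, `difference` (ms) and `ordering_ok`
#'   (`TRUE` when applanation precedes the velocity peak).
#' @export
compare_with_applanation <- function(trace, t_applanation = NULL) {
  stopifnot(inherits(trace, "velocity_trace"))
  if (is.null(t_applanation)) t_applanation <- attr(trace, "t_applanation")
  t_mv <- max_velocity_time(trace)
  if (is.null(t_applanation)) {
    out <- list(t_applanation = NA_real_, t_maxvel = t_mv,
                difference = NA_real_, ordering_ok = NA,
                partial = TRUE)
  } else {
    out <- list(t_applanation = t_applanation, t_maxvel = t_mv,
                difference = t_mv - t_applanation,
                ordering_ok = t_applanation < t_mv,
                partial = FALSE)
  }
  structure(out, class = "applanation_comparison")
}

#' @export
print.applanation_comparison <- function(x, ...) {
  if (x$partial) {
    cat(sprintf("<applanation_comparison> t_maxvel = %.2f ms; no applanation data (partial report)\n",
                x$t_maxvel))
  } else {
    cat(sprintf("<applanation_comparison> t_app1 = %.2f ms, t_maxvel = %.2f ms, difference = %.2f ms\n",
                x$t_applanation, x$t_maxvel, x$difference))
  }
  invisible(x)
}
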