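#' Apex velocity trace
#'
#' Device-style sampled apex-velocity signal: the Scheimpflug camera of a
#' non-contact tonometer records about 140 frames over the 30 ms air pulse,
#' from which the instrument reports the corneal apex velocity. Time is
#' measured from the load onset (ms); velocity is positive toward the
#' interior of the eye (mm/ms).
#'
#' @param time sample times, ms; strictly increasing.
#' @param velocity apex velocity samples, mm/ms.
#' @param displacement optional apex displacement, mm.
#' @param provenance one of `"simulated"`, `"clinical-style"`,
#'   `"synthetic"`.
#' @param t_applanation optional known first-applanation time, ms (device
#'   exports report it; synthetic traces carry their ground truth).
#' @return data frame of class `velocity_trace`.
#' @export
velocity_trace <- function(time, velocity, displacement = NULL,
                           provenance = c("clinical-style", "simulated",
                                          "synthetic"),
                           t_applanation = NULL) {
  provenance <- match.arg(provenance)
  if (length(time) != length(velocity))
    stop_wiop("time and velocity must have equal length")
  if (any(!is.finite(time)) || any(!is.finite(velocity)))
    stop_wiop("trace samples must be finite")
  if (any(diff(time) <= 0))
    stop_wiop("time must be strictly increasing")
  out <- data.frame(time = time, velocity = velocity)
  if (!is.null(displacement)) out$displacement <- displacement
  attr(out, "provenance") <- provenance
  attr(out, "t_applanation") <- t_applanation
  class(out) <- c("velocity_trace", "data.frame")
  out
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("<velocity_trace> %d samples over [%.2f, %.2f] ms (%s)\n",
              nrow(x), x$time[1L], x$time[nrow(x)], attr(x, "provenance")))
  cat(sprintf("  peak velocity %.4g mm/ms near t = %.2f ms\n",
              max(x$velocity), x$time[which.max(x$velocity)]))
  invisible(x)
}

#' @export
plot.velocity_trace <- function(x, ...) {
  graphics::plot(x$time, x$velocity, type = "l",
                 xlab = "time [ms]", ylab = "apex velocity [mm/ms]", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

moving_average <- function(v, window) {
  if (window <= 1L) return(v)
  if (window %% 2L == 0L) window <- window + 1L
  k <- rep(1 / window, window)
  pad <- (window - 1L) %/% 2L
  vp <- c(rep(v[1L], pad), v, rep(v[length(v)], pad))
  stats::filter(vp, k, sides = 2L)[(pad + 1L):(pad + length(v))]
}

#' Time of maximum apex velocity
#'
#' Locates the global maximum of the (optionally smoothed) inward velocity
#' and refines it by a three-point quadratic fit around the discrete peak.
#' The corneal velocity is maximal when the corneal acceleration -- and
#' hence the net force on the cornea -- vanishes; this instant drives the
#' work-based pressure estimate.
#'
#' @param trace a [velocity_trace()].
#' @param smooth_window moving-average window (samples) applied before the
#'   peak search; the 3-sample default suppresses sampling-scale ripple in
#'   both device-style and simulated traces.
#' @param refine logical; quadratic sub-sample refinement of the peak time.
#' @return peak time, ms (on the trace time base).
#' @export
max_velocity_time <- function(trace, smooth_window = NULL, refine = TRUE) {
  stopifnot(inherits(trace, "velocity_trace"))
  if (nrow(trace) < 3L) stop_wiop("trace too short for peak detection")
  if (is.null(smooth_window)) smooth_window <- 3L
  v <- moving_average(trace$velocity, smooth_window)
  tt <- trace$time
  k <- which.max(v)
  if (k == 1L || k == nrow(trace))
    stop_wiop("no interior velocity maximum: the trace is monotone over ",
              "the sampled window")
  if (!refine) return(tt[k])
  # least-squares parabola over a neighbourhood of the discrete peak; the
  # window grows with the smoothing so noisy traces use more support
  m <- max(1L, smooth_window %/% 2L + 1L)
  sel <- max(1L, k - m):min(nrow(trace), k + m)
  ts <- tt[sel] - tt[k]
  cf <- stats::lm.fit(cbind(1, ts, ts^2), v[sel])$coefficients
  if (!is.finite(cf[3L]) || cf[3L] >= 0) return(tt[k])
  t_pk <- tt[k] - cf[2L] / (2 * cf[3L])
  min(max(t_pk, tt[sel][1L]), tt[sel][length(sel)])
}

# signed apex curvature (1/mm) of the central chord of an anterior profile;
# negative = convex outward, positive = concave
central_curvature <- function(r, y, chord = 3) {
  sel <- which(abs(r) <= chord / 2)
  if (length(sel) < 3L)
    stop_wiop("fewer than 3 profile points inside the central chord")
  fit <- stats::lm.fit(cbind(1, r[sel]^2), y[sel])
  2 * fit$coefficients[2L]
}

#' Container for anterior-profile snapshots
#'
#' A minimal sequence of central corneal profiles, one per instant, for
#' applanation detection outside a full simulation (constructed deformations
#' and tests).
#'
#' @param times instants, ms.
#' @param profiles list of two-column matrices (r, y in mm), one per time.
#' @return object of class `profile_set`.
#' @export
profile_set <- function(times, profiles) {
  if (length(times) != length(profiles))
    stop_wiop("times and profiles must have equal length")
  structure(list(times = times, profiles = profiles), class = "profile_set")
}

#' Time of first applanation
#'
#' The instant at which the central cornea first becomes locally flat under
#' the external load: the best-fit curvature of the central 3 mm chord of
#' the anterior profile drops below `1/flat_radius` in magnitude (default
#' threshold: radius of curvature beyond 1 m). The crossing is located by
#' linear interpolation between output increments; times are reported
#' relative to the load onset.
#'
#' @param x a `sim_trajectory` or a [profile_set()].
#' @param chord central chord width used for the flatness fit, mm.
#' @param flat_radius radius-of-curvature threshold, mm.
#' @param ... unused.
#' @return applanation time, ms after load onset; `NA` with attribute
#'   `reason = "not reached"` if the profile never flattens in the record.
#' @export
first_applanation_time <- function(x, chord = 3, flat_radius = 1000, ...) {
  UseMethod("first_applanation_time")
}

applanation_from_curvature <- function(times, kappa, onset, threshold) {
  # flat once the signed curvature rises above -threshold (convex -> flat)
  flat <- kappa >= -threshold
  if (flat[1L]) return(max(times[1L] - onset, 0))
  k <- which(flat)[1L]
  if (is.na(k))
    return(structure(NA_real_, reason = "not reached"))
  f <- (-threshold - kappa[k - 1L]) / (kappa[k] - kappa[k - 1L])
  t_app <- times[k - 1L] + f * (times[k] - times[k - 1L])
  t_app - onset
}

#' @rdname first_applanation_time
#' @export
first_applanation_time.sim_trajectory <- function(x, chord = 3,
                                                  flat_radius = 1000, ...) {
  ant <- x$anterior
  sel <- which(x$time >= x$load_onset - 1e-9)
  if (length(sel) < 2L) stop_wiop("trajectory does not cover the load window")
  kappa <- vapply(sel, function(k)
    central_curvature(x$pos_r[ant, k], x$pos_y[ant, k], chord), 0)
  applanation_from_curvature(x$time[sel], kappa, x$load_onset,
                             1 / flat_radius)
}

#' @rdname first_applanation_time
#' @export
first_applanation_time.profile_set <- function(x, chord = 3,
                                               flat_radius = 1000, ...) {
  kappa <- vapply(x$profiles, function(p)
    central_curvature(p[, 1L], p[, 2L], chord), 0)
  applanation_from_curvature(x$times, kappa, x$times[1L], 1 / flat_radius)
}
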