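# run code with a private, restorable RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic apex-velocity trace with known ground truth
#'
#' Parametric waveform emulating the morphology of device traces: inward
#' acceleration from the load onset, first applanation while the velocity
#' is still rising, the velocity maximum 1-5 ms later, deceleration to zero
#' at highest concavity, then an outward rebound lobe; additive Gaussian
#' measurement noise on top. The two archetypes differ only in their
#' default peak-amplitude and lag distributions (softer keratoconic-like
#' corneas applanate earlier and move faster); they exercise batch
#' behaviour and make no claim of clinical realism.
#'
#' @param archetype `"healthy"` or `"keratoconic"`.
#' @param t_app first-applanation time, ms; drawn from the archetype
#'   distribution when `NULL`.
#' @param lag delay from first applanation to the velocity maximum, ms
#'   (non-negative); drawn uniformly from the archetype range when `NULL`.
#' @param peak_velocity peak inward velocity, mm/ms.
#' @param noise_sd additive noise standard deviation, mm/ms.
#' @param n number of samples (device default: 140 over 30 ms).
#' @param duration trace duration, ms.
#' @param peak_sharpness,peak_width shape of the summit: the base inward
#'   sine lobe is multiplied by
#'   `1 - peak_sharpness + peak_sharpness * exp(-((t - t_pk)/peak_width)^2)`,
#'   which leaves the maximum exactly at `t_app + lag` while giving the
#'   summit the localised curvature seen in device traces (a perfectly flat
#'   sine summit could not be timed under measurement noise).
#' @param seed integer seed for reproducibility.
#' @return a [velocity_trace()] with provenance `"synthetic"`, carrying
#'   attributes `t_maxvel_true`, `t_applanation` and the generating
#'   parameters.
#' @examples
#' tr <- generate_trace("healthy", t_app = 7, lag = 2, seed = 42)
#' attr(tr, "t_maxvel_true")
#' @export
generate_trace <- function(archetype = c("healthy", "keratoconic"),
                           t_app = NULL, lag = NULL, peak_velocity = NULL,
                           noise_sd = 0.004, n = 140, duration = 30,
                           peak_sharpness = 0.6, peak_width = 1,
                           seed = NULL) {
  archetype <- match.arg(archetype)
  with_seed(seed, {
    if (is.null(t_app))
      t_app <- stats::rnorm(1, if (archetype == "healthy") 7.5 else 6.5,
                            if (archetype == "healthy") 0.4 else 0.6)
    if (is.null(lag))
      lag <- if (archetype == "healthy") stats::runif(1, 1, 3)
             else stats::runif(1, 2, 5)
    if (is.null(peak_velocity))
      peak_velocity <- stats::rnorm(1, if (archetype == "healthy") 0.16
                                    else 0.24,
                                    if (archetype == "healthy") 0.02
                                    else 0.03)
    if (lag < 0) stop_wiop("lag must be non-negative")
    t_pk <- t_app + lag
    if (t_pk >= duration / 2)
      stop_wiop("t_app + lag must be below half the trace duration")
    tt <- seq(0, duration, length.out = n)
    v <- numeric(n)
    first <- tt <= 2 * t_pk
    # inward lobe: exact maximum at t_pk, zero (highest concavity) at 2 t_pk;
    # both factors are stationary at t_pk, so the sharpener moves no events
    sharp <- 1 - peak_sharpness +
      peak_sharpness * exp(-((tt[first] - t_pk) / peak_width)^2)
    v[first] <- peak_velocity * sin(pi * tt[first] / (2 * t_pk)) * sharp
    t_reb <- max((duration - 2 * t_pk) / 2, 1)
    reb <- !first & tt <= 2 * t_pk + 2 * t_reb
    v[reb] <- -0.45 * peak_velocity *
      sin(pi * (tt[reb] - 2 * t_pk) / (2 * t_reb))
    if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
    out <- velocity_trace(tt, v, provenance = "synthetic",
                          t_applanation = t_app)
    attr(out, "t_maxvel_true") <- t_pk
    attr(out, "params") <- list(archetype = archetype, t_app = t_app,
                                lag = lag, peak_velocity = peak_velocity,
                                noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Generate a toy pair of work curves with a known crossing
#'
#' Builds a monotone-decreasing internal-work curve starting from
#' `initial_work` and a monotone-increasing external-work curve that cross
#' exactly once, at `crossing_time` with value `crossing_value`, for testing
#' the intersection detector against ground truth.
#'
#' @param initial_work internal work at the load onset, mJ.
#' @param crossing_time crossing instant, ms; inside `(0, duration)`.
#' @param crossing_value work at the crossing, mJ; defaults to half the
#'   initial work, the relation observed across the pressure series.
#' @param duration window length, ms.
#' @param n samples.
#' @param p_down,p_up shape exponents of the two power-law curves.
#' @param noise_sd additive noise, mJ.
#' @param seed integer seed.
#' @return a `work_ledger`-classed data frame (`time`, `work_iop`,
#'   `work_ext`) with attributes `initial_work`, `load_onset = 0`,
#'   `crossing_time_true`, `crossing_value_true`.
#' @export
generate_work_curves <- function(initial_work, crossing_time,
                                 crossing_value = initial_work / 2,
                                 duration = 30, n = 140,
                                 p_down = 1.5, p_up = 2,
                                 noise_sd = 0, seed = NULL) {
  if (crossing_time <= 0 || crossing_time >= duration)
    stop_wiop("crossing_time must lie inside the window")
  if (crossing_value <= 0 || crossing_value >= initial_work)
    stop_wiop("crossing_value must lie strictly between 0 and initial_work")
  with_seed(seed, {
    tt <- seq(0, duration, length.out = n)
    xi <- tt / crossing_time
    w_iop <- initial_work - (initial_work - crossing_value) * xi^p_down
    w_ext <- crossing_value * xi^p_up
    if (noise_sd > 0) {
      w_iop <- w_iop + stats::rnorm(n, 0, noise_sd)
      w_ext <- w_ext + stats::rnorm(n, 0, noise_sd)
    }
    out <- data.frame(time = tt, work_iop = w_iop, work_ext = w_ext)
    attr(out, "load_onset") <- 0
    attr(out, "initial_work") <- initial_work
    attr(out, "scenario") <- "synthetic"
    attr(out, "crossing_time_true") <- crossing_time
    attr(out, "crossing_value_true") <- crossing_value
    class(out) <- c("work_ledger", "data.frame")
    out
  })
}
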