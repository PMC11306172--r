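test_that("the default quartic evaluates exactly and flags extrapolation", {
  cal <- default_calibration()
  tt <- c(0, 3.7, 8.1, 15)
  direct <- -2.01e-3 * tt^4 + 3.05e-2 * tt^3 + 2.99e-1 * tt^2 -
    3.15 * tt + 10.95
  expect_equal(polynomial_value(unclass(cal$quartic), tt), direct,
               tolerance = 1e-12)
  # boundary value at zero time is the published constant term
  expect_equal(polynomial_value(unclass(cal$quartic), 0), 10.95)

  # a trace peaking (essentially) at t = 0 is outside the fitted range
  tt2 <- seq(0, 30, length.out = 140L)
  v <- exp(-(tt2 - 0.8)^2 / 0.18)
  tr <- velocity_trace(tt2, v, provenance = "synthetic")
  est <- estimate_wiop(tr)
  expect_true(est$extrapolated)
})

test_that("the estimate depends on the peak time, not the amplitude", {
  tr <- generate_trace("healthy", t_app = 7, lag = 2, peak_velocity = 0.16,
                       noise_sd = 0, seed = 2)
  e1 <- estimate_wiop(tr)
  tr2 <- velocity_trace(tr$time, 5 * tr$velocity, provenance = "synthetic",
                        t_applanation = attr(tr, "t_applanation"))
  e2 <- estimate_wiop(tr2)
  expect_equal(e1$wIOP, e2$wIOP, tolerance = 1e-9)
  expect_false(e1$extrapolated)
})

test_that("estimates match the quartic at the known ground-truth peak", {
  cal <- default_calibration()
  grid <- seq(7, 11, by = 0.5)
  dt <- 30 / 139
  # slope bound of the quartic over the grid converts 1-sample timing error
  # into a pressure tolerance
  slope <- max(abs(diff(polynomial_value(unclass(cal$quartic),
                                         seq(6.5, 11.5, by = 0.01)))) / 0.01)
  for (tp in grid) {
    tr <- generate_trace("healthy", t_app = tp - 2, lag = 2,
                         peak_velocity = 0.18, noise_sd = 0, seed = 1)
    est <- estimate_wiop(tr)
    truth <- polynomial_value(unclass(cal$quartic), tp)
    expect_lt(abs(est$wIOP - truth), slope * dt)
  }
})

test_that("the default calibration is increasing over its fitted range", {
  # a later work intersection reflects a larger initial work of the IOP and
  # hence a higher pressure: the quartic rises monotonically across the
  # physiological fitted interval
  cal <- default_calibration()
  tt <- seq(cal$time_range[1L], cal$time_range[2L], length.out = 200L)
  w <- polynomial_value(unclass(cal$quartic), tt)
  expect_true(all(diff(w) > 0))
  # and spans the clinical range across the fitted interval
  expect_lt(w[1L], 12)
  expect_gt(w[length(w)], 25)
})

test_that("applanation comparison orders the events and varies per trace", {
  tr <- generate_trace("healthy", t_app = 7.2, lag = 2.4, noise_sd = 0.002,
                       seed = 4)
  cmp <- compare_with_applanation(tr)
  expect_false(cmp$partial)
  expect_true(cmp$ordering_ok)
  expect_equal(cmp$difference, 2.4, tolerance = 0.25)

  # a trace where the two instants coincide by construction
  cmp0 <- compare_with_applanation(tr, t_applanation = cmp$t_maxvel)
  expect_equal(cmp0$difference, 0)

  # batch over the two archetypes: differences vary between patients
  diffs <- vapply(1:12, function(s) {
    arch <- if (s <= 6) "healthy" else "keratoconic"
    compare_with_applanation(generate_trace(arch, seed = s))$difference
  }, 0)
  expect_true(all(diffs > 0))
  expect_gt(stats::sd(diffs), 0.2)

  # partial report when no applanation information exists
  plain <- velocity_trace(tr$time, tr$velocity, provenance = "synthetic")
  expect_true(compare_with_applanation(plain)$partial)
})

test_that("events files record both instants and their difference", {
  tr <- generate_trace("healthy", t_app = 7, lag = 2, noise_sd = 0, seed = 3)
  cmp <- compare_with_applanation(tr)
  path <- tempfile(fileext = ".tsv")
  write_events(cmp, path)
  back <- utils::read.table(path, header = TRUE, comment.char = "#")
  expect_equal(back$t_applanation1, 7)
  expect_equal(back$difference, back$t_maxvel - back$t_applanation1)
})

test_that("estimates survive the device-style file round trip", {
  tr <- generate_trace("keratoconic", t_app = 6.5, lag = 3, seed = 8)
  path <- tempfile(fileext = ".csv")
  write_velocity_trace(tr, path)
  back <- read_velocity_trace(path)
  expect_equal(attr(back, "t_applanation"), 6.5, tolerance = 1e-6)
  e1 <- estimate_wiop(tr)
  e2 <- estimate_wiop(back)
  expect_equal(e2$wIOP, e1$wIOP, tolerance = 1e-6)
  expect_equal(e2$lag, e1$lag, tolerance = 1e-6)
})
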