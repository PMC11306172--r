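test_that("quadratic fits recover exact and noisy coefficients", {
  x <- seq(-2, 3, length.out = 9L)
  y <- 1.5 * x^2 - 0.7 * x + 0.2
  f <- fit_quadratic(x, y)
  expect_equal(unname(f$coefficients), c(1.5, -0.7, 0.2), tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  # five points from the published pressurisation quadratic with 1% noise:
  # the fitted curve stays within 5% of the true curve over the design range
  # (individual coefficients of a 5-point quadratic trade off against each
  # other and are not pinned this tightly by 1% noise)
  set.seed(14)
  w <- c(0.0069, 0.016, 0.039, 0.062, 0.087)
  truth <- c(-1.69e3, 4.21e2, 6.18)
  iop <- polynomial_value(truth, w)
  iop_n <- iop * (1 + stats::rnorm(5, 0, 0.01))
  fn <- fit_quadratic(w, iop_n)
  grid <- seq(min(w), max(w), length.out = 50L)
  rel <- abs(polynomial_value(unname(fn$coefficients), grid) -
               polynomial_value(truth, grid)) / polynomial_value(truth, grid)
  expect_lt(max(rel), 0.05)
  expect_gt(fn$r_squared, 0.99)

  # constant response: vanishing quadratic and linear terms
  fc <- fit_quadratic(1:5, rep(2, 5L))
  expect_equal(unname(fc$coefficients[1:2]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(fc$coefficients[3L]), 2, tolerance = 1e-12)

  expect_error(fit_quadratic(c(1, 1, 1), c(1, 2, 3)), "rank-deficient")
  expect_error(fit_quadratic(1:2, 1:2), "3 points")
})

test_that("quartic composition is algebraically exact", {
  # identity-like quadratics compose to the pure cubic/linear monomial map
  q <- compose_wiop(c(0, 1, 0), c(0, 1, 0))
  expect_equal(unname(unclass(q)), c(0, 0, 0, 1, 0))

  # pointwise oracle on random quadratics: compose then evaluate equals
  # evaluate then evaluate
  set.seed(9)
  for (i in 1:25) {
    e5 <- stats::rnorm(3); e6 <- stats::rnorm(3)
    qq <- compose_wiop(e5, e6)
    tt <- stats::runif(100, -2, 2)
    direct <- polynomial_value(e5, polynomial_value(e6, tt))
    composed <- polynomial_value(unclass(qq), tt)
    expect_equal(composed, direct, tolerance = 1e-12)
  }
})

test_that("composing the published quadratics reproduces the published quartic", {
  work_to_iop <- c(-1.69e3, 4.21e2, 6.18)
  time_to_work <- c(1.09e-3, -8.28e-3, 1.19e-2)
  q <- unclass(compose_wiop(work_to_iop, time_to_work))
  printed <- c(-2.01e-3, 3.05e-2, 2.99e-1, -3.15, 10.95)
  # agreement at each coefficient's printed precision (half an ulp of the
  # printed figure)
  ulp <- c(0.005e-3, 0.005e-2, 0.005e-1, 0.005, 0.005)
  expect_true(all(abs(q - printed) <= ulp))
  # and the published constant is the zero-time boundary value
  expect_equal(unname(q[5L]), 10.95, tolerance = 5e-4)
})

test_that("the sweep design matches the sixteen printed cases", {
  cases <- sweep_cases()
  expect_equal(nrow(cases), 16L)
  expect_equal(cases$IOP[1:5], c(10, 15, 20, 25, 30))
  expect_equal(cases$CCT[14:16], c(484, 525, 600))
  expect_equal(cases$k2[12], 1000)
  # the shipped sweep file round-trips through the table reader
  path <- system.file("extdata", "sweep_design.tsv", package = "wiop")
  expect_true(nzchar(path))
  tab <- read_material_table(path)
  expect_equal(tab$C10, cases$C10)
  expect_equal(tab$CCT, cases$CCT)
})

test_that("calibration on the pressure series composes into a usable quartic", {
  sw <- fix_sweep()
  expect_true(all(sw$ok[1:5]))
  cal <- calibrate_wiop(sw)
  expect_s3_class(cal$work_to_iop, "quad_fit")
  expect_gt(cal$work_to_iop$r_squared, 0.9)
  expect_gt(cal$time_to_work$r_squared, 0.9)
  # composed quartic equals the two-step evaluation on the fitted range
  tt <- seq(cal$time_range[1L], cal$time_range[2L], length.out = 50L)
  two_step <- polynomial_value(cal$work_to_iop$coefficients,
                               polynomial_value(cal$time_to_work$coefficients, tt))
  expect_equal(polynomial_value(unclass(cal$quartic), tt), two_step,
               tolerance = 1e-10)
  # calibrations survive a JSON round trip
  path <- tempfile(fileext = ".json")
  write_calibration(cal, path)
  cal2 <- read_calibration(path)
  expect_equal(unclass(cal2$quartic), unclass(cal$quartic),
               tolerance = 1e-12)
})

test_that("intersection time grows monotonically along the pressure series", {
  sw <- fix_sweep()
  t_int <- sw$t_intersection[1:5]
  expect_true(all(is.finite(t_int)))
  expect_true(all(diff(t_int) > 0))
})
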