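test_that("trapezoidal surface work handles the rigid-translation patch", {
  # constant pressure P on a flat patch of total projected area A translated
  # by d along y: work = P * A * d exactly, whatever the node count
  n <- 7L; K <- 11L
  A <- matrix(rep(c(0.2, 0.3, 0.1, 0.25, 0.05, 0.06, 0.04), K), n, K)
  P <- 2e-3
  d <- 0.75
  Y <- matrix(rep(seq(0, d, length.out = K), each = n), n, K)
  W <- wiop:::trapezoidal_surface_work(P * A, Y)
  expect_equal(W[K], P * sum(A[, 1L]) * d, tolerance = 1e-12)
  expect_equal(W[1L], 0)
  # zero displacement gives identically zero work
  Y0 <- matrix(1, n, K)
  expect_equal(wiop:::trapezoidal_surface_work(P * A, Y0), rep(0, K))
})

test_that("trapezoidal work converges at second order to the fine integral", {
  # smooth synthetic history: ramping pressure with sinusoidal displacement
  n <- 5L
  phi <- seq(0.5, 1, length.out = n)
  history <- function(K) {
    tt <- seq(0, 1, length.out = K)
    P <- outer(phi, tt^2 + 0.2)
    A <- outer(phi, rep(1, K)) * (1 + 0.1 * sin(outer(phi, tt)))
    Y <- outer(phi, sin(pi * tt / 2))
    list(F = P * A, Y = Y)
  }
  fine <- history(100001L)
  W_ref <- wiop:::trapezoidal_surface_work(fine$F, fine$Y)
  W_ref <- W_ref[length(W_ref)]
  err <- vapply(c(101L, 201L, 401L), function(K) {
    h <- history(K)
    W <- wiop:::trapezoidal_surface_work(h$F, h$Y)
    abs(W[length(W)] - W_ref)
  }, 0)
  expect_lt(err[1L] / abs(W_ref), 1e-3)
  # halving the step divides the error by about four (O(dt^2))
  expect_equal(err[1L] / err[2L], 4, tolerance = 0.2)
  expect_equal(err[2L] / err[3L], 4, tolerance = 0.2)
})

test_that("work of the IOP rises on pressurization and falls under loading", {
  led <- fix_puff_run()$ledger
  onset <- attr(led, "load_onset")
  w0 <- attr(led, "initial_work")
  expect_gt(w0, 0)
  # rising during the ramp
  ramp <- led$time <= 10
  expect_gt(led$work_iop[max(which(ramp))], 0.8 * w0)
  # monotone signs during the inward phase of the puff
  tr <- apex_kinematics(fix_puff_run()$traj)
  t_hc <- onset + tr$time[which.min(tr$displacement)]
  inward <- led$time > onset + 1 & led$time < t_hc
  expect_true(all(diff(led$work_iop[inward]) <= 1e-9))
  expect_true(all(diff(led$work_ext[inward]) >= -1e-9))
})

test_that("mass energies satisfy the closed-form free-fall checks", {
  run <- fix_mass_run()
  me <- run$energies
  cfg <- falling_mass_config()
  traj <- run$traj
  pre <- which(!is.na(me$total) & me$time < traj$t_contact)
  # total mechanical energy constant before the impact
  expect_lt(diff(range(me$total[pre])) / max(me$total[pre]), 0.005)
  # at rest at the release height: KE = 0, PE = m g h
  expect_lt(me$kinetic[pre][1L], 1e-4)
  expect_equal(me$potential[pre][1L], cfg$mass * cfg$gravity * 8,
               tolerance = 0.01)
  # kinetic energy at contact equals m g h within 1%
  ke_c <- stats::approx(me$time[pre], me$kinetic[pre],
                        xout = traj$t_contact, rule = 2)$y
  expect_equal(ke_c, cfg$mass * cfg$gravity * cfg$drop_height,
               tolerance = 0.01)
  # total energy strictly decreasing from impact to maximum deformation
  t_maxdef <- traj$time[which.min(traj$apex_y)]
  mid <- which(me$time > traj$t_contact + 0.5 & me$time < t_maxdef)
  expect_true(all(diff(me$total[mid]) < 1e-9))
})

test_that("the cornea-fluid closure holds early in the impact", {
  # in the first phase of the impact the corneal strain-energy gain tracks
  # the magnitude of the work given up by the intraocular pressure
  run <- fix_mass_run()
  led <- run$ledger
  t0 <- run$traj$t_contact
  t_maxdef <- run$traj$time[which.min(run$traj$apex_y)]
  t1 <- t0 + 0.4 * (t_maxdef - t0)
  at <- function(col, t) stats::approx(led$time, led[[col]], xout = t,
                                       rule = 2)$y
  d_cornea <- at("cornea_strain", t1) - at("cornea_strain", t0)
  d_wiop <- at("work_iop", t1) - at("work_iop", t0)
  expect_equal(d_cornea, -d_wiop, tolerance = 0.10)
})

test_that("intersection detection is exact on straight lines", {
  led <- data.frame(time = seq(0, 2, by = 0.01))
  led$work_iop <- 1 - led$time
  led$work_ext <- led$time
  xi <- find_intersection(led, load_onset = 0)
  expect_true(xi$crossed)
  expect_equal(xi$time, 0.5, tolerance = 1e-12)
  expect_equal(xi$work_at_intersection, 0.5, tolerance = 1e-12)
  # no crossing: an explicit result, not an error
  led$work_ext <- led$work_iop - 1
  xi2 <- find_intersection(led, load_onset = 0)
  expect_false(xi2$crossed)
  expect_length(xi2$times, 0L)
})

test_that("the puff work curves cross twice with a sensible primary crossing", {
  led <- fix_puff_run()$ledger
  xi <- find_intersection(led)
  expect_true(xi$crossed)
  expect_gte(length(xi$times), 2L)
  expect_lt(xi$time, xi$times[2L])
  expect_gt(xi$ratio, 0)
  expect_lt(xi$ratio, 1)
  expect_true(all(xi$times > 0 &
                    xi$times < attr(led, "load_onset") + 35))
})

test_that("ledger export writes a self-describing text table", {
  led <- fix_puff_run()$ledger
  path <- tempfile(fileext = ".tsv")
  write_work_ledger(led, path)
  lines <- readLines(path, n = 3L)
  expect_true(grepl("mJ", lines[1L]))
  back <- utils::read.table(path, header = TRUE, comment.char = "#")
  expect_equal(nrow(back), nrow(led))
  expect_equal(back$work_iop, led$work_iop, tolerance = 1e-6)
})
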