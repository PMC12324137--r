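test_that("range normalization maps extremes to -1/+1 exactly", {
  ramp <- seq(0, 10, length.out = 50)
  y <- range_normalize(ramp)
  expect_equal(min(y), -1)
  expect_equal(max(y), 1)
  expect_equal(y, seq(-1, 1, length.out = 50))      # linearity preserved

  z <- seq(-1, 1, length.out = 21)
  expect_equal(range_normalize(z), z)               # already normalized

  set.seed(8)
  for (i in 1:5) {
    x <- stats::rnorm(40)
    expect_equal(range_normalize(x), -rev(range_normalize(rev(-x))))
  }
  expect_error(range_normalize(rep(3, 10)), "constant")
})

test_that("velocity estimation is exact on linear and accurate on sine signals", {
  t <- seq(0, 2, 0.01)
  lin <- movement_repetition(cbind(j = 3.5 * t + 1), time = t)
  expect_equal(estimate_velocity(lin, "j"), rep(3.5, length(t)),
               tolerance = 1e-10)

  t2 <- seq(0, 2, 0.001)                            # 1 kHz
  sine <- movement_repetition(cbind(j = sin(t2)), time = t2)
  expect_lt(max(abs(estimate_velocity(sine, "j") - cos(t2))), 1e-4)

  expect_error(estimate_velocity(
    movement_repetition(cbind(j = c(0, 1)), time = c(0, 1)), "j"),
    "at least 3")
  expect_error(movement_repetition(cbind(j = 1:4), time = c(0, 1, 1, 2)),
               "strictly increasing")
})

test_that("noise-ratio guard keeps resolvable joints and zeroes residual ones", {
  big <- seq(0, 40, length.out = 50)                # 40 deg ROM
  expect_equal(noise_ratio_guard(big, 0.5)$action, "keep")
  tiny <- seq(0, 0.2, length.out = 50)              # 0.2 deg ROM, 1 deg noise
  expect_equal(noise_ratio_guard(tiny, 1)$action, "zero_substitute")
  expect_gt(noise_ratio_guard(tiny, 1)$ratio, 1)

  t <- seq(0, 1, 0.01)
  repn <- movement_repetition(cbind(a = sin(2 * pi * t),
                                    b = 0.001 * cos(2 * pi * t)), time = t)
  pp <- phase_portrait(repn, "b", noise_range = 1)
  expect_false(pp$contributing)
  expect_true(all(pp$phase == 0))
  # CRP against a zeroed joint reduces to the other joint's phase
  pa <- phase_portrait(repn, "a", noise_range = 1)
  cv <- crp(pa, pp)
  expect_equal(cv$values, wrap_pi_test(-pa$phase))
})

test_that("phase angles resolve all quadrants and track a cosine analytically", {
  expect_equal(phase_angle(1, 0), 0)
  expect_equal(phase_angle(0, 1), pi / 2)
  expect_equal(phase_angle(-1, 0), pi)              # range is (-pi, pi]
  expect_equal(phase_angle(0, -1), -pi / 2)

  # theta = cos(t) over a whole period: phase approx -t (wrapped)
  t <- seq(0, 2 * pi, length.out = 2001)
  repn <- movement_repetition(cbind(j = cos(t)), time = t)
  pp <- phase_portrait(repn, "j")
  interior <- 10:1990
  err <- wrap_pi_test(pp$phase[interior] + t[interior])
  expect_lt(max(abs(err)), 5e-3)
  # and advances monotonically (mod 2 pi)
  steps <- wrap_pi_test(diff(pp$phase[interior]))
  expect_true(all(steps < 0))
})

test_that("CRP is zero for identical joints, constant for a pure lag, antisymmetric", {
  t <- seq(0, 4, 0.005)                             # whole periods at 1 Hz
  th <- sin(2 * pi * t)
  repn <- movement_repetition(cbind(a = th, b = th), time = t)
  c_same <- crp(phase_portrait(repn, "a"), phase_portrait(repn, "b"))
  expect_lt(max(abs(c_same$values)), 1e-9)

  # a joint ahead in time sits at a lower phase-portrait angle (the
  # portrait of a sinusoid rotates clockwise), so a constant temporal lag
  # delta of the second joint gives a constant CRP of -delta
  delta <- 0.5
  rep2 <- movement_repetition(cbind(a = sin(2 * pi * t),
                                    b = sin(2 * pi * t + delta)), time = t)
  pa <- phase_portrait(rep2, "a"); pb <- phase_portrait(rep2, "b")
  cv <- crp(pa, pb)
  interior <- 50:(length(t) - 50)
  expect_equal(cv$values[interior], rep(-delta, length(interior)),
               tolerance = 1e-2)

  expect_equal(crp(pa, pb)$values, -crp(pb, pa)$values)
  expect_error(crp(1:5, 1:4), "length")
})

test_that("time normalization is exact on linear curves and idempotent on the grid", {
  cv <- crp(seq(0, 1, length.out = 37) * 0, seq(0, 2, length.out = 37),
            time = seq(0, 0.9, length.out = 37))
  tn <- time_normalize(cv, G = 101L)
  expect_equal(tn$grid, seq(0, 100, 1))
  expect_equal(tn$values, seq(0, 2, length.out = 101), tolerance = 1e-12)
  expect_equal(tn$duration, 0.9)
  # already on the target grid: unchanged
  expect_identical(time_normalize(tn, G = 101L), tn)
  # constant curves stay constant whatever the original duration
  const <- crp(rep(0, 20), rep(0.7, 20), time = seq(0, 3, length.out = 20))
  expect_equal(time_normalize(const, G = 51L)$values, rep(0.7, 51))
})

test_that("mean CRP averages time-normalized curves and reports pointwise SD", {
  t <- seq(0, 2, 0.01)
  mk <- function(shift, dur = 2) {
    tt <- seq(0, dur, length.out = length(t))
    movement_repetition(cbind(a = sin(2 * pi * tt / dur),
                              b = sin(2 * pi * tt / dur + shift)), time = tt)
  }
  single <- movement_dataset(list(mk(0.5)), angle_unit = "rad")
  mc1 <- mean_crp(single)
  one <- time_normalize(rep_crp_test(single$repetitions[[1]]), G = 101L)
  expect_equal(mc1$values, one$values)
  expect_equal(mc1$sd, rep(0, 101))

  # identical shapes with different durations average to the common shape
  multi <- movement_dataset(list(mk(0.5, 2), mk(0.5, 3), mk(0.5, 1.5)),
                            angle_unit = "rad")
  mcm <- mean_crp(multi)
  expect_equal(mcm$values, one$values, tolerance = 1e-3)
  expect_lt(max(mcm$sd), 1e-2)
})

test_that("mirror-image curves average to zero", {
  t <- seq(0, 2, 0.01)
  a <- sin(2 * pi * t)
  up <- movement_repetition(cbind(a = a, b = sin(2 * pi * t + 0.4)), time = t)
  dn <- movement_repetition(cbind(a = a, b = sin(2 * pi * t - 0.4)), time = t)
  ds <- movement_dataset(list(up, dn), angle_unit = "rad")
  mc <- mean_crp(ds)
  interior <- 5:97
  expect_lt(max(abs(mc$values[interior])), 2e-2)
})

test_that("JsvCRP is zero on self, symmetric, non-negative, with rectangle-exact areas", {
  sim <- make_sine_datasets(sine_spec())
  expect_equal(as.numeric(jsvcrp(sim$A, sim$A)), 0)
  ab <- as.numeric(jsvcrp(sim$A, sim$B))
  ba <- as.numeric(jsvcrp(sim$B, sim$A))
  expect_gt(ab, 0)
  expect_equal(ab, ba, tolerance = 1e-12)

  # constant mean curves c1, c2 over an axis of length L give |c1 - c2| * L
  c1 <- new_curve_test(seq(0, 100, 1), rep(0.25, 101))
  c2 <- new_curve_test(seq(0, 100, 1), rep(-0.55, 101))
  expect_equal(crp_area(c1, c2), 0.8 * 100, tolerance = 1e-12)
})

test_that("areas agree with a high-resolution Riemann oracle on piecewise-linear curves", {
  set.seed(99)
  for (i in 1:5) {
    grid <- seq(0, 100, 1)
    y1 <- stats::approx(seq(0, 100, length.out = 6), stats::rnorm(6), grid)$y
    y2 <- stats::approx(seq(0, 100, length.out = 6), stats::rnorm(6), grid)$y
    area <- crp_area(new_curve_test(grid, y1), new_curve_test(grid, y2))
    # the integrand is the piecewise-linear interpolant of |y2 - y1|
    # through the grid samples; integrate it at high resolution
    fine <- seq(0, 100, length.out = 100001)
    d <- stats::approx(grid, abs(y2 - y1), fine)$y
    riemann <- sum((d[-1] + d[-length(d)]) / 2) * diff(fine[1:2])
    expect_equal(area, riemann, tolerance = 1e-6)
  }
})

test_that("the area converges under grid refinement on smooth curves", {
  sim <- make_sine_datasets(sine_spec())
  a101 <- as.numeric(jsvcrp(sim$A, sim$B, G = 101L, axis = "seconds"))
  a1001 <- as.numeric(jsvcrp(sim$A, sim$B, G = 1001L, axis = "seconds"))
  expect_lt(abs(a101 - a1001) / a1001, 0.01)
})

test_that("output units track the dataset angle unit", {
  sims <- simulate_experiment(arm_spec(reps_per_target = 2L), seed = 3L)
  args <- reach_crp_args()
  a_deg <- do.call(jsvcrp, c(list(sims$physiological, sims$desync), args))
  a_rad <- do.call(jsvcrp, c(list(sims$physiological, sims$desync,
                                  unit = "rad"), args))
  expect_equal(attr(a_deg, "unit"), "deg")
  expect_equal(as.numeric(a_deg), as.numeric(a_rad) * 180 / pi,
               tolerance = 1e-9)
})

test_that("jsvcrp_all covers every joint pair once", {
  ds <- random_dataset(n_joints = 3L, n_reps = 2L, seed = 77)
  res <- jsvcrp_all(ds, ds)
  expect_length(res, 3L)
  expect_named(res, c("j1:j2", "j1:j3", "j2:j3"))
  expect_true(all(res == 0))
})
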