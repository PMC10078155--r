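test_that("derivatives vanish when all sources are off at the origin", {
  p <- kndy_params(k_D = 0, k_N = 0, I0 = 0)
  d <- kndy_derivatives(kndy_state(0, 0, 0), p, arc_input(0, 0))
  expect_equal(unname(d), c(0, 0, 0))
})

test_that("dv/dt is monotone in the input channels", {
  set.seed(42)
  p <- kndy_params()
  for (i in 1:25) {
    s <- kndy_state(runif(1, 0, 2), runif(1, 0, 3), runif(1, 0, 2))
    a <- runif(1, 0, 0.5); b <- runif(1, 0, 0.5); delta <- runif(1, 0, 0.3)
    d0 <- kndy_derivatives(s, p, arc_input(a, b))
    d_exc <- kndy_derivatives(s, p, arc_input(a + delta, b))
    d_inh <- kndy_derivatives(s, p, arc_input(a, b + delta))
    expect_gte(d_exc[["dv"]], d0[["dv"]])
    expect_lte(d_inh[["dv"]], d0[["dv"]])
  }
})

test_that("non-finite states and parameters are rejected by field name", {
  p <- kndy_params()
  expect_error(kndy_derivatives(c(D = 0, N = NaN, v = 0), p), "N")
  bad <- p; bad$tau_D <- Inf
  expect_error(kndy_derivatives(kndy_state(), bad), "tau_D")
  expect_error(kndy_state(-1, 0, 0), "D")
})

test_that("the silenced fixed point found by the root-finding oracle has zero derivatives", {
  p <- kndy_params()
  inp <- arc_input(0, 1)  # strong inhibition: below the lower threshold
  traj <- kndy_simulate(p, function(t) inp, t_span = c(0, 200), dt_out = 0.5)
  n <- nrow(traj)
  fp <- find_kndy_fixed_point(p, inp, c(traj$D[n], traj$N[n], traj$v[n]))
  expect_lt(fp$residual, 1e-8)
  d <- kndy_derivatives(fp$state, p, inp)
  expect_lt(max(abs(d)), 1e-8)
  # the trajectory itself converged to that point
  expect_lt(abs(traj$v[n] - fp$state[["v"]]), 1e-4)
})

test_that("simulation matches finite differences of the derivative field", {
  p <- kndy_params()
  traj <- get_default_traj()
  set.seed(7)
  idx <- sample(which(traj$time_min > 5 & traj$time_min < 295), 100)
  for (h in c(1e-3, 1e-4)) {
    # O(h) agreement at randomly sampled trajectory points
    errs <- vapply(idx[1:25], function(i) {
      y <- kndy_state(traj$D[i], traj$N[i], traj$v[i])
      d <- kndy_derivatives(y, p)
      fine <- kndy_simulate(p, t_span = c(traj$time_min[i],
                                          traj$time_min[i] + h),
                            dt_out = h, init = y)
      fd <- (unlist(fine[nrow(fine), c("D", "N", "v")]) -
               unlist(fine[1, c("D", "N", "v")])) / h
      max(abs(fd - d))
    }, numeric(1))
    expect_lt(max(errs), 50 * h)
  }
})

test_that("simulation is deterministic and converges under tolerance refinement", {
  p <- kndy_params()
  a <- kndy_simulate(p, t_span = c(0, 100), dt_out = 0.5)
  b <- kndy_simulate(p, t_span = c(0, 100), dt_out = 0.5)
  expect_identical(a, b)
  fine <- kndy_simulate(p, t_span = c(0, 100), dt_out = 0.5,
                        atol = 5e-9, rtol = 5e-7)
  expect_lt(max(abs(a$v - fine$v)) / max(abs(a$v)), 1e-4)
})

test_that("default parameters oscillate at zero external input with period 15-35 min", {
  traj <- get_default_traj()
  expect_equal(classify_regime(traj, c(240, 300)), "pulsatile")
  ev <- pulse_times_from_activity(traj, 0.5)
  ev <- ev[ev > 60]
  expect_gte(length(ev), 3)
  period <- mean(diff(ev))
  expect_gte(period, 15)
  expect_lte(period, 35)
})

test_that("measured period agrees with a longer, finer reference simulation", {
  p <- kndy_params()
  traj <- get_default_traj()
  ev <- pulse_times_from_activity(traj, 0.5)
  period <- mean(diff(ev[ev > 60]))
  ref <- kndy_simulate(p, t_span = c(0, 900), dt_out = 0.02,
                       atol = 1e-10, rtol = 1e-8)
  ev_ref <- pulse_times_from_activity(ref, 0.5)
  period_ref <- mean(diff(ev_ref[ev_ref > 60]))
  expect_lt(abs(period - period_ref) / period_ref, 0.02)
  # event counts agree over the shared span
  expect_equal(length(ev), sum(ev_ref <= 300))
})

test_that("halving the integration tolerance changes the period by < 0.5%", {
  p <- kndy_params()
  per <- vapply(c(1, 0.5), function(f) {
    tr <- kndy_simulate(p, t_span = c(0, 300), dt_out = 0.1,
                        atol = 1e-8 * f, rtol = 1e-6 * f)
    ev <- pulse_times_from_activity(tr, 0.5)
    mean(diff(ev[ev > 60]))
  }, numeric(1))
  expect_lt(abs(per[1] - per[2]) / per[2], 0.005)
})

test_that("strong sustained inhibition silences firing", {
  p <- kndy_params()
  traj <- kndy_simulate(p, function(t) arc_input(0, 2),
                        t_span = c(0, 200), dt_out = 0.5)
  expect_equal(classify_regime(traj, c(140, 200)), "silent")
  win <- traj[traj$time_min >= 100, ]
  expect_length(pulse_times_from_activity(win, 0.5), 0)
})

test_that("event extraction handles constant and synthetic periodic traces", {
  flat <- structure(data.frame(time_min = seq(0, 100, 0.5), D = 0, N = 0,
                               v = 1),
                    class = c("pg_trajectory", "data.frame"), v_max = 2)
  expect_length(pulse_times_from_activity(flat, 0.5), 0)
  tt <- seq(0, 100, by = 0.1)
  wave <- structure(data.frame(time_min = tt, D = 0, N = 0,
                               v = 1 + sin(2 * pi * (tt - 5) / 25)),
                    class = c("pg_trajectory", "data.frame"), v_max = 2)
  ev <- pulse_times_from_activity(wave, 0.5)
  expect_length(ev, 4)
  expect_equal(diff(ev), rep(25, 3), tolerance = 0.01)
  short <- structure(data.frame(time_min = 0, D = 0, N = 0, v = 0),
                     class = c("pg_trajectory", "data.frame"), v_max = 2)
  expect_error(pulse_times_from_activity(short, 0.5), "2 samples")
  expect_error(pulse_times_from_activity(wave, 1.2))
})

test_that("pulse trains must be finite and strictly increasing", {
  expect_error(pulse_train(c(2, 1)), "increasing")
  expect_error(pulse_train(c(0, NA)), "finite")
  expect_length(pulse_train(numeric(0)), 0)
})
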