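test_that("double logistic evaluates the printed formula", {
  # single logistic at its midpoint
  expect_equal(double_logistic(5, growth_params(1, 1, 5, k1 = 0)), 0.5)
  # large-time limit is the sum of the asymptotes
  gp <- growth_params(0.9, 0.7, 5, k1 = 0.3, k2 = 1.2)
  expect_equal(double_logistic(1e4, gp), 1.2, tolerance = 1e-12)
  # generic point against direct arithmetic
  gp2 <- growth_params(1, 2, 4, k1 = 0.5, k2 = 1.5)
  expect_equal(double_logistic(4, gp2),
               1 / 2 + 0.5 / (1 + exp(0.5 * 2 * (1.5 * 4 - 4))))
  expect_error(double_logistic(NaN, gp), "non-finite")
})

test_that("growth parameter constraints are enforced", {
  expect_error(growth_params(-1, 1, 1), "positivity")
  expect_error(growth_params(1, 0, 1), "positivity")
  expect_silent(growth_params(1, 1, 1, k1 = 0, k2 = 0.5))
})

test_that("dilution rate matches the analytic and finite-difference forms", {
  # single logistic at midpoint: mu = a1 (1 - N/L1) = a1/2
  gp <- growth_params(1.3, 0.8, 5, k1 = 0)
  expect_equal(dilution_rate(5, gp), 0.8 / 2, tolerance = 1e-12)
  # saturation
  expect_lt(dilution_rate(500, test_gp()), 1e-10)
  # central finite difference of log N, step 1e-5 h
  gp2 <- test_gp()
  for (t in c(1.7, 4.2, 6.9, 11.3)) {
    h <- 1e-5
    fd <- (log(double_logistic(t + h, gp2)) -
             log(double_logistic(t - h, gp2))) / (2 * h)
    expect_equal(dilution_rate(t, gp2), fd, tolerance = 1e-4)
  }
})

test_that("ribosome availability follows the interpolation formula", {
  expect_equal(ribosome_availability(0, 0.2), 0.2)
  expect_equal(ribosome_availability(1, 0.7), 1)
  expect_equal(ribosome_availability(0.5, 0.2), 0.6)
  expect_error(ribosome_availability(1.2, 0.5), "\\[0, 1\\]")
  expect_error(ribosome_availability(0.5, -0.1), "\\[0, 1\\]")
  # bounds over a sweep
  A <- seq(0, 1, 0.1)
  r <- ribosome_availability(A, 0.35)
  expect_true(all(r >= 0.35 - 1e-12 & r <= 1 + 1e-12))
})

test_that("simulation honours structural limits of the equations", {
  gp <- test_gp()
  # no transcription, zero start: everything stays zero
  tr0 <- simulate_biosensor(gp, test_kp(vmax_PROM = 0))
  expect_true(all(tr0$mrna == 0 & tr0$fder == 0 & tr0$gfp_per_od == 0))
  # frozen growth: mRNA reaches its closed-form steady state
  kp <- test_kp(K_Pk = 0.8, K_mRNAp = 1.4, K_mRNAdeg = 1.6)
  tr1 <- simulate_biosensor(gp, kp, times = seq(0, 200, 0.5),
                            growth = "frozen")
  ss <- kp$vmax_PROM * kp$K_Pk * kp$K_mRNAp / (kp$k_deg * kp$K_mRNAdeg)
  expect_equal(tail(tr1$mrna, 1), ss, tolerance = 1e-6)
  # invalid grids and states are refused
  expect_error(simulate_biosensor(gp, kp, times = c(0, 0, 1)), "increasing")
  expect_error(simulate_biosensor(gp, kp, init = c(-1, 0, 0)), "non-negative")
})

test_that("adaptive solution matches a fine fixed-step reference", {
  gp <- test_gp()
  times <- default_grid()
  set.seed(31)
  for (case in 1:5) {
    kp <- test_kp(RBS_strength = exp(runif(1, -1, 1)),
                  vmax_NAR = exp(runif(1, 0, 1.4)),
                  K_P = exp(runif(1, -0.7, 0.7)),
                  k_deg_GFP = exp(runif(1, -3, -1.6)))
    tr <- simulate_biosensor(gp, kp, times = times)
    ref <- rk4_reference(gp, kp, times, refine = 100)
    scale <- pmax(abs(ref), max(abs(ref)) * 1e-3)
    expect_lt(max(abs(cbind(tr$mrna, tr$fder, tr$gfp_per_od) - ref) / scale),
              1e-5)
  }
})

test_that("states remain non-negative and induction-free decay is exact", {
  gp <- test_gp()
  set.seed(77)
  for (i in 1:10) {
    kp <- test_kp(RBS_strength = exp(runif(1, -2, 2)),
                  k_deg_FDER = exp(runif(1, -3, 0)),
                  K_lysis = exp(runif(1, -0.7, 0.7)))
    tr <- simulate_biosensor(gp, kp)
    expect_true(all(tr$mrna >= 0 & tr$fder >= 0 & tr$gfp_per_od >= 0))
  }
  # vmax_NAR = 0: GFP/OD is pure decay of its initial condition,
  # G(t) = G0 exp(-k_deg_GFP K_lysis t) N(0)/N(t)
  kp0 <- test_kp(vmax_NAR = 0, k_deg_GFP = 0.12, K_lysis = 1.3)
  tr <- simulate_biosensor(gp, kp0, init = c(0, 0, 2))
  expected <- 2 * exp(-0.12 * 1.3 * tr$time_h) *
    double_logistic(0, gp) / double_logistic(tr$time_h, gp)
  expect_equal(tr$gfp_per_od, expected, tolerance = 1e-6)
})

test_that("gain is the horizon maximum, relative gain is percent of best", {
  tr <- data.frame(time_h = 0:10, gfp_per_od = c(0:7, 7.3, 7.3, 7.3))
  expect_equal(steady_state_gain(tr), 7.3)
  expect_equal(relative_gain(c(10, 8, 5)), c(100, 80, 50))
  expect_error(steady_state_gain(list(gfp_per_od = numeric(0))), "empty")
  # peak-then-decay keeps the peak, not the endpoint
  gp <- test_gp()
  kp <- test_kp(k_deg_GFP = 1.5, K_lysis = 2)   # strong proteolysis
  tr2 <- simulate_biosensor(gp, kp)
  expect_equal(steady_state_gain(tr2), max(tr2$gfp_per_od))
  expect_gt(steady_state_gain(tr2), tail(tr2$gfp_per_od, 1))
})

test_that("half-time interpolates the 50% crossing in seconds", {
  ramp <- data.frame(time_h = seq(0, 10, 1), gfp_per_od = seq(0, 1, 0.1))
  expect_equal(half_time(ramp), 5 * 3600)
  # already above half at the first sample: boundary convention
  step <- data.frame(time_h = c(2, 3, 4), gfp_per_od = c(0.9, 1, 1))
  expect_equal(half_time(step), 2 * 3600)
  expect_error(half_time(data.frame(time_h = 0:2, gfp_per_od = c(0, 0, 0))),
               "no response")
  # dense 1-s resampling oracle on a simulated trajectory
  tr <- simulate_biosensor(test_gp(), test_kp())
  fine <- stats::approx(tr$time_h, tr$gfp_per_od,
                        xout = seq(0, 16, by = 1 / 3600))
  t_dense <- fine$x[which(fine$y >= max(tr$gfp_per_od) / 2)[1]] * 3600
  expect_lt(abs(half_time(tr) - t_dense), 10)
})
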