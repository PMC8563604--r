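test_that("hydraulic diameter reproduces closed forms", {
  d <- 0.8
  expect_equal(hydraulic_diameter(pi * d^2 / 4, pi * d), d)
  s <- 1.3
  expect_equal(hydraulic_diameter(s^2, 4 * s), s)
  a <- 0.5 # regular hexagon of side a: 4 * (3 sqrt(3)/2 a^2) / (6 a)
  expect_equal(hydraulic_diameter(3 * sqrt(3) / 2 * a^2, 6 * a),
               sqrt(3) * a)
  expect_error(hydraulic_diameter(0, 1), "positive")
})

test_that("Reynolds number is rho u d / mu and linear in velocity", {
  fl <- fluid_properties(1000, 1e-3)
  expect_equal(reynolds(fl, 0.01, 0.001), 10)
  expect_equal(reynolds(fl, 0.02, 0.001), 2 * reynolds(fl, 0.01, 0.001))
  expect_equal(reynolds(fluid_properties(998, 1.2e-3), 0.005, 5e-4),
               2.0792, tolerance = 1e-4)
  expect_error(reynolds(fl, -1, 0.001), "positive")
})

test_that("insert library is self-consistent", {
  lib <- insert_library()
  expect_named(lib, c("HC1", "HC2", "HC3", "CL1", "CL2", "CL3"))
  for (g in lib) {
    expect_equal(hydraulic_diameter(g$cross_section_area,
                                    g$wetted_perimeter),
                 g$hydraulic_diameter)
    expect_equal(g$cross_section_area * g$length, g$internal_volume,
                 tolerance = 1e-9)
  }
  expect_equal(lib$HC3$internal_volume, 234.65)
  expect_equal(lib$CL3$internal_volume, 467.12)
  # declared area-to-volume ratios are honoured within 1%
  expect_silent(insert_geometry("x", "HC", 0.263, 234.65, 3572.21, 39.8,
                                area_to_volume = 15.2))
  expect_error(insert_geometry("x", "HC", 0.263, 234.65, 3572.21, 39.8,
                               area_to_volume = 20), "1%")
})

test_that("normalize_step rescales, flips step-downs and flags flat signals", {
  n <- 200
  step_up <- c(rep(100, n / 2), rep(900, n / 2))
  f <- normalize_step(step_up)
  expect_true(all(f[1:(n / 2)] == 0))
  expect_true(all(f[(n / 2 + 1):n] == 1))
  # a step-down trace gives the same F-curve as its mirrored step-up
  expect_equal(normalize_step(rev(step_up) * -1 + 1000), f)
  expect_error(normalize_step(rep(5, 100) + rnorm(100)),
               "indistinguishable")
})

test_that("f_to_e differentiates and always integrates to one", {
  time <- seq(0, 4, length.out = 401)
  f <- pmin(pmax(time / 2, 0), 1) # linear ramp over [0, 2]
  e <- f_to_e(f, time, smooth_window = 1)
  expect_equal(e[time > 0.1 & time < 1.9], rep(0.5, sum(time > 0.1 &
                                                          time < 1.9)),
               tolerance = 1e-9)
  expect_equal(pracma::trapz(time, e), 1, tolerance = 1e-3)

  # property: unit area for arbitrary noisy-but-valid F-curves
  set.seed(7)
  for (i in 1:5) {
    fr <- sort(runif(300))
    tr <- seq(0, 10, length.out = 300)
    er <- f_to_e(fr, tr)
    expect_equal(pracma::trapz(tr, er), 1, tolerance = 1e-3)
    expect_true(all(er >= 0))
  }

  expect_error(f_to_e(c(0, 1), c(0, 1)), "5 samples")
})

test_that("recovered E-curve matches the analytic open-open density", {
  dev <- analytic_device(bo = 20, tau = 30, n = 2000)
  e_rec <- f_to_e(dev$f, dev$time, smooth_window = 5)
  expect_lt(max(abs(e_rec - dev$e)) / max(dev$e), 0.02)
})

test_that("E-curve moments match closed forms", {
  time <- seq(0, 2, length.out = 2001)
  m <- rtd_moments(rep(0.5, 2001), time) # uniform on [0, 2]
  expect_equal(unname(m["t_mean"]), 1, tolerance = 1e-6)
  expect_equal(unname(m["variance"]), 1 / 3, tolerance = 1e-4)

  # narrow spike at t0 behaves like a delta
  t0 <- 5
  tt <- seq(0, 10, length.out = 4001)
  spike <- dnorm(tt, t0, 0.01)
  m2 <- rtd_moments(spike / pracma::trapz(tt, spike), tt)
  expect_equal(unname(m2["t_mean"]), t0, tolerance = 1e-4)
  expect_lt(unname(m2["variance"]), 1e-3)

  # exponential CSTR density: variance / tau^2 = 1
  tau <- 3
  te <- seq(0, 12 * tau, length.out = 1e4)
  ee <- exp(-te / tau) / tau
  me <- rtd_moments(ee / pracma::trapz(te, ee), te)
  expect_equal(unname(me["variance"]) / tau^2, 1, tolerance = 0.02)
})

test_that("step_moments agrees with E-curve moments on smooth data", {
  dev <- analytic_device(bo = 10, tau = 20, n = 4000)
  m_e <- rtd_moments(dev$e / pracma::trapz(dev$time, dev$e), dev$time)
  m_f <- step_moments(dev$f / max(dev$f), dev$time)
  expect_equal(unname(m_f["t_mean"]), unname(m_e["t_mean"]),
               tolerance = 0.01)
  expect_equal(unname(m_f["variance"]), unname(m_e["variance"]),
               tolerance = 0.02)
})

test_that("moment correction subtracts inlet contributions", {
  expect_equal(correct_moments(c(t_mean = 10, variance = 4),
                               c(t_mean = 0, variance = 0)),
               c(t_mean = 10, variance = 4))
  expect_equal(correct_moments(c(t_mean = 10, variance = 4),
                               c(t_mean = 3, variance = 1)),
               c(t_mean = 7, variance = 3))
  expect_error(correct_moments(c(t_mean = 2, variance = 1),
                               c(t_mean = 3, variance = 1)),
               "inconsistent")
})

test_that("moments are additive under convolution of two devices", {
  # device 1 feeds device 2; the composite E is their convolution
  n <- 4000
  time <- seq(0, 300, length.out = n)
  dt <- time[2] - time[1]
  e1 <- open_open_E(time / 10, 30) / 10
  e2 <- open_open_E(time / 40, 8) / 40
  e12 <- flowdoe:::convolve_densities(e1, e2, dt)
  m1 <- rtd_moments(e1 / pracma::trapz(time, e1), time)
  m12 <- rtd_moments(e12, time)
  m2_own <- rtd_moments(e2 / pracma::trapz(time, e2), time)
  corrected <- correct_moments(m12, m1)
  expect_equal(unname(corrected["t_mean"]), unname(m2_own["t_mean"]),
               tolerance = 0.02)
  expect_equal(unname(corrected["variance"]), unname(m2_own["variance"]),
               tolerance = 0.02)
})

test_that("open-open variance relation inverts in closed form", {
  expect_equal(bodenstein_from_variance(3), 2)
  expect_equal(bodenstein_from_variance(0.0208), 100)
  for (bo in c(0.5, 1, 10, 500)) {
    expect_equal(bodenstein_from_variance(sigma_theta2_from_bodenstein(bo)),
                 bo, tolerance = 1e-12)
  }
  expect_error(bodenstein_from_variance(-1), "positive")
})

test_that("measured-moment inversion accounts for the open-vessel mean bias", {
  for (bo in c(2, 5, 20, 80, 300)) {
    tau <- 25
    t_meas <- tau * (1 + 2 / bo)
    v_meas <- tau^2 * sigma_theta2_from_bodenstein(bo)
    expect_equal(bodenstein_from_measured(t_meas, v_meas), bo,
                 tolerance = 1e-10)
  }
  expect_equal(bodenstein_from_measured(10, 0), Inf)
})

test_that("analyze_rtd recovers the Bodenstein number from synthetic steps", {
  fl <- water_like()
  geom <- hc3()
  log0 <- simulate_tracer_step(bo = 20, t_mean = 30, noise_rel = 0)
  fit0 <- analyze_rtd(log0, geom, fl, flowrate = 0.5)
  expect_equal(fit0$bodenstein, 20, tolerance = 0.02)
  expect_equal(fit0$space_time, 30, tolerance = 0.02)

  # internal consistency of the reported coefficients
  u <- fit0$velocity
  expect_equal(fit0$d_ax, u * geom$length / 1000 / fit0$bodenstein,
               tolerance = 1e-9)
  expect_equal(bodenstein_from_variance(fit0$sigma_theta2),
               fit0$bodenstein, tolerance = 1e-6)

  # with noise, the ordering of backmixing levels is preserved
  fit_lo <- analyze_rtd(simulate_tracer_step(5, 30, seed = 2), geom, fl,
                        0.5)
  fit_hi <- analyze_rtd(simulate_tracer_step(80, 30, seed = 2), geom, fl,
                        0.5)
  expect_lt(fit_lo$bodenstein, fit_hi$bodenstein)
})

test_that("identical inlet and outlet flags dispersion above range", {
  log <- simulate_tracer_step(bo = 20, t_mean = 30, noise_rel = 0)
  log$signal_outlet <- log$signal_inlet
  fit <- analyze_rtd(log, hc3(), water_like(), flowrate = 0.5)
  expect_true(fit$above_range)
  expect_identical(fit$bodenstein, Inf)
})

test_that("rtd_fit methods print and summarise", {
  fit <- analyze_rtd(simulate_tracer_step(20, 30, seed = 1), hc3(),
                     water_like(), 0.5)
  expect_output(print(fit), "Bo")
  expect_output(print(summary(fit)), "bodenstein")
  expect_named(coef(fit), c("t_mean", "variance", "space_time",
                            "sigma_theta2", "bodenstein", "d_ax",
                            "velocity", "reynolds"))
})
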