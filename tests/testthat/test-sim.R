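test_that("open-open density normalizes with the expected variance", {
  th <- seq(1e-6, 40, length.out = 2e5)
  e <- open_open_E(th, 20)
  expect_equal(pracma::trapz(th, e), 1, tolerance = 1e-3)
  m1 <- pracma::trapz(th, th * e)
  v <- pracma::trapz(th, (th - m1)^2 * e)
  expect_equal(v, 2 / 20 + 8 / 400, tolerance = 0.02)

  # near plug flow the mass concentrates at theta = 1
  th2 <- seq(1e-6, 3, length.out = 2e5)
  e2 <- open_open_E(th2, 1000)
  inside <- th2 >= 0.9 & th2 <= 1.1
  expect_gte(pracma::trapz(th2[inside], e2[inside]), 0.85)

  expect_error(open_open_E(1, -2), "positive")
})

test_that("tracer steps are seeded, mass-conserving and invertible", {
  a <- simulate_tracer_step(20, 30, seed = 9)
  b <- simulate_tracer_step(20, 30, seed = 9)
  expect_identical(a, b)
  c2 <- simulate_tracer_step(20, 30, seed = 10)
  expect_false(identical(a, c2))

  # inlet and outlet settle on the same plateau (the step conserves mass)
  clean <- simulate_tracer_step(20, 30, noise_rel = 0)
  n <- nrow(clean)
  tail_idx <- seq.int(n - 50, n)
  expect_equal(mean(clean$signal_inlet[tail_idx]),
               mean(clean$signal_outlet[tail_idx]), tolerance = 1e-4)

  # self-consistency: the analyzer recovers the generating Bo
  fit <- analyze_rtd(clean, hc3(), water_like(), 0.5)
  expect_equal(fit$bodenstein, 20, tolerance = 0.02)
})

test_that("temperature profile peaks at the optimum and is symmetric", {
  kin <- kinetic_params(vmax_ref = 0.2, t_opt = 30, t_width = 6)
  expect_equal(vmax_at_temperature(30, kin), 0.2)
  expect_equal(vmax_at_temperature(33, kin), vmax_at_temperature(27, kin))
  expect_equal(vmax_at_temperature(25, kin), 0.7066 * 0.2,
               tolerance = 1e-4)
})

test_that("tank count matches the dispersion model variance", {
  expect_equal(n_tanks_from_bodenstein(20), 8L) # 1 / 0.12 = 8.33
  expect_equal(n_tanks_from_bodenstein(2), 1L)
  expect_equal(n_tanks_from_bodenstein(200), 98L) # 1 / 0.0102
})

test_that("cascade outlet hits the kinetic limits", {
  # Vmax = 0 passes the feed through unchanged
  kin0 <- kinetic_params(vmax_ref = 1e-30, km = 0.5, n_tanks = 3)
  out0 <- cstr_cascade_outlet(1.5, 60, kin0)
  expect_equal(out0$substrate, 1.5, tolerance = 1e-9)

  # first-order limit (Km >> c0), single tank: X = k tau / (1 + k tau)
  kin1 <- kinetic_params(vmax_ref = 0.01, km = 1000, n_tanks = 1,
                         t_width = 6)
  k <- 0.01 / 1000
  tau <- 500
  out1 <- cstr_cascade_outlet(0.001, tau, kin1)
  x1 <- out1$product / 0.001
  expect_equal(x1, k * tau / (1 + k * tau), tolerance = 1e-6)

  # many tanks approach the plug-flow limit 1 - exp(-k tau)
  kin200 <- kinetic_params(vmax_ref = 0.01, km = 1000, n_tanks = 200)
  out200 <- cstr_cascade_outlet(0.001, tau, kin200)
  expect_equal(out200$product / 0.001, 1 - exp(-k * tau),
               tolerance = 0.005)
})

test_that("cascade conserves mass and responds monotonically", {
  kin <- kinetic_params(vmax_ref = 0.05, km = 0.5, n_tanks = 8)
  taus <- seq(5, 120, length.out = 30)
  out <- cstr_cascade_outlet(1.2, taus, kin)
  expect_equal(out$substrate + out$product, rep(1.2, 30),
               tolerance = 1e-12)
  expect_true(all(diff(out$substrate) <= 1e-12)) # longer tau, less substrate

  vms <- seq(0.01, 0.2, length.out = 20)
  subs <- vapply(vms, function(v) {
    cstr_cascade_outlet(1.2, 30, kinetic_params(vmax_ref = v, km = 0.5,
                                                n_tanks = 8))$substrate
  }, numeric(1))
  expect_true(all(diff(subs) <= 1e-12))
})

test_that("simulated experiments are seeded per run and noise-free deterministic", {
  reactor <- virtual_reactor(kinetics = kinetic_params(noise_rel = 0))
  pt <- data.frame(flowrate = 1.1, temperature = 30, dilution = 9.4,
                   run_index = 1L, iteration = 1L, role = "center")
  r1 <- simulate_experiment(pt, reactor)
  r2 <- simulate_experiment(pt, reactor)
  expect_identical(r1, r2)
  expect_equal(r1$c_substrate + r1$c_product, r1$c0, tolerance = 1e-12)
  expect_lte(r1$yield, r1$conversion + 1e-9)

  noisy <- virtual_reactor(kinetics = kinetic_params(noise_rel = 0.01))
  a <- simulate_experiment(pt, noisy)
  pt2 <- pt
  pt2$run_index <- 2L
  b <- simulate_experiment(pt2, noisy)
  expect_false(isTRUE(all.equal(a$c_product, b$c_product)))

  # conversion falls as the flowrate rises (shorter residence time)
  frs <- seq(0.3, 1.9, length.out = 12)
  convs <- vapply(frs, function(fr) {
    p <- pt
    p$flowrate <- fr
    simulate_experiment(p, reactor)$conversion
  }, numeric(1))
  expect_true(all(diff(convs) < 0))
})

test_that("simulated spectra frames quantify back to the outlet state", {
  cal <- spectra_calibration(2, 1.5)
  reactor <- virtual_reactor(kinetics = kinetic_params(noise_rel = 0))
  pt <- data.frame(flowrate = 0.8, temperature = 30, dilution = 9.4,
                   run_index = 3L, iteration = 1L, role = "axial")
  res <- simulate_experiment(pt, reactor, spectra = TRUE,
                             calibration = cal)
  fr <- attr(res, "spectra")
  expect_s3_class(fr, "spectra_frame")
  expect_equal(absorbance_to_concentration(fr, cal, "product"),
               res$c_product, tolerance = 1e-9)
  expect_equal(absorbance_to_concentration(fr, cal, "substrate"),
               res$c_substrate, tolerance = 1e-9)
})

test_that("brute-force optimum dominates the design points", {
  reactor <- virtual_reactor(kinetics = kinetic_params(noise_rel = 0))
  camp <- run_campaign(simulator_provider(reactor), campaign_config())
  opt <- true_optimum(reactor, design_space(), grid_n = 15)
  expect_gte(opt$best$sty, max(camp$results$sty) - 1e-9)

  # refining the grid never lowers the oracle optimum (nested grids)
  coarse <- true_optimum(reactor, design_space(), grid_n = 5)$best$sty
  fine <- true_optimum(reactor, design_space(), grid_n = 9)$best$sty
  expect_gte(fine, coarse - 1e-12)

  # the separable temperature factor peaks at the grid value nearest
  # the kinetic optimum
  expect_equal(opt$best$temperature, 30, tolerance = 1e-9)
})

test_that("sampled kinetics stay in their documented ranges", {
  space <- design_space()
  for (s in 1:10) {
    kin <- sample_kinetics(s, space)
    expect_gte(kin$t_opt, 26.5)
    expect_lte(kin$t_opt, 33.5)
    expect_gte(kin$km, 0.2)
    expect_lte(kin$km, 2)
    expect_true(kin$n_tanks %in% 4:20)
  }
  expect_identical(unclass(sample_kinetics(4, space)),
                   unclass(sample_kinetics(4, space)))
})
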