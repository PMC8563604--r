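#' Open-open axial dispersion exit-age density
#'
#' `E(theta) = 1 / (2 sqrt(pi theta / Bo)) * exp(-(1 - theta)^2 Bo / (4 theta))`
#' in dimensionless time `theta = t / tau`. The density integrates to 1,
#' has mean `1 + 2/Bo` and variance `2/Bo + 8/Bo^2`.
#'
#' @param theta Dimensionless time (>= 0; the density is 0 at `theta = 0`).
#' @param bo Bodenstein number (> 0).
#' @return Dimensionless density values.
#' @export
open_open_E <- function(theta, bo) {
  check_positive(bo = bo)
  if (any(!is.finite(theta)) || any(theta < 0)) {
    stop_domain("'theta' must be finite and non-negative")
  }
  out <- numeric(length(theta))
  pos <- theta > 0
  th <- theta[pos]
  out[pos] <- 1 / (2 * sqrt(pi * th / bo)) *
    exp(-(1 - th)^2 * bo / (4 * th))
  out
}

# Dimensional exit-age density of a device with space time tau, 1/s.
device_E <- function(time, tau, bo) {
  open_open_E(time / tau, bo) / tau
}

#' Simulate a dual-point step-tracer experiment
#'
#' Generates the raw inlet and outlet detector traces of a step-input
#' tracer experiment on a virtual column with known Bodenstein number.
#' The inlet flow cell sees a nearly ideal step that has passed only the
#' feed capillary (a short, weakly dispersed device); the outlet sees
#' that inlet signal convolved with the column's open-open exit-age
#' density at (`bo`, `t_mean`). Both traces are reported as raw detector
#' values `baseline + span * F(t)` with seeded multiplicative Gaussian
#' noise, ready for [read_tracer_log()]-style processing and
#' [analyze_rtd()].
#'
#' @param bo Column Bodenstein number (ground truth).
#' @param t_mean Column space time, s.
#' @param n Number of samples (default 2000).
#' @param t_end Record length, s; default long enough for the outlet
#'   plateau (inlet delay + column mean + 6 standard deviations).
#' @param delay Valve-switch time, s: the pre-step hold during which both
#'   cells read the baseline. Default 15% of the post-step record, so the
#'   baseline window of [normalize_step()] lies fully before the step.
#' @param noise_rel Relative (multiplicative) detector noise (default
#'   0.005).
#' @param seed Integer seed.
#' @param inlet_t_mean,inlet_bo Space time (s) and Bodenstein number of
#'   the feed capillary seen by the inlet cell (defaults 2 s, 150).
#' @param baseline,span Raw detector baseline and step height (defaults
#'   40 and 980, emulating a 10-bit ADC range).
#' @return A `tracer_log` data frame (`time`, `signal_inlet`,
#'   `signal_outlet`) with the ground truth stored in attributes `bo` and
#'   `t_mean`.
#' @examples
#' log <- simulate_tracer_step(bo = 20, t_mean = 30, seed = 1)
#' @export
simulate_tracer_step <- function(bo, t_mean, n = 2000, t_end = NULL,
                                 noise_rel = 0.005, seed = 1L,
                                 inlet_t_mean = 2, inlet_bo = 150,
                                 baseline = 40, span = 980,
                                 delay = NULL) {
  check_positive(bo = bo, t_mean = t_mean, inlet_t_mean = inlet_t_mean,
                 inlet_bo = inlet_bo, span = span)
  check_positive(noise_rel = noise_rel, .allow_zero = TRUE)
  if (is.null(t_end)) {
    sd_col <- t_mean * sqrt(sigma_theta2_from_bodenstein(bo))
    t_end <- inlet_t_mean * (1 + 2 / inlet_bo) +
      t_mean * (1 + 2 / bo) + 6 * sd_col + 5 * inlet_t_mean
  }
  if (is.null(delay)) delay <- 0.15 * t_end
  time <- seq(0, t_end + delay, length.out = n)
  dt <- time[2] - time[1]
  t_post <- pmax(time - delay, 0)
  e_in <- device_E(t_post, inlet_t_mean, inlet_bo)
  e_col <- device_E(time, t_mean, bo)
  e_out <- convolve_densities(e_in, e_col, dt)
  f_in <- cum_trapz(time, e_in)
  f_out <- cum_trapz(time, e_out)
  # both F's are forced to a common plateau of 1: the step conserves mass
  f_in <- pmin(f_in / max(f_in), 1)
  f_out <- pmin(f_out / max(f_out), 1)
  s_in <- baseline + span * f_in
  s_out <- baseline + span * f_out
  if (noise_rel > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(2 * n, 0, noise_rel),
                                    ncol = 2))
    s_in <- s_in * (1 + noise[, 1])
    s_out <- s_out * (1 + noise[, 2])
  }
  out <- data.frame(time = time, signal_inlet = s_in, signal_outlet = s_out)
  class(out) <- c("tracer_log", "data.frame")
  attr(out, "bo") <- bo
  attr(out, "t_mean") <- t_mean
  out
}

# Numerical convolution of two exit-age densities sampled on a common
# uniform grid; returns the first n samples, renormalized to unit area.
convolve_densities <- function(e1, e2, dt) {
  n <- length(e1)
  full <- stats::convolve(e1, rev(e2), type = "open") * dt
  out <- pmax(full[seq_len(n)], 0)
  area <- sum(out) * dt
  if (area > 0) out <- out / area
  out
}

#' Ground-truth kinetics of the virtual reactor
#'
#' Parameter set of the virtual immobilized-enzyme reactor used as the
#' synthetic-data generator: Michaelis-Menten kinetics whose maximal rate
#' follows a Gaussian temperature-activity profile peaking at `t_opt`,
#' evaluated on a tanks-in-series cascade. The defaults emulate the study
#' system: an interior temperature optimum near 30 C, saturation kinetics
#' (`km` well below the undiluted feed), strong backmixing (`n_tanks`
#' matching a Bodenstein number around 20) and 1% relative measurement
#' noise.
#'
#' @param vmax_ref Maximal volumetric rate at the optimum temperature,
#'   mM/s (default 0.1).
#' @param t_opt Optimum temperature, C (default 30).
#' @param t_width Gaussian width of the activity-temperature profile, C
#'   (default 6).
#' @param km Michaelis constant, mM (default 0.5).
#' @param n_tanks Number of tanks in the cascade (integer >= 1; default
#'   [n_tanks_from_bodenstein()] of 20).
#' @param noise_rel Relative measurement noise on concentrations
#'   (default 0.01).
#' @param flow_decay Flowrate scale (mL/min) of the flow-maldistribution
#'   effectiveness factor (default 1.7); see [flow_efficiency()]. Use
#'   `Inf` for an ideally distributed bed.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(vmax_ref = 0.1, t_opt = 30, t_width = 6,
                           km = 0.5, n_tanks = n_tanks_from_bodenstein(20),
                           noise_rel = 0.01, flow_decay = 1.7, seed = 1L) {
  check_positive(vmax_ref = vmax_ref, t_width = t_width, km = km,
                 flow_decay = flow_decay)
  check_positive(noise_rel = noise_rel, .allow_zero = TRUE)
  if (!is.finite(n_tanks) || n_tanks < 1 || n_tanks != round(n_tanks)) {
    stop_domain("'n_tanks' must be an integer >= 1")
  }
  structure(list(vmax_ref = vmax_ref, t_opt = t_opt, t_width = t_width,
                 km = km, n_tanks = as.integer(n_tanks),
                 noise_rel = noise_rel, flow_decay = flow_decay,
                 seed = as.integer(seed)),
            class = "kinetic_params")
}

#' Flow-maldistribution effectiveness factor
#'
#' Structured beds lose effective catalytic contact as the flowrate
#' rises: maldistribution and channeling let a growing share of the feed
#' bypass the enzyme-coated walls. The virtual reactor models this with a
#' Gaussian effectiveness factor on the maximal rate,
#' `eta(FR) = exp(-(FR / flow_decay)^2 / 2)`, which bends the space-time
#' yield over into an interior flowrate optimum (a medium flowrate beats
#' both extremes) instead of the monotone flowrate dependence an ideally
#' distributed Michaelis-Menten bed would show.
#'
#' @param flowrate Flowrate, mL/min.
#' @param kinetics A [kinetic_params()].
#' @return Effectiveness in (0, 1].
#' @export
flow_efficiency <- function(flowrate, kinetics) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  if (!is.finite(kinetics$flow_decay)) return(rep(1, length(flowrate)))
  exp(-(flowrate / kinetics$flow_decay)^2 / 2)
}

#' Tank count equivalent to a Bodenstein number
#'
#' Matches the tanks-in-series and dispersion models through their
#' dimensionless variances: `1/n ~ sigma_theta^2(Bo)`, rounded to the
#' nearest integer (ties upward), at least 1.
#'
#' @param bo Bodenstein number.
#' @return Integer tank count.
#' @export
n_tanks_from_bodenstein <- function(bo) {
  check_positive(bo = bo)
  max(1L, as.integer(floor(1 / sigma_theta2_from_bodenstein(bo) + 0.5)))
}

#' Temperature-dependent maximal rate
#'
#' Gaussian activity-temperature profile of the virtual enzyme:
#' `Vmax(T) = vmax_ref * exp(-(T - t_opt)^2 / (2 t_width^2))`.
#'
#' @param temperature Temperature, C.
#' @param kinetics A [kinetic_params()] object.
#' @return Maximal rate in mM/s.
#' @export
vmax_at_temperature <- function(temperature, kinetics) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  kinetics$vmax_ref *
    exp(-(temperature - kinetics$t_opt)^2 / (2 * kinetics$t_width^2))
}

#' Outlet of a tanks-in-series cascade with Michaelis-Menten kinetics
#'
#' Solves the steady state of `n_tanks` equal CSTRs in series, each with
#' residence time `tau / n_tanks` and rate `Vmax c / (Km + c)`. Each tank
#' has the closed-form outlet concentration (positive root of a
#' quadratic), applied sequentially. Vectorized over `c0`, `tau` and
#' `temperature`.
#'
#' @param c0 Feed substrate concentration, mM.
#' @param tau Total residence time, s.
#' @param kinetics A [kinetic_params()].
#' @param temperature Temperature (C) at which to evaluate `Vmax`;
#'   default the kinetics' optimum.
#' @param flowrate Optional flowrate (mL/min) used to apply the
#'   [flow_efficiency()] maldistribution factor; `NULL` (default) means
#'   ideal distribution (`eta = 1`), the pure-kinetics limit.
#' @return List with `substrate` and `product` outlet concentrations
#'   (mM); mass balance `substrate + product = c0` holds exactly.
#' @export
cstr_cascade_outlet <- function(c0, tau, kinetics,
                                temperature = kinetics$t_opt,
                                flowrate = NULL) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  check_positive(c0 = c0, tau = tau)
  vmax <- vmax_at_temperature(temperature, kinetics)
  if (!is.null(flowrate)) {
    vmax <- vmax * flow_efficiency(flowrate, kinetics)
  }
  km <- kinetics$km
  n <- kinetics$n_tanks
  tau_tank <- tau / n
  c_cur <- rep_len(c0, max(length(c0), length(tau), length(vmax)))
  tau_tank <- rep_len(tau_tank, length(c_cur))
  vmax <- rep_len(vmax, length(c_cur))
  for (i in seq_len(n)) {
    b <- km + tau_tank * vmax - c_cur
    c_cur <- (-b + sqrt(b^2 + 4 * km * c_cur)) / 2
  }
  c0_full <- rep_len(c0, length(c_cur))
  list(substrate = c_cur, product = c0_full - c_cur)
}

#' Virtual structured-bed reactor
#'
#' Couples an insert geometry with ground-truth kinetics and a substrate
#' stock concentration: the simulator's stand-in for one coated insert on
#' the automated rig.
#'
#' @param geometry An [insert_geometry()].
#' @param kinetics A [kinetic_params()].
#' @param stock Substrate stock concentration, mM (default 10).
#' @return An object of class `virtual_reactor`.
#' @export
virtual_reactor <- function(geometry = insert_library()$HC3,
                            kinetics = kinetic_params(), stock = 10) {
  stopifnot(inherits(geometry, "insert_geometry"),
            inherits(kinetics, "kinetic_params"))
  check_positive(stock = stock)
  structure(list(geometry = geometry, kinetics = kinetics, stock = stock),
            class = "virtual_reactor")
}

#' Simulate one steady-state experiment on the virtual reactor
#'
#' Runs a single design point through the virtual reactor: the dilution
#' ratio sets the feed concentration, the flowrate sets the residence
#' time, the temperature sets `Vmax`, and the cascade gives the
#' steady-state outlet. Measured concentrations carry multiplicative
#' Gaussian noise seeded per run index, so distinct runs get independent
#' draws while the whole campaign stays reproducible.
#'
#' @param point One-row data frame with `flowrate`, `temperature`,
#'   `dilution` and (for seeding and bookkeeping) `run_index`,
#'   `iteration`, `role` (see [generate_ccd()]).
#' @param reactor A [virtual_reactor()].
#' @param noise_rel Override for the kinetics' relative measurement
#'   noise; `0` gives a deterministic result.
#' @param spectra If `TRUE`, also attach a small synthetic UV-Vis
#'   [spectra_frame()] of the outlet (attribute `"spectra"`).
#' @param calibration Calibration used when `spectra = TRUE`.
#' @return A one-row experiment-result data frame: the point, `c0`,
#'   measured outlet concentrations, conversion, yield, residence time
#'   and space-time yield.
#' @export
simulate_experiment <- function(point, reactor,
                                noise_rel = reactor$kinetics$noise_rel,
                                spectra = FALSE,
                                calibration = spectra_calibration(2, 1.5)) {
  stopifnot(inherits(reactor, "virtual_reactor"))
  point <- as.data.frame(point)[1, , drop = FALSE]
  if (is.null(point$run_index)) point$run_index <- 1L
  if (is.null(point$iteration)) point$iteration <- 1L
  if (is.null(point$role)) point$role <- "manual"
  c0 <- dilution_to_concentration(reactor$stock, point$dilution)
  tau <- residence_time(reactor$geometry$internal_volume, point$flowrate)
  out <- cstr_cascade_outlet(c0, tau, reactor$kinetics,
                             temperature = point$temperature,
                             flowrate = point$flowrate)
  c_sub <- out$substrate
  c_prod <- out$product
  if (noise_rel > 0) {
    eps <- with_seed(run_seed(reactor$kinetics$seed, point$run_index),
                     stats::rnorm(2, 0, noise_rel))
    c_sub <- max(0, c_sub * (1 + eps[1]))
    c_prod <- max(0, c_prod * (1 + eps[2]))
  }
  res <- experiment_result(point, c0, c_sub, c_prod, reactor$geometry)
  if (spectra) {
    attr(res, "spectra") <- synthetic_spectra_frame(
      c_prod, c_sub, calibration)
  }
  res
}

#' Synthetic UV-Vis spectra frame for known concentrations
#'
#' Builds an idealized absorbance frame in which each species contributes
#' `slope * concentration` uniformly over its own calibration window (and
#' nothing outside), so [absorbance_to_concentration()] recovers the
#' constructed concentrations exactly.
#'
#' @param c_product,c_substrate Concentrations, mM.
#' @param calibration A [spectra_calibration()].
#' @param timestamps Frame timestamps, s.
#' @param wavelengths Wavelength axis, nm (default 1 nm steps over
#'   260-330 nm).
#' @return A [spectra_frame()].
#' @export
synthetic_spectra_frame <- function(c_product, c_substrate, calibration,
                                    timestamps = 0,
                                    wavelengths = seq(260, 330, by = 1)) {
  stopifnot(inherits(calibration, "spectra_calibration"))
  nt <- length(timestamps)
  c_product <- rep_len(c_product, nt)
  c_substrate <- rep_len(c_substrate, nt)
  pw <- calibration$product_window
  sw <- calibration$substrate_window
  a <- matrix(0, nt, length(wavelengths))
  in_p <- wavelengths >= pw[1] & wavelengths <= pw[2]
  in_s <- wavelengths >= sw[1] & wavelengths <= sw[2]
  a[, in_p] <- a[, in_p] + outer(c_product * calibration$product_slope,
                                 rep(1, sum(in_p)))
  a[, in_s] <- a[, in_s] + outer(c_substrate * calibration$substrate_slope,
                                 rep(1, sum(in_s)))
  spectra_frame(timestamps, wavelengths, a)
}

#' Brute-force optimum of the virtual reactor
#'
#' Exhaustive noise-free grid evaluation of the space-time yield over a
#' design space: the oracle against which the iterative optimizer is
#' judged.
#'
#' @param reactor A [virtual_reactor()].
#' @param space A [design_space()] (use [plan_campaign()]'s reachable
#'   region to compare against the two-iteration scheme).
#' @param grid_n Grid points per axis (default 21).
#' @return List with `best` (one-row data frame with factors and `sty`)
#'   and the full `grid` data frame.
#' @export
true_optimum <- function(reactor, space = design_space(), grid_n = 21) {
  stopifnot(inherits(reactor, "virtual_reactor"),
            inherits(space, "design_space"))
  if (grid_n < 2) stop_domain("'grid_n' must be at least 2")
  axes <- lapply(space$bounds, function(b) seq(b[1], b[2],
                                               length.out = grid_n))
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  c0 <- dilution_to_concentration(reactor$stock, grid$dilution)
  tau <- residence_time(reactor$geometry$internal_volume, grid$flowrate)
  out <- cstr_cascade_outlet(c0, tau, reactor$kinetics,
                             temperature = grid$temperature,
                             flowrate = grid$flowrate)
  grid$sty <- sty(mm_to_g_per_l(out$product), grid$flowrate,
                  reactor$geometry$internal_volume)
  best <- grid[which.max(grid$sty), , drop = FALSE]
  list(best = best, grid = grid)
}

#' Random interior kinetics for recovery studies
#'
#' Draws a seeded `kinetic_params` whose temperature optimum lies in the
#' interior 70% of the design space's temperature axis, with maximal rate
#' log-uniform in 0.03-0.3 mM/s, `km` uniform in 0.2-2 mM, profile width
#' uniform in 3-8 C, tank count uniform in 4-20 and maldistribution
#' scale uniform in 1.4-2.2 mL/min: plausible variations of the default
#' virtual enzyme and bed for optimizer-recovery experiments.
#'
#' @param seed Integer seed.
#' @param space [design_space()] whose temperature axis bounds the
#'   optimum.
#' @param noise_rel Measurement noise passed through (default 0.01).
#' @return A [kinetic_params()].
#' @export
sample_kinetics <- function(seed, space = design_space(),
                            noise_rel = 0.01) {
  b <- space$bounds$temperature
  mid <- mean(b)
  hs <- diff(b) / 2 * 0.7
  with_seed(seed, {
    kinetic_params(
      vmax_ref = exp(stats::runif(1, log(0.03), log(0.3))),
      t_opt = stats::runif(1, mid - hs, mid + hs),
      t_width = stats::runif(1, 3, 8),
      km = stats::runif(1, 0.2, 2),
      n_tanks = sample(4:20, 1),
      noise_rel = noise_rel,
      flow_decay = stats::runif(1, 1.4, 2.2),
      seed = as.integer(seed)
    )
  })
}
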