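# Shared fixtures for the test suite. Everything is built in code.

water_like <- function() fluid_properties(density = 998,
                                          viscosity = 1e-3)

hc3 <- function() insert_library()$HC3

# Uniform time grid and the analytic open-open curves of one device,
# used as ground truth for curve-level comparisons.
analytic_device <- function(bo, tau, t_end = 6 * tau, n = 2000) {
  time <- seq(0, t_end, length.out = n)
  e <- open_open_E(time / tau, bo) / tau
  f <- as.numeric(pracma::cumtrapz(time, e))
  list(time = time, e = e, f = f)
}
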