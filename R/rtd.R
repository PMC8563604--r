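#' Normalize a raw step-tracer signal to an F-curve
#'
#' Converts a raw detector trace from a step-input tracer experiment into
#' the cumulative residence-time distribution F(t). The baseline is the
#' median of the first `edge_fraction` of samples and the plateau the
#' median of the last `edge_fraction`; the signal is rescaled to
#' `(s - baseline)/(plateau - baseline)` and clipped to `[0, 1]`. A
#' step-down trace (plateau below baseline) is handled transparently by
#' the same rescaling, which flips it into a rising F-curve.
#'
#' @param signal Raw detector values.
#' @param edge_fraction Fraction of samples used for the baseline and
#'   plateau medians (default 0.1).
#' @param min_step Minimum |plateau - baseline| required, as a multiple of
#'   the baseline-window spread (default 5); below it the step is
#'   indistinguishable from noise and an error is raised.
#' @param clip Clip the rescaled curve into `[0, 1]` (default `TRUE`).
#'   Clipping rectifies zero-mean detector noise at the baseline and
#'   plateau and therefore biases moment integrals; [analyze_rtd()] uses
#'   the unclipped curve for its moments and the clipped one for the
#'   reported F-curves.
#' @return Numeric F-curve (in `[0, 1]` when clipped).
#' @seealso [f_to_e()], [analyze_rtd()]
#' @export
normalize_step <- function(signal, edge_fraction = 0.1, min_step = 5,
                           clip = TRUE) {
  if (!is.numeric(signal) || length(signal) < 5L) {
    stop_domain("'signal' must be numeric with at least 5 samples")
  }
  n <- length(signal)
  m <- max(2L, floor(edge_fraction * n))
  head_w <- signal[seq_len(m)]
  tail_w <- signal[seq.int(n - m + 1L, n)]
  baseline <- stats::median(head_w)
  plateau <- stats::median(tail_w)
  noise <- max(stats::mad(head_w), stats::mad(tail_w), .Machine$double.eps)
  if (abs(plateau - baseline) < min_step * noise) {
    stop_domain("step height indistinguishable from baseline noise")
  }
  f <- (signal - baseline) / (plateau - baseline)
  if (clip) f <- pmin(pmax(f, 0), 1)
  f
}

#' Differentiate an F-curve into an E-curve
#'
#' E(t) = dF/dt by central differences (one-sided at the ends), after an
#' optional moving-average smoothing of F. Negative excursions from noise
#' are clipped to zero and the curve is renormalized so that the
#' trapezoidal integral of E over the record is exactly 1.
#'
#' @param f F-curve from [normalize_step()].
#' @param time Sample times, s, strictly increasing.
#' @param smooth_window Moving-average window on F before differencing
#'   (samples, default 5; 1 disables smoothing).
#' @return Numeric exit-age density E(t), 1/s.
#' @export
f_to_e <- function(f, time, smooth_window = 5) {
  if (length(f) < 5L || length(f) != length(time)) {
    stop_domain("need at least 5 samples and matching 'f'/'time' lengths")
  }
  if (any(diff(time) <= 0)) {
    stop_domain("'time' must be strictly increasing")
  }
  fs <- moving_average(f, smooth_window)
  n <- length(fs)
  e <- numeric(n)
  e[1] <- (fs[2] - fs[1]) / (time[2] - time[1])
  e[n] <- (fs[n] - fs[n - 1]) / (time[n] - time[n - 1])
  i <- 2:(n - 1)
  e[i] <- (fs[i + 1] - fs[i - 1]) / (time[i + 1] - time[i - 1])
  e <- pmax(e, 0)
  area <- trapz_int(time, e)
  if (area <= 0) {
    stop_domain("E-curve has zero mass; signal carries no step")
  }
  e / area
}

#' Moments of an exit-age distribution
#'
#' Mean residence time and variance of an E-curve by trapezoidal
#' quadrature: `t_mean = int t E dt`, `sigma^2 = int (t - t_mean)^2 E dt`.
#'
#' @param e E-curve (1/s), normalized to unit area.
#' @param time Sample times, s.
#' @return Named numeric `c(t_mean = , variance = )`.
#' @export
rtd_moments <- function(e, time) {
  if (length(e) != length(time) || length(e) < 5L) {
    stop_domain("need at least 5 samples and matching lengths")
  }
  t_mean <- trapz_int(time, time * e)
  variance <- trapz_int(time, (time - t_mean)^2 * e)
  c(t_mean = t_mean, variance = variance)
}

#' Moments of a step response directly from the F-curve
#'
#' For a normalized step response rising from 0 to 1, the RTD moments can
#' be taken without differentiating: `t_mean = int (1 - F) dt` and
#' `sigma^2 = 2 int t (1 - F) dt - t_mean^2` (integration by parts of the
#' E-curve moments). Avoiding the numerical derivative makes this
#' estimator far more robust to detector noise than the E-curve route,
#' and it is what [analyze_rtd()] uses internally; the record must extend
#' well into the plateau for the integrals to have converged.
#'
#' @param f Normalized F-curve in `[0, 1]` from [normalize_step()].
#' @param time Sample times, s, strictly increasing.
#' @return Named numeric `c(t_mean = , variance = )`.
#' @seealso [rtd_moments()] for the E-curve quadrature form.
#' @export
step_moments <- function(f, time) {
  if (length(f) != length(time) || length(f) < 5L) {
    stop_domain("need at least 5 samples and matching lengths")
  }
  if (any(diff(time) <= 0)) {
    stop_domain("'time' must be strictly increasing")
  }
  t_mean <- trapz_int(time, 1 - f)
  m2 <- 2 * trapz_int(time, time * (1 - f))
  c(t_mean = t_mean, variance = m2 - t_mean^2)
}

# Robust step-response moments for noisy detector traces, used by
# analyze_rtd(). Three refinements over a plain step_moments() on the
# median-normalized curve, each targeting a distinct noise pathway:
#   1. the plateau onset is located on a widely smoothed curve and the
#      (1 - F) integrals are truncated there -- beyond it the true
#      integrand is zero and the record contributes only noise;
#   2. baseline and plateau levels are re-estimated as means over their
#      full detected regions (the default last-10% median is far noisier
#      and a plateau-level error rescales the whole curve, which is the
#      dominant error term in the variance integral);
#   3. the curve is left unclipped so zero-mean noise stays zero-mean.
robust_step_moments <- function(signal, time) {
  f0 <- normalize_step(signal, clip = FALSE)
  n <- length(f0)
  w <- max(5L, floor(n / 40))
  fs <- moving_average(f0, w)
  sig_f <- stats::mad(diff(f0)) / sqrt(2)
  thr <- max(3 * sig_f / sqrt(w), 1e-5)
  below <- fs < 1 - thr
  i_plateau <- if (any(below)) min(n, max(which(below)) + w) else n
  above0 <- fs > thr
  i_rise <- if (any(above0)) max(2L, min(which(above0)) - w) else 2L
  f <- f0
  # re-estimate levels from the full flat regions when they are long
  # enough to improve on the edge medians
  if (n - i_plateau + 1L >= 50L && i_rise >= 50L) {
    baseline <- mean(signal[seq_len(i_rise)])
    plateau <- mean(signal[i_plateau:n])
    if (abs(plateau - baseline) > .Machine$double.eps) {
      f <- (signal - baseline) / (plateau - baseline)
    }
  }
  keep <- seq_len(i_plateau)
  tk <- time[keep]
  fk <- f[keep]
  t_mean <- trapz_int(tk, 1 - fk)
  m2 <- 2 * trapz_int(tk, tk * (1 - fk))
  c(t_mean = t_mean, variance = m2 - t_mean^2)
}

#' Inlet correction of RTD moments by additivity
#'
#' For devices in series, means and variances of the residence-time
#' distribution add. Subtracting the moments measured at the column inlet
#' from those at the outlet removes the contribution of the feed
#' capillary and upstream equipment.
#'
#' @param outlet,inlet Named numeric `c(t_mean = , variance = )` as
#'   returned by [rtd_moments()].
#' @return Corrected `c(t_mean = , variance = )`.
#' @export
correct_moments <- function(outlet, inlet) {
  out <- c(t_mean = unname(outlet["t_mean"] - inlet["t_mean"]),
           variance = unname(outlet["variance"] - inlet["variance"]))
  if (any(out < 0)) {
    stop_domain(
      "corrected moments negative: outlet moments smaller than inlet (inconsistent data)")
  }
  out
}

#' Dimensionless RTD variance of the open-open dispersion model
#'
#' `sigma_theta^2 = 2/Bo + 8/Bo^2`, the variance (normalized by the
#' squared space time) of the open-open axial dispersion model.
#'
#' @param bo Bodenstein number (> 0).
#' @return Dimensionless variance.
#' @seealso [bodenstein_from_variance()] for the exact inverse.
#' @export
sigma_theta2_from_bodenstein <- function(bo) {
  check_positive(bo = bo)
  2 / bo + 8 / bo^2
}

#' Bodenstein number from the dimensionless RTD variance
#'
#' Closed-form inverse of [sigma_theta2_from_bodenstein()]: the unique
#' positive root of `sigma_theta^2 = 2/Bo + 8/Bo^2`, namely
#' `Bo = 8 / (sqrt(1 + 8 sigma_theta^2) - 1)`.
#'
#' @param sigma_theta2 Dimensionless variance (> 0), normalized by the
#'   squared space time.
#' @return Bodenstein number.
#' @export
bodenstein_from_variance <- function(sigma_theta2) {
  check_positive(sigma_theta2 = sigma_theta2)
  8 / (sqrt(1 + 8 * sigma_theta2) - 1)
}

#' Bodenstein number from measured (observed-mean) moments
#'
#' In the open-open model the measured mean residence time exceeds the
#' space time tau: `t_mean = tau (1 + 2/Bo)`, while the variance relation
#' `sigma^2 = tau^2 (2/Bo + 8/Bo^2)` is written on tau. Eliminating tau,
#' the observable ratio `r = sigma^2 / t_mean^2` satisfies
#' `r = (2/Bo + 8/Bo^2) / (1 + 2/Bo)^2`, a quadratic in `1/Bo` whose
#' positive root this function returns. Use this form when only measured
#' moments are available; it is exactly consistent with
#' [bodenstein_from_variance()] once the mean bias is accounted for.
#'
#' @param t_mean Measured (inlet-corrected) mean residence time, s.
#' @param variance Measured (inlet-corrected) variance, s^2.
#' @return Bodenstein number (`Inf` when the variance is zero).
#' @export
bodenstein_from_measured <- function(t_mean, variance) {
  check_positive(t_mean = t_mean)
  check_positive(variance = variance, .allow_zero = TRUE)
  r <- unname(variance / t_mean^2)
  if (r == 0) return(Inf)
  if (r >= 2) {
    # r -> 2 as Bo -> 0; beyond it no open-open solution exists
    stop_domain("sigma^2/t_mean^2 >= 2: outside the open-open model range")
  }
  a <- 8 - 4 * r
  b <- 2 - 4 * r
  x <- (-b + sqrt(b^2 + 4 * a * r)) / (2 * a)
  1 / x
}

#' Full residence-time-distribution analysis of a step-tracer experiment
#'
#' Runs the complete estimation pipeline on dual-point (inlet + outlet)
#' step-tracer data: normalize both raw signals to F-curves, differentiate
#' to E-curves, take moments, correct the outlet moments for the inlet
#' contribution by additivity, and invert the open-open axial dispersion
#' model for the Bodenstein number. Also reports the space time, axial
#' dispersion coefficient `D_ax = u L / Bo`, superficial velocity and
#' Reynolds number for the insert at the given flowrate.
#'
#' If the corrected variance is (numerically) zero the dispersion is below
#' the measurement's resolution; the fit is flagged `above_range` and
#' `Bo = Inf` is reported rather than an error.
#'
#' @param log A `tracer_log` data frame from [read_tracer_log()] or
#'   [simulate_tracer_step()] (columns `time`, `signal_inlet`,
#'   `signal_outlet`).
#' @param geometry An [insert_geometry()].
#' @param fluid A [fluid_properties()].
#' @param flowrate Flowrate in mL/min.
#' @param smooth_window Smoothing window passed to [f_to_e()].
#' @return An object of class `rtd_fit` with the curves, raw and corrected
#'   moments, `sigma_theta2`, `bodenstein`, `space_time`, `d_ax` (m^2/s),
#'   `velocity` (m/s), `reynolds` and the `above_range` flag. Has
#'   `print()`, `summary()`, `coef()` and `plot()` methods.
#' @examples
#' log <- simulate_tracer_step(bo = 20, t_mean = 30, seed = 1)
#' fit <- analyze_rtd(log, insert_library()$HC3,
#'                    fluid_properties(998, 1e-3), flowrate = 0.5)
#' coef(fit)["bodenstein"]
#' @export
analyze_rtd <- function(log, geometry, fluid, flowrate,
                        smooth_window = 5) {
  stopifnot(inherits(geometry, "insert_geometry"),
            inherits(fluid, "fluid_properties"))
  check_positive(flowrate = flowrate)
  time <- log$time
  f_in <- normalize_step(log$signal_inlet)
  f_out <- normalize_step(log$signal_outlet)
  e_in <- f_to_e(f_in, time, smooth_window)
  e_out <- f_to_e(f_out, time, smooth_window)
  m_in <- robust_step_moments(log$signal_inlet, time)
  m_out <- robust_step_moments(log$signal_outlet, time)
  if (m_out["t_mean"] < m_in["t_mean"]) {
    stop_domain("outlet mean residence time below inlet mean: inconsistent data")
  }
  corrected <- c(t_mean = unname(m_out["t_mean"] - m_in["t_mean"]),
                 variance = max(0, unname(m_out["variance"] -
                                            m_in["variance"])))
  above_range <- corrected["variance"] <= 0 ||
    corrected["t_mean"] <= 0
  if (above_range) {
    bo <- Inf
    space_time <- unname(corrected["t_mean"])
    sigma_theta2 <- 0
  } else {
    bo <- bodenstein_from_measured(corrected["t_mean"],
                                   corrected["variance"])
    space_time <- unname(corrected["t_mean"]) / (1 + 2 / bo)
    sigma_theta2 <- unname(corrected["variance"]) / space_time^2
    above_range <- bo > 1e4
  }
  u <- superficial_velocity(flowrate, geometry$cross_section_area)
  l_char <- geometry$length / 1000
  d_ax <- if (is.finite(bo)) u * l_char / bo else 0
  re <- reynolds(fluid, u, geometry$hydraulic_diameter / 1000)
  structure(list(
    time = time, f_inlet = f_in, f_outlet = f_out,
    e_inlet = e_in, e_outlet = e_out,
    moments_inlet = m_in, moments_outlet = m_out,
    moments_corrected = corrected,
    sigma_theta2 = sigma_theta2,
    bodenstein = unname(bo),
    space_time = space_time,
    d_ax = d_ax, velocity = u, reynolds = re,
    flowrate = flowrate, geometry = geometry, fluid = fluid,
    above_range = isTRUE(unname(above_range))
  ), class = "rtd_fit")
}

#' @export
print.rtd_fit <- function(x, ...) {
  cat(sprintf("<rtd_fit> %s at %.3g mL/min\n", x$geometry$name,
              x$flowrate))
  cat(sprintf("  t_mean (corrected) = %.3g s, sigma^2 = %.3g s^2\n",
              x$moments_corrected["t_mean"],
              x$moments_corrected["variance"]))
  if (x$above_range) {
    cat("  Bo above measurable range (dispersion below resolution)\n")
  } else {
    cat(sprintf("  Bo = %.3g, D_ax = %.3g m^2/s, Re = %.3g\n",
                x$bodenstein, x$d_ax, x$reynolds))
  }
  invisible(x)
}

#' @export
summary.rtd_fit <- function(object, ...) {
  out <- list(coefficients = coef.rtd_fit(object),
              geometry = object$geometry,
              flowrate = object$flowrate,
              above_range = object$above_range)
  class(out) <- "summary.rtd_fit"
  out
}

#' @export
print.summary.rtd_fit <- function(x, ...) {
  cat(sprintf("Residence-time distribution fit: %s at %.3g mL/min\n\n",
              x$geometry$name, x$flowrate))
  print(round(x$coefficients, 6))
  if (x$above_range) {
    cat("\nNote: dispersion below the measurement resolution (Bo flagged above range)\n")
  }
  invisible(x)
}

#' @export
coef.rtd_fit <- function(object, ...) {
  c(t_mean = unname(object$moments_corrected["t_mean"]),
    variance = unname(object$moments_corrected["variance"]),
    space_time = object$space_time,
    sigma_theta2 = object$sigma_theta2,
    bodenstein = object$bodenstein,
    d_ax = object$d_ax,
    velocity = object$velocity,
    reynolds = object$reynolds)
}

#' @export
plot.rtd_fit <- function(x, which = c("F", "E"), ...) {
  which <- match.arg(which)
  if (which == "F") {
    graphics::plot(x$time, x$f_outlet, type = "l", xlab = "time [s]",
                   ylab = "F(t)", main = sprintf("%s: cumulative RTD",
                                                 x$geometry$name), ...)
    graphics::lines(x$time, x$f_inlet, lty = 2)
    graphics::legend("bottomright", c("outlet", "inlet"), lty = c(1, 2),
                     bty = "n")
  } else {
    graphics::plot(x$time, x$e_outlet, type = "l", xlab = "time [s]",
                   ylab = "E(t) [1/s]", main = sprintf("%s: exit-age density",
                                                       x$geometry$name), ...)
    graphics::lines(x$time, x$e_inlet, lty = 2)
    graphics::legend("topright", c("outlet", "inlet"), lty = c(1, 2),
                     bty = "n")
  }
  invisible(x)
}
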