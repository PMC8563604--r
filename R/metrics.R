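#' Starting concentration from a dilution ratio
#'
#' The platform doses substrate by running a solvent pump and a substrate
#' pump in a flow ratio `D` (solvent : substrate), so the feed
#' concentration is `c0 = stock / (1 + D)`. A 10 mM stock at `D = 4.36`
#' gives 1.87 mM.
#'
#' @param stock Stock concentration in mM.
#' @param dilution Dilution ratio `D` (>= 0, dimensionless).
#' @return Feed concentration in mM.
#' @export
dilution_to_concentration <- function(stock, dilution) {
  check_positive(stock = stock)
  check_positive(dilution = dilution, .allow_zero = TRUE)
  stock / (1 + dilution)
}

#' Split a total flowrate between substrate and solvent pumps
#'
#' For a target dilution ratio `D` the substrate pump delivers
#' `total / (1 + D)` and the solvent pump `total * D / (1 + D)`; the two
#' always sum exactly to the total.
#'
#' @param total_flowrate Total feed flowrate, mL/min.
#' @param dilution Dilution ratio `D` >= 0.
#' @return Named numeric vector `c(substrate = , solvent = )`, mL/min.
#' @export
pump_split <- function(total_flowrate, dilution) {
  check_positive(total_flowrate = total_flowrate)
  check_positive(dilution = dilution, .allow_zero = TRUE)
  substrate <- total_flowrate / (1 + dilution)
  c(substrate = substrate, solvent = total_flowrate - substrate)
}

#' UV-Vis quantification calibration
#'
#' Inline quantification integrates the absorbance over a species-specific
#' wavelength window and converts it to concentration with a linear
#' (Beer-Lambert) calibration slope. Defaults: product (vinylphenol)
#' window 263-269 nm, substrate (coumaric acid) window 325-328 nm, where
#' the product does not absorb; 1.5 mm flow-cell path length.
#'
#' @param product_slope,substrate_slope Calibration slopes in AU per mM.
#' @param product_window,substrate_window Wavelength windows in nm
#'   (length-2, non-overlapping).
#' @param path_length Optical path length in mm (stored for reference; the
#'   slopes are taken at this path length).
#' @return An object of class `spectra_calibration`.
#' @export
spectra_calibration <- function(product_slope, substrate_slope,
                                product_window = c(263, 269),
                                substrate_window = c(325, 328),
                                path_length = 1.5) {
  check_positive(product_slope = product_slope,
                 substrate_slope = substrate_slope,
                 path_length = path_length)
  pw <- sort(as.numeric(product_window))
  sw <- sort(as.numeric(substrate_window))
  if (pw[1] <= sw[2] && sw[1] <= pw[2]) {
    stop_domain("product and substrate windows must not overlap")
  }
  structure(list(product_window = pw, substrate_window = sw,
                 product_slope = product_slope,
                 substrate_slope = substrate_slope,
                 path_length = path_length),
            class = "spectra_calibration")
}

#' Quantify a species from a spectra frame
#'
#' Averages the absorbance over the species' calibration window and
#' divides by its slope. Negative concentrations (baseline noise) are
#' clipped to zero; when clipping occurs the result carries a `clipped`
#' attribute and a warning is raised.
#'
#' @param frame A [spectra_frame()].
#' @param calibration A [spectra_calibration()].
#' @param species `"product"` or `"substrate"`.
#' @return Numeric vector of concentrations (mM), one per timestamp.
#' @export
absorbance_to_concentration <- function(frame, calibration,
                                        species = c("product",
                                                    "substrate")) {
  stopifnot(inherits(frame, "spectra_frame"),
            inherits(calibration, "spectra_calibration"))
  species <- match.arg(species)
  window <- calibration[[paste0(species, "_window")]]
  slope <- calibration[[paste0(species, "_slope")]]
  wl <- frame$wavelengths
  if (window[1] < min(wl) || window[2] > max(wl)) {
    stop_domain(sprintf(
      "%s window [%g, %g] nm outside the frame's wavelength axis [%g, %g]",
      species, window[1], window[2], min(wl), max(wl)))
  }
  sel <- wl >= window[1] & wl <= window[2]
  conc <- rowMeans(frame$absorbance[, sel, drop = FALSE]) / slope
  if (any(conc < 0)) {
    warning("negative concentration clipped to 0")
    clipped <- conc < 0
    conc[clipped] <- 0
    attr(conc, "clipped") <- clipped
  }
  conc
}

#' Conversion and yield on a mole basis
#'
#' For the 1:1 decarboxylation of coumaric acid to vinylphenol:
#' conversion `X = (c0 - c_substrate)/c0`, yield `Y = c_prod/c0`.
#'
#' @param c0 Feed substrate concentration, mM (> 0).
#' @param c_substrate Steady-state outlet substrate concentration, mM.
#' @param c_prod Steady-state outlet product concentration, mM.
#' @return List with `conversion` and `yield` (fractions).
#' @export
conversion_and_yield <- function(c0, c_substrate, c_prod) {
  check_positive(c0 = c0)
  check_positive(c_substrate = c_substrate, c_prod = c_prod,
                 .allow_zero = TRUE)
  list(conversion = (c0 - c_substrate) / c0, yield = c_prod / c0)
}

#' Hydraulic residence time of an insert
#'
#' `tau = V_i / FR` with the interface units of the bench: volume in mm^3,
#' flowrate in mL/min, result in seconds.
#'
#' @param volume Internal volume in mm^3.
#' @param flowrate Flowrate in mL/min.
#' @return Residence time in s.
#' @examples
#' residence_time(234.65, 1.1) # ~12.8 s
#' @export
residence_time <- function(volume, flowrate) {
  check_positive(volume = volume, flowrate = flowrate)
  (volume / 1000) / flowrate * 60
}

#' Space-time yield
#'
#' `STY = c_prod * FR / V_i`: product mass concentration (g/L) times
#' volumetric flowrate over reactor internal volume, in g/(L h).
#'
#' @param c_prod Product concentration in g/L (>= 0).
#' @param flowrate Flowrate in mL/min.
#' @param volume Reactor internal volume in mm^3.
#' @return Space-time yield in g/(L h).
#' @export
sty <- function(c_prod, flowrate, volume) {
  check_positive(flowrate = flowrate, volume = volume)
  check_positive(c_prod = c_prod, .allow_zero = TRUE)
  fr_l_per_h <- flowrate * 60 / 1000
  v_l <- volume * 1e-6
  c_prod * fr_l_per_h / v_l
}

#' Millimolar to mass concentration
#'
#' @param conc_mM Concentration in mM.
#' @param molar_mass Molar mass in g/mol; default is vinylphenol
#'   (120.15 g/mol).
#' @return Concentration in g/L.
#' @export
mm_to_g_per_l <- function(conc_mM, molar_mass = 120.15) {
  conc_mM * molar_mass / 1000
}

#' Immobilization yield
#'
#' Percentage of solution enzymatic activity transferred to the support:
#' `Yi = (A_b - A_a)/A_b * 100`, from the activity of the immobilization
#' solution before (`A_b`) and after (`A_a`) immobilization.
#'
#' @param activity_before,activity_after Activities in U.
#' @return Yield in percent.
#' @export
immobilization_yield <- function(activity_before, activity_after) {
  check_positive(activity_before = activity_before)
  check_positive(activity_after = activity_after, .allow_zero = TRUE)
  if (any(activity_after > activity_before)) {
    stop_domain("activity after immobilization exceeds activity before")
  }
  (activity_before - activity_after) / activity_before * 100
}

#' Enzymatic activity from a timed batch assay
#'
#' `U = (C0 - Ct) * V_assay / t`: micromoles of substrate consumed per
#' minute over the initial linear region of the assay (by convention the
#' first 30 min).
#'
#' @param c_start,c_end Substrate concentrations at the start and end of
#'   the assay window, in umol/L.
#' @param assay_volume Assay volume in L.
#' @param time Assay duration in min (default 30).
#' @return Activity in U (umol/min).
#' @export
activity_units <- function(c_start, c_end, assay_volume, time = 30) {
  check_positive(assay_volume = assay_volume, time = time)
  check_positive(c_start = c_start, c_end = c_end, .allow_zero = TRUE)
  if (any(c_end > c_start)) {
    stop_domain("substrate concentration increased during the assay")
  }
  (c_start - c_end) * assay_volume / time
}

#' Detect steady state in a concentration trace
#'
#' Scans for the earliest window of `window` consecutive samples whose
#' relative range `(max - min)/|mean|` is at most `rel_tol`, and reports
#' the mean of that window as the steady-state value.
#'
#' @param x Numeric concentration series.
#' @param window Window length in samples (>= 3).
#' @param rel_tol Relative range tolerance (default 0.02).
#' @return List with `reached` (logical), `value` (window mean or `NA`)
#'   and `index` (start of the detected window or `NA`).
#' @export
steady_state_detect <- function(x, window = 30, rel_tol = 0.02) {
  if (window < 3) stop_domain("'window' must be at least 3 samples")
  n <- length(x)
  if (n >= window) {
    for (i in seq_len(n - window + 1L)) {
      w <- x[i:(i + window - 1L)]
      m <- mean(w)
      if (m != 0 && (max(w) - min(w)) / abs(m) <= rel_tol) {
        return(list(reached = TRUE, value = m, index = i))
      }
    }
  }
  list(reached = FALSE, value = NA_real_, index = NA_integer_)
}

# Assemble the standard per-run result row from a design point and the
# measured outlet concentrations.
experiment_result <- function(point, c0, c_substrate, c_product, insert,
                              molar_mass = 120.15) {
  cy <- conversion_and_yield(c0, c_substrate, c_product)
  tau <- residence_time(insert$internal_volume, point$flowrate)
  c_prod_g <- mm_to_g_per_l(c_product, molar_mass)
  data.frame(
    iteration = point$iteration, run_index = point$run_index,
    role = point$role,
    flowrate = point$flowrate, temperature = point$temperature,
    dilution = point$dilution,
    c0 = c0, c_substrate = c_substrate, c_product = c_product,
    c_product_g_l = c_prod_g,
    conversion = cy$conversion, yield = cy$yield,
    residence_time = tau,
    sty = sty(c_prod_g, point$flowrate, insert$internal_volume)
  )
}
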