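#' Read a dual-point tracer log
#'
#' Parses the plain-text serial-log dialect used for step-tracer
#' experiments: one line per sample, `"<t>,<v_in>,<v_out>"`, with `#`
#' starting comment lines. Times are seconds and must be strictly
#' increasing; the two detector signals are raw (arbitrary-unit) values
#' from the inlet and outlet flow cells.
#'
#' @param file Path or connection.
#' @return A data frame of class `tracer_log` with columns `time`,
#'   `signal_inlet`, `signal_outlet`, in file order.
#' @seealso [write_tracer_log()], [simulate_tracer_step()], [analyze_rtd()]
#' @export
read_tracer_log <- function(file) {
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop_domain("tracer log contains no data lines")
  }
  parts <- strsplit(lines[idx], ",", fixed = TRUE)
  for (j in seq_along(parts)) {
    p <- parts[[j]]
    vals <- suppressWarnings(as.numeric(p))
    if (length(p) != 3L || anyNA(vals) || any(!is.finite(vals))) {
      stop_domain(sprintf("malformed tracer log line %d: '%s'",
                          idx[j], lines[idx[j]]))
    }
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
  if (any(m[, 1] < 0)) {
    stop_domain("tracer log: negative elapsed time")
  }
  if (any(diff(m[, 1]) <= 0)) {
    bad <- which(diff(m[, 1]) <= 0)[1]
    stop_domain(sprintf(
      "tracer log: time not strictly increasing at data line %d (t = %g after %g)",
      bad + 1L, m[bad + 1L, 1], m[bad, 1]))
  }
  out <- data.frame(time = m[, 1], signal_inlet = m[, 2],
                    signal_outlet = m[, 3])
  class(out) <- c("tracer_log", "data.frame")
  out
}

#' Write a tracer log
#'
#' Inverse of [read_tracer_log()]: writes `time,signal_inlet,signal_outlet`
#' lines, optionally preceded by `#` comment lines.
#'
#' @param x A `tracer_log` data frame (or any data frame with the three
#'   columns).
#' @param file Path or connection.
#' @param comments Character vector of comment lines (without the leading
#'   `#`).
#' @export
write_tracer_log <- function(x, file, comments = NULL) {
  stopifnot(all(c("time", "signal_inlet", "signal_outlet") %in% names(x)))
  hdr <- if (length(comments)) paste0("# ", comments) else character()
  body <- sprintf("%.10g,%.10g,%.10g", x$time, x$signal_inlet,
                  x$signal_outlet)
  writeLines(c(hdr, body), file)
  invisible(NULL)
}

#' Read a UV-Vis spectra frame
#'
#' Reads a CSV whose first row holds wavelengths (nm, strictly increasing)
#' and whose first column holds timestamps (s); the body is an absorbance
#' matrix (AU), one row per timestamp.
#'
#' @param file Path or connection.
#' @return An object of class `spectra_frame`: a list with `timestamps`,
#'   `wavelengths` and the `absorbance` matrix (time x wavelength).
#' @export
read_spectra_frame <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2L) {
    stop_domain("spectra frame: need a header row and at least one data row")
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  width <- length(fields[[1]])
  bad <- which(vapply(fields, length, integer(1)) != width)
  if (length(bad)) {
    stop_domain(sprintf("spectra frame: ragged row at line %d", bad[1]))
  }
  wl <- suppressWarnings(as.numeric(fields[[1]][-1]))
  if (anyNA(wl)) {
    stop_domain("spectra frame: non-numeric wavelength header")
  }
  if (any(diff(wl) <= 0)) {
    stop_domain("spectra frame: wavelengths must be strictly increasing")
  }
  body <- matrix(suppressWarnings(as.numeric(unlist(fields[-1]))),
                 ncol = width, byrow = TRUE)
  if (anyNA(body)) {
    stop_domain("spectra frame: non-numeric value in body")
  }
  spectra_frame(timestamps = body[, 1],
                wavelengths = wl,
                absorbance = body[, -1, drop = FALSE])
}

#' Construct a spectra frame
#'
#' @param timestamps Numeric vector, seconds.
#' @param wavelengths Numeric vector, nm, strictly increasing.
#' @param absorbance Matrix, `length(timestamps)` x `length(wavelengths)`.
#' @return A `spectra_frame` object.
#' @export
spectra_frame <- function(timestamps, wavelengths, absorbance) {
  absorbance <- as.matrix(absorbance)
  if (any(diff(wavelengths) <= 0)) {
    stop_domain("wavelengths must be strictly increasing")
  }
  if (nrow(absorbance) != length(timestamps) ||
      ncol(absorbance) != length(wavelengths)) {
    stop_domain("absorbance matrix dimensions must match the axes")
  }
  structure(list(timestamps = as.numeric(timestamps),
                 wavelengths = as.numeric(wavelengths),
                 absorbance = absorbance),
            class = "spectra_frame")
}

#' @export
print.spectra_frame <- function(x, ...) {
  cat(sprintf("<spectra_frame> %d time points x %d wavelengths (%.1f-%.1f nm)\n",
              length(x$timestamps), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Write a spectra frame
#'
#' @param x A `spectra_frame`.
#' @param file Path or connection.
#' @export
write_spectra_frame <- function(x, file) {
  stopifnot(inherits(x, "spectra_frame"))
  hdr <- paste(c("time_s", format(x$wavelengths, trim = TRUE)),
               collapse = ",")
  body <- apply(cbind(x$timestamps, x$absorbance), 1, function(r) {
    paste(format(r, trim = TRUE, digits = 15), collapse = ",")
  })
  writeLines(c(hdr, body), file)
  invisible(NULL)
}

#' Write / read a design table
#'
#' A design table holds one row per planned experimental run: the
#' iteration, run index, role (center, axial or factorial), the coded
#' coordinates in the iteration's subregion and the real factor values in
#' engineering units.
#'
#' @param points A design-point data frame as produced by
#'   [generate_ccd()] or [plan_campaign()].
#' @param file Path or connection.
#' @return `read_design_table()` returns the data frame; the writer
#'   returns `NULL` invisibly.
#' @export
write_design_table <- function(points, file) {
  cols <- design_table_columns()
  stopifnot(all(cols %in% names(points)))
  utils::write.csv(points[, cols, drop = FALSE], file, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_design_table
#' @export
read_design_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  cols <- design_table_columns()
  if (!all(cols %in% names(df))) {
    stop_domain("design table: missing columns ",
                paste(setdiff(cols, names(df)), collapse = ", "))
  }
  df[, cols, drop = FALSE]
}

design_table_columns <- function() {
  c("iteration", "run_index", "role",
    paste0("coded_", factor_names()), factor_names())
}

#' Read / write a campaign configuration
#'
#' Campaign configurations are stored as YAML (`.yml`/`.yaml`) or JSON
#' (`.json`): factor bounds, stock concentration, subregion fractions,
#' insert name or geometry, steady-state settings and the seed.
#'
#' @param file Path; format chosen by extension.
#' @return `read_campaign_config()` returns a [campaign_config()] object.
#' @export
read_campaign_config <- function(file) {
  raw <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  space <- do.call(design_space, lapply(raw$design_space, as.numeric))
  insert <- raw$insert
  geom <- if (is.character(insert)) {
    insert_library()[[insert]]
  } else {
    do.call(insert_geometry, insert)
  }
  if (is.null(geom)) {
    stop_domain("campaign config: unknown insert '", insert, "'")
  }
  campaign_config(
    design_space = space,
    stock_concentration = raw$stock_concentration %||% 10,
    first_fraction = raw$first_fraction %||% 0.7,
    second_fraction = raw$second_fraction %||% 0.4,
    insert = geom,
    steady_state = raw$steady_state %||% list(window = 30, rel_tol = 0.02),
    seed = raw$seed %||% 1L
  )
}

#' @rdname read_campaign_config
#' @param config A [campaign_config()] object.
#' @export
write_campaign_config <- function(config, file) {
  stopifnot(inherits(config, "campaign_config"))
  raw <- list(
    design_space = lapply(config$design_space$bounds, as.numeric),
    stock_concentration = config$stock_concentration,
    first_fraction = config$first_fraction,
    second_fraction = config$second_fraction,
    insert = config$insert$name,
    steady_state = config$steady_state,
    seed = config$seed
  )
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(raw, file, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(raw, file)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
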