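#' Design space for the flow-reactor optimization
#'
#' The three manipulated factors of the automated campaign: total feed
#' flowrate (mL/min), reaction temperature (degrees C) and dilution ratio
#' (solvent-to-substrate pump flow ratio, dimensionless). Defaults are the
#' bounds screened on the structured-bed reactors: 0.2-2 mL/min, 25-35 C,
#' dilution 4-40.
#'
#' @param flowrate,temperature,dilution Length-2 numeric `c(lower, upper)`
#'   bounds per factor.
#' @return An object of class `design_space`.
#' @examples
#' design_space()
#' @export
design_space <- function(flowrate = c(0.2, 2),
                         temperature = c(25, 35),
                         dilution = c(4, 40)) {
  bounds <- list(flowrate = as.numeric(flowrate),
                 temperature = as.numeric(temperature),
                 dilution = as.numeric(dilution))
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || any(!is.finite(b)) || b[1] >= b[2]) {
      stop_domain(sprintf("'%s' bounds must be finite with lower < upper", nm))
    }
  }
  structure(list(bounds = bounds), class = "design_space")
}

factor_names <- function() c("flowrate", "temperature", "dilution")

#' @export
print.design_space <- function(x, ...) {
  cat("<design_space>\n")
  for (nm in names(x$bounds)) {
    cat(sprintf("  %-12s [%g, %g]\n", nm, x$bounds[[nm]][1],
                x$bounds[[nm]][2]))
  }
  invisible(x)
}

#' Axial/corner distance of the spherical CCD
#'
#' For a spherical central composite design with `k` factors the factorial
#' corners sit at radial distance `alpha = sqrt(k)` in coded units, equal
#' to the norm of a `(+/-1, ..., +/-1)` corner.
#'
#' @param k Number of factors (integer >= 1).
#' @return `sqrt(k)`.
#' @examples
#' ccd_alpha(3)
#' @export
ccd_alpha <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k)) {
    stop_domain("'k' must be a single integer >= 1")
  }
  sqrt(k)
}

#' Half-fraction corner points of a two-level factorial
#'
#' Returns the `2^(k-1)` sign vectors whose component product is `+1`
#' (defining relation `I = ABC...`), the half of the cube corners retained
#' by the fractional design. For `k = 3` these are the four corners
#' `(+,+,+), (+,-,-), (-,+,-), (-,-,+)`.
#'
#' @param k Number of factors.
#' @return A `2^(k-1) x k` matrix of `+1`/`-1`.
#' @export
half_fraction_corners <- function(k = 3) {
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k)) {
    stop_domain("'k' must be a single integer >= 1")
  }
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), k)))
  dimnames(signs) <- NULL
  keep <- apply(signs, 1, prod) == 1
  signs[keep, , drop = FALSE]
}

#' Centered first-iteration subregion
#'
#' The first CCD iteration screens a centered subsection of the full
#' design space whose per-axis span is `fraction` times the full span
#' (default 70%).
#'
#' @param space A [design_space()].
#' @param fraction Scalar in (0, 1].
#' @return An object of class `subregion` with per-factor `center` and
#'   `half_span`.
#' @examples
#' subregion_first(design_space(), 0.7)
#' @export
subregion_first <- function(space, fraction = 0.7) {
  stopifnot(inherits(space, "design_space"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop_domain("'fraction' must be in (0, 1]")
  }
  center <- vapply(space$bounds, mean, numeric(1))
  half_span <- vapply(space$bounds, function(b) diff(b) / 2, numeric(1)) *
    fraction
  new_subregion(center, half_span, space)
}

#' Second-iteration subregion around the first-iteration best point
#'
#' The second CCD iteration zooms onto the best point found in the first:
#' its subregion has per-axis span equal to `fraction` (default 40%) of
#' the first subregion's span and is centered at the best point. If a
#' non-default combination of fractions would push the region outside the
#' full design space it is translated inward, preserving its span, so the
#' CCD geometry stays intact.
#'
#' @param space The full [design_space()].
#' @param first The first-iteration [subregion_first()] region.
#' @param best Named numeric vector (or one-row data frame) with the real
#'   factor values of the first-iteration best point.
#' @param fraction Scalar in (0, 1].
#' @return A `subregion`.
#' @export
subregion_second <- function(space, first, best, fraction = 0.4) {
  stopifnot(inherits(space, "design_space"), inherits(first, "subregion"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop_domain("'fraction' must be in (0, 1]")
  }
  if (is.data.frame(best)) best <- unlist(best[1, factor_names()])
  best <- best[factor_names()]
  if (anyNA(best)) {
    stop_domain("'best' must supply all factor values")
  }
  lo_first <- first$center - first$half_span
  hi_first <- first$center + first$half_span
  if (any(best < lo_first - 1e-9) || any(best > hi_first + 1e-9)) {
    stop_domain("best point must lie inside the first-iteration subregion")
  }
  half_span <- fraction * first$half_span
  center <- best
  for (nm in factor_names()) {
    b <- space$bounds[[nm]]
    if (2 * half_span[nm] > diff(b)) {
      stop_domain("second subregion span exceeds the design space on '",
                  nm, "'")
    }
    center[nm] <- min(max(center[nm], b[1] + half_span[nm]),
                      b[2] - half_span[nm])
  }
  new_subregion(center, half_span, space)
}

new_subregion <- function(center, half_span, space) {
  nms <- factor_names()
  center <- stats::setNames(as.numeric(center[nms]), nms)
  half_span <- stats::setNames(as.numeric(half_span[nms]), nms)
  for (nm in nms) {
    b <- space$bounds[[nm]]
    if (center[nm] - half_span[nm] < b[1] - 1e-9 ||
        center[nm] + half_span[nm] > b[2] + 1e-9) {
      stop_domain("subregion extends outside the design space on '", nm, "'")
    }
  }
  structure(list(center = center, half_span = half_span, space = space),
            class = "subregion")
}

#' @export
print.subregion <- function(x, ...) {
  cat("<subregion>\n")
  for (nm in factor_names()) {
    cat(sprintf("  %-12s [%g, %g] (center %g)\n", nm,
                x$center[nm] - x$half_span[nm],
                x$center[nm] + x$half_span[nm], x$center[nm]))
  }
  invisible(x)
}

#' Convert between coded and real factor values
#'
#' Coded units map a subregion onto `[-1, +1]` per axis:
#' `real = center + coded * half_span`. The two functions are exact
#' inverses.
#'
#' @param coded,real Numeric vector or matrix (columns in factor order).
#' @param subregion A `subregion`.
#' @return Vector or matrix of the converted values.
#' @export
coded_to_real <- function(coded, subregion) {
  stopifnot(inherits(subregion, "subregion"))
  if (is.matrix(coded) || is.data.frame(coded)) {
    coded <- as.matrix(coded)
    sweep(sweep(coded, 2, subregion$half_span[colnames(coded) %||%
                                                factor_names()], `*`),
          2, subregion$center, `+`)
  } else {
    subregion$center + coded * subregion$half_span
  }
}

#' @rdname coded_to_real
#' @export
real_to_coded <- function(real, subregion) {
  stopifnot(inherits(subregion, "subregion"))
  if (is.matrix(real) || is.data.frame(real)) {
    real <- as.matrix(real)
    sweep(sweep(real, 2, subregion$center, `-`), 2, subregion$half_span, `/`)
  } else {
    (real - subregion$center) / subregion$half_span
  }
}

#' Generate one iteration of the fractional spherical CCD
#'
#' Builds the design points of one CCD iteration in a subregion as a
#' spherical design: the center point (optional), `2k` axial points at
#' `+/-1` on one coded axis (the subregion face centers), and the
#' half-fraction factorial corners at `+/-1/sqrt(k)` on every axis -- so
#' every non-center point lies on the coded unit sphere. In the textbook
#' scaling where corners sit at `+/-1`, the common radial distance is
#' `alpha = sqrt(k)`. For `k = 3` that is 11 points with the center and
#' 10 without.
#'
#' @param subregion The `subregion` to fill.
#' @param include_center Include the center point? The second campaign
#'   iteration reuses the measured first-iteration best as its center and
#'   does not re-run it.
#' @param iteration Iteration label stored with each point.
#' @param start_index Run index of the first generated point.
#' @return A data frame with columns `iteration`, `run_index`, `role`
#'   (`"center"`, `"axial"`, `"factorial"`), coded coordinates
#'   (`coded_*`) and real factor values.
#' @examples
#' nrow(generate_ccd(subregion_first(design_space())))
#' @export
generate_ccd <- function(subregion, include_center = TRUE, iteration = 1L,
                         start_index = 1L) {
  stopifnot(inherits(subregion, "subregion"))
  k <- length(factor_names())
  coded <- NULL
  role <- character()
  if (include_center) {
    coded <- rbind(coded, rep(0, k))
    role <- c(role, "center")
  }
  for (j in seq_len(k)) {
    for (s in c(-1, 1)) {
      v <- rep(0, k)
      v[j] <- s
      coded <- rbind(coded, v)
      role <- c(role, "axial")
    }
  }
  corners <- half_fraction_corners(k) / sqrt(k)
  coded <- rbind(coded, corners)
  role <- c(role, rep("factorial", nrow(corners)))
  colnames(coded) <- factor_names()
  rownames(coded) <- NULL
  real <- coded_to_real(coded, subregion)
  out <- data.frame(iteration = as.integer(iteration),
                    run_index = seq.int(start_index,
                                        length.out = nrow(coded)),
                    role = role)
  for (j in seq_len(k)) {
    out[[paste0("coded_", factor_names()[j])]] <- coded[, j]
  }
  for (j in seq_len(k)) {
    out[[factor_names()[j]]] <- real[, j]
  }
  out
}

#' Per-axis coverage of the two-iteration zoom scheme
#'
#' Fraction of each factor's full range reachable by some point of the
#' two-iteration scheme: a centered first region spanning `f1` of the
#' axis, plus a second region spanning `f2 * f1`, centered anywhere in the
#' first region (so extending at most `f2 * f1 / 2` beyond each first-region
#' edge). With the default fractions (0.7, 0.4) this is 0.98.
#'
#' @param f1,f2 First- and second-iteration span fractions, each in (0, 1].
#' @return Reachable fraction of the axis, capped at 1.
#' @examples
#' coverage_fraction(0.7, 0.4)
#' @export
coverage_fraction <- function(f1, f2) {
  if (any(!is.finite(c(f1, f2))) || any(c(f1, f2) <= 0) ||
      any(c(f1, f2) > 1)) {
    stop_domain("fractions must be in (0, 1]")
  }
  min(1, f1 * (1 + f2))
}

# Design space actually reachable by the two-iteration scheme: centered
# per-axis span f1*(1+f2) of the full range, capped at the full range.
reachable_space <- function(space, f1 = 0.7, f2 = 0.4) {
  stopifnot(inherits(space, "design_space"))
  cov <- coverage_fraction(f1, f2)
  bounds <- lapply(space$bounds, function(b) {
    mid <- mean(b)
    hs <- diff(b) / 2 * cov
    c(mid - hs, mid + hs)
  })
  do.call(design_space, bounds)
}

#' Select the best experimental run by space-time yield
#'
#' @param results Data frame of experiment results with columns `sty` and
#'   `run_index`.
#' @return The single best row; ties broken by earliest `run_index`.
#' @export
select_best <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    stop_domain("no results to select from")
  }
  stopifnot(all(c("sty", "run_index") %in% names(results)))
  ord <- order(-results$sty, results$run_index)
  results[ord[1], , drop = FALSE]
}

#' Campaign configuration
#'
#' Everything needed to plan and run a two-iteration optimization
#' campaign on one insert.
#'
#' @param design_space A [design_space()].
#' @param stock_concentration Substrate stock concentration in mM
#'   (default 10).
#' @param first_fraction,second_fraction Subregion span fractions of the
#'   two CCD iterations (defaults 0.7 and 0.4).
#' @param insert An [insert_geometry()].
#' @param steady_state List with `window` (samples) and `rel_tol` used by
#'   [steady_state_detect()] when a provider streams concentrations.
#' @param seed Integer campaign seed.
#' @return An object of class `campaign_config`.
#' @export
campaign_config <- function(design_space = flowdoe::design_space(),
                            stock_concentration = 10,
                            first_fraction = 0.7,
                            second_fraction = 0.4,
                            insert = insert_library()$HC3,
                            steady_state = list(window = 30,
                                                rel_tol = 0.02),
                            seed = 1L) {
  stopifnot(inherits(design_space, "design_space"),
            inherits(insert, "insert_geometry"))
  check_positive(stock_concentration = stock_concentration)
  for (f in c(first_fraction, second_fraction)) {
    if (!is.finite(f) || f <= 0 || f > 1) {
      stop_domain("subregion fractions must be in (0, 1]")
    }
  }
  structure(list(design_space = design_space,
                 stock_concentration = stock_concentration,
                 first_fraction = first_fraction,
                 second_fraction = second_fraction,
                 insert = insert,
                 steady_state = steady_state,
                 seed = as.integer(seed)),
            class = "campaign_config")
}

#' Plan a two-iteration CCD campaign
#'
#' Builds the first-iteration design (11 runs for three factors). The
#' second iteration depends on measurement: once the first-iteration best
#' point is known, pass it as `best` to complete the plan with the 10
#' second-iteration runs (the best point itself becomes the new center and
#' is not re-run), for 21 runs in total.
#'
#' @param config A [campaign_config()].
#' @param best Optional named vector / one-row data frame of real factor
#'   values of the first-iteration best point.
#' @return An object of class `campaign_plan`: subregions, the point
#'   table, and `alpha`.
#' @examples
#' plan <- plan_campaign(campaign_config())
#' nrow(plan$points) # 11 until the best point is known
#' @export
plan_campaign <- function(config, best = NULL) {
  stopifnot(inherits(config, "campaign_config"))
  k <- length(factor_names())
  sub1 <- subregion_first(config$design_space, config$first_fraction)
  pts <- generate_ccd(sub1, include_center = TRUE, iteration = 1L,
                      start_index = 1L)
  sub2 <- NULL
  if (!is.null(best)) {
    sub2 <- subregion_second(config$design_space, sub1, best,
                             config$second_fraction)
    pts2 <- generate_ccd(sub2, include_center = FALSE, iteration = 2L,
                         start_index = nrow(pts) + 1L)
    pts <- rbind(pts, pts2)
  }
  structure(list(subregion_1 = sub1, subregion_2 = sub2, points = pts,
                 alpha = ccd_alpha(k), config = config),
            class = "campaign_plan")
}

#' @export
print.campaign_plan <- function(x, ...) {
  n1 <- sum(x$points$iteration == 1L)
  n2 <- sum(x$points$iteration == 2L)
  cat(sprintf("<campaign_plan> alpha = %.4f, %d + %d runs%s\n", x$alpha,
              n1, n2,
              if (is.null(x$subregion_2)) " (iteration 2 pending)" else ""))
  invisible(x)
}
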