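#' Experiment provider backed by the virtual reactor
#'
#' Wraps a [virtual_reactor()] into the provider contract used by
#' [run_campaign()]: a function taking one design point and returning the
#' measured steady-state outlet concentrations
#' `list(substrate = , product = )` in mM. The simulator provider is
#' stateless apart from its per-run seeding, so the same point with the
#' same seed always returns the same result.
#'
#' @param reactor A [virtual_reactor()].
#' @param noise_rel Override for the measurement noise (default: the
#'   reactor kinetics' own).
#' @return A function `function(point) list(substrate, product)`.
#' @export
simulator_provider <- function(reactor,
                               noise_rel = reactor$kinetics$noise_rel) {
  stopifnot(inherits(reactor, "virtual_reactor"))
  function(point) {
    res <- simulate_experiment(point, reactor, noise_rel = noise_rel)
    list(substrate = res$c_substrate, product = res$c_product)
  }
}

#' Run a two-iteration automated optimization campaign
#'
#' The software analogue of the automated reaction platform: plan the
#' first CCD iteration (11 runs), execute every point through the
#' experiment provider, pick the best run by space-time yield, zoom the
#' design onto it (40% subregion by default, best point as new center),
#' execute the 10 second-iteration runs, and report the overall best of
#' all 21.
#'
#' A provider failure on a point marks that run failed and excludes it
#' from the selection; the campaign aborts (with an informative error) if
#' more than 20% of the runs fail.
#'
#' @param provider A function `function(point) list(substrate, product)`
#'   returning measured steady-state concentrations in mM, e.g.
#'   [simulator_provider()].
#' @param config A [campaign_config()].
#' @return An object of class `flow_campaign`: the completed plan, the
#'   per-run results table (21 rows, with a `status` column), the best
#'   run of iteration 1 and the final best. Has `print()`, `summary()`
#'   and `plot()` methods; see [campaign_report()] for file output.
#' @examples
#' reactor <- virtual_reactor(kinetics = kinetic_params(noise_rel = 0))
#' camp <- run_campaign(simulator_provider(reactor), campaign_config())
#' camp$best_final$sty
#' @export
run_campaign <- function(provider, config) {
  stopifnot(is.function(provider), inherits(config, "campaign_config"))
  plan1 <- plan_campaign(config)
  res1 <- run_points(provider, plan1$points, config)
  ok1 <- res1[res1$status == "ok", , drop = FALSE]
  check_failure_budget(res1, nrow(plan1$points))
  best1 <- select_best(ok1)
  plan <- plan_campaign(config, best = best1[, factor_names()])
  pts2 <- plan$points[plan$points$iteration == 2L, , drop = FALSE]
  res2 <- run_points(provider, pts2, config)
  results <- rbind(res1, res2)
  check_failure_budget(results, nrow(plan$points))
  ok <- results[results$status == "ok", , drop = FALSE]
  best_final <- select_best(ok)
  structure(list(plan = plan, config = config, results = results,
                 best_iteration1 = best1, best_final = best_final),
            class = "flow_campaign")
}

run_points <- function(provider, points, config) {
  rows <- vector("list", nrow(points))
  for (i in seq_len(nrow(points))) {
    pt <- points[i, , drop = FALSE]
    c0 <- dilution_to_concentration(config$stock_concentration,
                                    pt$dilution)
    meas <- tryCatch(provider(pt), error = function(e) e)
    if (inherits(meas, "error")) {
      row <- experiment_result(pt, c0, c0, 0, config$insert)
      row[c("c_substrate", "c_product", "c_product_g_l", "conversion",
            "yield", "sty")] <- NA_real_
      row$status <- "failed"
      row$message <- conditionMessage(meas)
    } else {
      row <- experiment_result(pt, c0,
                               max(0, meas$substrate),
                               max(0, meas$product),
                               config$insert)
      row$status <- "ok"
      row$message <- ""
    }
    row$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

check_failure_budget <- function(results, n_planned) {
  n_fail <- sum(results$status != "ok")
  if (n_fail > 0.2 * n_planned) {
    stop_domain(sprintf(
      "campaign aborted: %d of %d runs failed (more than 20%%)",
      n_fail, n_planned))
  }
  invisible(TRUE)
}

#' @export
print.flow_campaign <- function(x, ...) {
  ok <- sum(x$results$status == "ok")
  cat(sprintf("<flow_campaign> %s: %d/%d runs ok\n",
              x$config$insert$name, ok, nrow(x$results)))
  b <- x$best_final
  cat(sprintf(
    "  best: %.3g mL/min, %.3g C, dilution %.3g -> STY %.3g g/(L h)\n",
    b$flowrate, b$temperature, b$dilution, b$sty))
  invisible(x)
}

#' @export
summary.flow_campaign <- function(object, ...) {
  out <- list(insert = object$config$insert$name,
              table = campaign_summary_table(object),
              best_final = object$best_final,
              n_failed = sum(object$results$status != "ok"))
  class(out) <- "summary.flow_campaign"
  out
}

#' @export
print.summary.flow_campaign <- function(x, ...) {
  cat(sprintf("Two-iteration CCD campaign on %s\n\n", x$insert))
  print(x$table, row.names = FALSE, digits = 4)
  if (x$n_failed > 0) {
    cat(sprintf("\n%d run(s) failed and were excluded\n", x$n_failed))
  }
  invisible(x)
}

# Per-iteration best yield / STY / residence time, one row per iteration.
campaign_summary_table <- function(x) {
  ok <- x$results[x$results$status == "ok", , drop = FALSE]
  do.call(rbind, lapply(sort(unique(ok$iteration)), function(it) {
    b <- select_best(ok[ok$iteration == it, , drop = FALSE])
    data.frame(iteration = it,
               yield_pct = 100 * b$yield,
               sty = b$sty,
               residence_time_s = b$residence_time,
               flowrate = b$flowrate,
               temperature = b$temperature,
               dilution = b$dilution)
  }))
}

#' @export
plot.flow_campaign <- function(x, ...) {
  ok <- x$results[x$results$status == "ok", , drop = FALSE]
  cols <- ifelse(ok$iteration == 1L, "steelblue", "firebrick")
  graphics::plot(ok$residence_time, ok$sty, pch = 19, col = cols,
                 xlab = "residence time [s]", ylab = "STY [g/(L h)]",
                 main = sprintf("Campaign on %s", x$config$insert$name),
                 ...)
  b <- x$best_final
  graphics::points(b$residence_time, b$sty, pch = 1, cex = 2)
  graphics::legend("topright", c("iteration 1", "iteration 2", "best"),
                   pch = c(19, 19, 1),
                   col = c("steelblue", "firebrick", "black"), bty = "n")
  invisible(x)
}

#' Write campaign outputs to files
#'
#' Writes the machine-readable record of a campaign: the full per-run log
#' as CSV (`runs.csv`), the per-iteration best table as CSV
#' (`summary.csv`) and a JSON summary (`summary.json`) with the plan
#' geometry and the best points. For an aborted campaign, pass the
#' partial results via `runs` and an `abort_reason`.
#'
#' @param x A `flow_campaign` from [run_campaign()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
campaign_report <- function(x, dir) {
  stopifnot(inherits(x, "flow_campaign"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  runs_path <- file.path(dir, "runs.csv")
  summary_path <- file.path(dir, "summary.csv")
  json_path <- file.path(dir, "summary.json")
  utils::write.csv(x$results, runs_path, row.names = FALSE)
  utils::write.csv(campaign_summary_table(x), summary_path,
                   row.names = FALSE)
  best <- x$best_final
  jsonlite::write_json(list(
    insert = x$config$insert$name,
    alpha = x$plan$alpha,
    n_runs = nrow(x$results),
    n_failed = sum(x$results$status != "ok"),
    best_iteration1 = as.list(x$best_iteration1[, c(factor_names(),
                                                    "yield", "sty")]),
    best_final = as.list(best[, c(factor_names(), "yield", "sty",
                                  "residence_time")])
  ), json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(runs = runs_path, summary = summary_path, json = json_path))
}
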