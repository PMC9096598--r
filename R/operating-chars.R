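#' Named simulation scenarios
#'
#' Two presets are shipped: `"null"` (both arms 25\% favorable — the
#' no-treatment-benefit hypothesis under which the published
#' operating-characteristic comparisons were made) and `"alternative"`
#' (25\% control vs 32\% treatment, the design effect).  Any generator
#' parameter can be overridden.
#'
#' @param name `"null"`, `"alternative"`, or `"custom"`.
#' @param ... Overrides passed to [generator_params()] (e.g.
#'   `p90_treatment`, `accrual_rate`).
#' @return An object of class `trial_scenario`.
#' @export
trial_scenario <- function(name = c("null", "alternative", "custom"), ...) {
  name <- match.arg(name)
  base <- switch(name,
                 null = list(p90_control = 0.25, p90_treatment = 0.25),
                 alternative = list(p90_control = 0.25, p90_treatment = 0.32),
                 custom = list())
  overrides <- list(...)
  structure(list(name = name, params = utils::modifyList(base, overrides)),
            class = "trial_scenario")
}

.scenario_params <- function(scenario, seed) {
  if (is.character(scenario)) scenario <- trial_scenario(scenario)
  stopifnot(inherits(scenario, "trial_scenario"))
  do.call(generator_params, utils::modifyList(scenario$params, list(seed = seed)))
}

#' Monte-Carlo operating characteristics of either design
#'
#' Generates `n_sims` independent seeded patient-level datasets from the
#' scenario and runs the chosen design end-to-end on each (dataset `i` uses
#' seed `seed + i`, so the run is fully reproducible and extensible).
#' Futility is treated as binding for both designs in this mode — the
#' published design-stage numbers came from binding-rule simulation, and
#' the executed trial's data-monitoring-committee discretion is not
#' simulable.
#'
#' @param design `"goldilocks"` or `"group_sequential"`.
#' @param scenario A [trial_scenario()] or preset name.
#' @param n_sims Number of simulated trials.
#' @param seed Base seed.
#' @param config Design configuration ([goldilocks_config()] or
#'   [gs_config()]); sensible defaults are used if omitted.  For the
#'   Goldilocks design, `config$n_draws` controls the inner predictive
#'   draws per interim.
#' @return An object of class `oc_result`: expected enrolled sample size at
#'   termination, early-futility and success probabilities (with Monte-Carlo
#'   standard errors), the per-stop-point distribution, and the per-trial
#'   results table.
#' @export
simulate_ocs <- function(design = c("goldilocks", "group_sequential"),
                         scenario = "null", n_sims = 1000L, seed = 1L,
                         config = NULL) {
  design <- match.arg(design)
  n_sims <- assert_count(n_sims, "n_sims")
  if (n_sims < 1L) stop("`n_sims` must be >= 1", call. = FALSE)
  if (is.null(config)) {
    config <- if (design == "goldilocks") goldilocks_config(n_draws = 2000L)
              else gs_config(boundary_table = shine_boundaries(), futility_binding = TRUE)
  }
  gs_bounds <- if (design == "group_sequential") boundaries_from_spending(config)
  res <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    params <- .scenario_params(scenario, seed = seed + i)
    dataset <- generate_trial(params)
    if (design == "goldilocks") {
      cfg_i <- config
      cfg_i$seed <- as.integer(seed + i)
      r <- .run_goldilocks_multi(dataset, cfg_i, cfg_i$final_posterior_threshold)
      res[[i]] <- data.frame(sim = i, n_final = r$n_final[1L],
                             stop_reason = r$reason[1L], success = r$success[1L],
                             stringsAsFactors = FALSE)
    } else {
      r <- run_gs(dataset, config, stop_on_futility = TRUE, bounds = gs_bounds)
      res[[i]] <- data.frame(sim = i, n_final = r$n_enrolled_final,
                             stop_reason = r$stop_reason, success = r$success,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, res)
  p_se <- function(p) sqrt(p * (1 - p) / n_sims)
  early_fut <- res$stop_reason == "futility"
  p_fut <- mean(early_fut)
  p_succ <- mean(res$success)
  expected_n <- mean(res$n_final)
  structure(list(design = design,
                 scenario = if (is.character(scenario)) scenario else scenario$name,
                 n_sims = n_sims, expected_n = expected_n,
                 se_expected_n = stats::sd(res$n_final) / sqrt(n_sims),
                 p_early_futility = p_fut, se_p_early_futility = p_se(p_fut),
                 p_success = p_succ, se_p_success = p_se(p_succ),
                 stop_distribution = prop.table(table(res$n_final)),
                 results = res),
            class = "oc_result")
}

#' @export
print.oc_result <- function(x, ...) {
  cat(sprintf("Operating characteristics: %s design, '%s' scenario, %d simulated trials\n",
              x$design, x$scenario, x$n_sims))
  cat(sprintf("  expected enrolled N at termination: %.1f (MC SE %.1f)\n",
              x$expected_n, x$se_expected_n))
  cat(sprintf("  P(early futility stop): %.3f (MC SE %.3f)\n",
              x$p_early_futility, x$se_p_early_futility))
  cat(sprintf("  P(trial success):       %.3f (MC SE %.3f)\n",
              x$p_success, x$se_p_success))
  invisible(x)
}

#' Calibrate the final posterior-superiority threshold by simulation
#'
#' Simulates null-scenario Goldilocks executions at every candidate final
#' threshold using common random numbers (one shared set of datasets and
#' interim predictive draws; the interim draws do not depend on the
#' threshold, so each trial is executed once and thresholded across the
#' whole grid), and returns the smallest grid threshold whose simulated
#' one-sided type I error is at or below the target.
#'
#' @param grid Increasing candidate thresholds in (0.5, 1).
#' @param target_alpha One-sided type I error bound.
#' @param scenario Null-truth scenario (both arms at the control rate by
#'   default).
#' @param n_sims Simulated trials.
#' @param seed Base seed.
#' @param config Base [goldilocks_config()]; its
#'   `final_posterior_threshold` is replaced by each grid value.
#' @return A list with `threshold` (the selected grid value), `curve` (a
#'   data frame of simulated type I error by threshold, with MC standard
#'   errors) and `n_sims`.  Errors if no grid point meets the target.
#' @export
calibrate_final_threshold <- function(grid = seq(0.969, 0.989, by = 0.002),
                                      target_alpha = 0.025,
                                      scenario = "null", n_sims = 1000L,
                                      seed = 1L,
                                      config = goldilocks_config(n_draws = 2000L)) {
  grid <- sort(grid)
  if (any(grid <= 0.5) || any(grid >= 1)) {
    stop("`grid` thresholds must lie in (0.5, 1)", call. = FALSE)
  }
  assert_scalar_prob(target_alpha, "target_alpha")
  succ <- matrix(FALSE, n_sims, length(grid))
  for (i in seq_len(n_sims)) {
    params <- .scenario_params(scenario, seed = seed + i)
    dataset <- generate_trial(params)
    cfg_i <- config
    cfg_i$seed <- as.integer(seed + i)
    succ[i, ] <- .run_goldilocks_multi(dataset, cfg_i, grid)$success
  }
  type1 <- colMeans(succ)
  curve <- data.frame(threshold = grid, type1 = type1,
                      mc_se = sqrt(type1 * (1 - type1) / n_sims))
  ok <- which(type1 <= target_alpha)
  if (!length(ok)) {
    stop(paste0("no grid threshold attains the target type I error; curve:\n",
                paste(utils::capture.output(print(curve)), collapse = "\n")),
         call. = FALSE)
  }
  list(threshold = grid[min(ok)], curve = curve, n_sims = n_sims)
}
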