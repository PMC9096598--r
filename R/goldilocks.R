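#' Configuration of the Bayesian Goldilocks design
#'
#' Defaults are the published alternative design of the motivating stroke
#' glycemic-control trial: first interim after 500 patients randomized, a
#' further interim after every additional 100, maximum 1400 patients;
#' accrual stops early for predicted success when the predictive probability
#' of success at the current sample size exceeds 99\%; the trial stops
#' (bindingly) for futility when the predictive probability of success at
#' the maximum sample size falls below 5\%; the final analysis declares
#' success when the posterior probability of superiority is at least 97.9\%,
#' a critical value calibrated by simulation to keep the one-sided type I
#' error below 2.5\% despite the repeated looks.
#'
#' @param first_interim Randomized-patient count at the first interim.
#' @param interim_step Additional randomized patients between interims.
#' @param n_max Maximum number randomized.
#' @param pp_success_threshold Stop accrual for predicted success when
#'   PPn exceeds this value.
#' @param pp_futility_threshold Stop for futility when PPmax falls below
#'   this value.
#' @param final_posterior_threshold Posterior probability of superiority
#'   required for success at the final analysis.
#' @param n_draws Posterior-predictive completions per interim.
#' @param seed Master seed; each interim draws from a substream keyed by
#'   `seed + milestone` so one interim's decision never perturbs the draws
#'   of a later one.
#' @param use_longitudinal Impute incomplete 90-day outcomes of patients
#'   with a 6-week outcome through the longitudinal model?  When `FALSE`,
#'   such patients are imputed from the arm's marginal posterior instead.
#' @param pooled_transition Pool the transition model across arms (see
#'   [fit_transition_model()])?
#' @param prior Prior [beta_posterior()] for every rate (noninformative
#'   uniform by default).
#' @return An object of class `goldilocks_config`.
#' @export
goldilocks_config <- function(first_interim = 500L, interim_step = 100L,
                              n_max = 1400L,
                              pp_success_threshold = 0.99,
                              pp_futility_threshold = 0.05,
                              final_posterior_threshold = 0.979,
                              n_draws = 10000L, seed = 1L,
                              use_longitudinal = TRUE,
                              pooled_transition = FALSE,
                              prior = beta_posterior(1, 1)) {
  first_interim <- assert_count(first_interim, "first_interim")
  interim_step <- assert_count(interim_step, "interim_step")
  n_max <- assert_count(n_max, "n_max")
  assert_scalar_prob(pp_success_threshold, "pp_success_threshold")
  assert_scalar_prob(pp_futility_threshold, "pp_futility_threshold")
  assert_scalar_prob(final_posterior_threshold, "final_posterior_threshold")
  if (!(pp_futility_threshold < pp_success_threshold)) {
    stop("`pp_futility_threshold` must be below `pp_success_threshold`", call. = FALSE)
  }
  if (first_interim > n_max) stop("`first_interim` must not exceed `n_max`", call. = FALSE)
  if (interim_step < 1L) stop("`interim_step` must be >= 1", call. = FALSE)
  n_draws <- assert_count(n_draws, "n_draws")
  structure(list(first_interim = first_interim, interim_step = interim_step,
                 n_max = n_max, pp_success_threshold = pp_success_threshold,
                 pp_futility_threshold = pp_futility_threshold,
                 final_posterior_threshold = final_posterior_threshold,
                 n_draws = n_draws, seed = as.integer(seed),
                 use_longitudinal = isTRUE(use_longitudinal),
                 pooled_transition = isTRUE(pooled_transition),
                 prior = prior),
            class = "goldilocks_config")
}

#' Interim schedule of the Goldilocks design
#'
#' Milestones (randomized-patient counts) at which interims occur; the
#' final analysis at `n_max` is not an interim and is never included.
#'
#' @param config A [goldilocks_config()].
#' @return Integer vector of milestones (possibly empty).
#' @export
interim_schedule <- function(config) {
  stopifnot(inherits(config, "goldilocks_config"))
  s <- seq(config$first_interim, config$n_max, by = config$interim_step)
  as.integer(s[s < config$n_max])
}

#' Interim decision rule of the Goldilocks design
#'
#' Accrual stops for predicted success when `pp_current` exceeds the
#' success threshold; otherwise the trial stops for futility when `pp_max`
#' falls below the futility threshold; otherwise enrollment continues.
#'
#' @param pp A [predictive_probabilities()] result.
#' @param config A [goldilocks_config()].
#' @return One of `"stop_accrual_predicted_success"`, `"stop_futility"`,
#'   `"continue"`.
#' @export
interim_decide <- function(pp, config) {
  stopifnot(inherits(pp, "predictive_result"), inherits(config, "goldilocks_config"))
  if (pp$pp_current > config$pp_success_threshold) {
    "stop_accrual_predicted_success"
  } else if (pp$pp_max < config$pp_futility_threshold) {
    "stop_futility"
  } else {
    "continue"
  }
}

#' Final Bayesian analysis on complete follow-up
#'
#' Computes the posterior probability that the treatment arm's favorable
#' rate exceeds the control arm's, from a dataset in which every patient has
#' an observed 90-day outcome, and compares it with the success threshold.
#'
#' @param dataset A `trial_data` data frame with no missing `y90` (impute or
#'   exclude incomplete patients upstream).
#' @param config A [goldilocks_config()].
#' @return A list with `posterior_superiority`, `success`, and the per-arm
#'   counts used.
#' @export
final_analysis <- function(dataset, config) {
  validate_trial_data(dataset)
  stopifnot(inherits(config, "goldilocks_config"))
  if (anyNA(dataset$y90)) {
    stop("final analysis requires an observed 90-day outcome for every patient",
         call. = FALSE)
  }
  tt <- dataset$arm == "treatment"
  x_t <- sum(dataset$y90[tt]); n_t <- sum(tt)
  x_c <- sum(dataset$y90[!tt]); n_c <- sum(!tt)
  if (n_t == 0L || n_c == 0L) stop("both arms must be represented", call. = FALSE)
  post <- .psup_counts(x_t, n_t, x_c, n_c, config$prior)
  list(posterior_superiority = post,
       success = post >= config$final_posterior_threshold,
       x_t = x_t, n_t = n_t, x_c = x_c, n_c = n_c)
}

# Shared virtual-execution engine, evaluated at one or more candidate final
# posterior thresholds simultaneously.  The interim posterior-predictive
# draws do not depend on the final threshold, so the per-draw superiority
# probabilities (qn, qm) are computed once per interim and thresholded
# afterwards; this makes threshold calibration (common random numbers across
# the grid) no more expensive than a single execution.
.run_goldilocks_multi <- function(dataset, config, thresholds, keep_log = FALSE) {
  validate_trial_data(dataset)
  n_avail <- nrow(dataset)
  n_final_cap <- min(config$n_max, n_avail)
  sched <- interim_schedule(config)
  sched <- sched[sched <= n_avail]
  k <- length(thresholds)
  active <- rep(TRUE, k)
  reason <- rep("max_enrollment", k)
  n_final <- rep(as.integer(n_final_cap), k)
  log_rows <- list()
  final_cache <- new.env(parent = emptyenv())
  final_post_at <- function(m) {
    key <- as.character(m)
    if (is.null(final_cache[[key]])) {
      d <- dataset[seq_len(m), , drop = FALSE]
      d <- d[!is.na(d$y90), , drop = FALSE]  # complete cases at full follow-up
      tt <- d$arm == "treatment"
      final_cache[[key]] <- .psup_counts(sum(d$y90[tt]), sum(tt),
                                         sum(d$y90[!tt]), sum(!tt), config$prior)
    }
    final_cache[[key]]
  }
  for (m in sched) {
    if (!any(active)) break
    snap <- snapshot_at(dataset, m)
    model <- fit_transition_model(snap, config$prior, config$pooled_transition)
    d <- with_seed(config$seed + m,
                   .pp_draws(snap, model, config$n_max, config$n_draws,
                             config$prior, config$use_longitudinal))
    ppn <- colMeans(outer(d$qn, thresholds, ">="))
    ppm <- colMeans(outer(d$qm, thresholds, ">="))
    if (keep_log) {
      ct <- d$counts$treatment; cc <- d$counts$control
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        milestone = m, n_enrolled = snap$n_enrolled,
        n_complete90 = snap$n_complete90,
        prop_treatment = if (ct$n_obs > 0) ct$x_obs / ct$n_obs else NA_real_,
        prop_control = if (cc$n_obs > 0) cc$x_obs / cc$n_obs else NA_real_,
        pp_current = ppn[1L], pp_max = ppm[1L],
        action = NA_character_, stringsAsFactors = FALSE)
    }
    stop_succ <- active & ppn > config$pp_success_threshold
    stop_fut <- active & !stop_succ & ppm < config$pp_futility_threshold
    reason[stop_succ] <- "predicted_success"
    reason[stop_fut] <- "futility"
    n_final[stop_succ | stop_fut] <- m
    active <- active & !stop_succ & !stop_fut
    if (keep_log) {
      act <- if (stop_succ[1L]) "stop_accrual_predicted_success"
             else if (stop_fut[1L]) "stop_futility" else "continue"
      log_rows[[length(log_rows)]]$action <- act
      if (act != "continue") break
    }
  }
  final_post <- rep(NA_real_, k)
  success <- rep(FALSE, k)
  needs_final <- reason != "futility"
  for (i in which(needs_final)) {
    final_post[i] <- final_post_at(n_final[i])
    success[i] <- final_post[i] >= thresholds[i]
  }
  list(reason = reason, n_final = n_final, final_post = final_post,
       success = success,
       log = if (keep_log) do.call(rbind, log_rows) else NULL)
}

#' Virtually execute the Goldilocks design on a patient-level dataset
#'
#' Walks the interim schedule: at each milestone the interim snapshot is
#' taken, the longitudinal transition model is fitted, the two predictive
#' probabilities are computed and the interim decision rule applied.  On a
#' futility stop the trial terminates unsuccessfully (the futility rule is
#' binding; no final analysis occurs).  On an accrual stop for predicted
#' success, the enrolled patients complete follow-up (their eventual 90-day
#' outcomes in `dataset` are revealed) and the final analysis is run.  If no
#' interim triggers, enrollment proceeds to the maximum and the final
#' analysis is run there.
#'
#' @param dataset A `trial_data` data frame covering all patients that could
#'   be randomized (see [generate_trial()] or [read_trial_csv()]).
#' @param config A [goldilocks_config()].
#' @return An object of class `goldilocks_result`: a list with `decisions`
#'   (the interim decision log), `stop_reason` (`"futility"`,
#'   `"predicted_success"` or `"max_enrollment"`), `n_enrolled_final`,
#'   `final_posterior_superiority` (`NA` after a futility stop) and
#'   `success`.
#' @export
run_goldilocks <- function(dataset, config) {
  stopifnot(inherits(config, "goldilocks_config"))
  r <- .run_goldilocks_multi(dataset, config,
                             config$final_posterior_threshold, keep_log = TRUE)
  structure(list(decisions = r$log, stop_reason = r$reason[1L],
                 n_enrolled_final = r$n_final[1L],
                 final_posterior_superiority = r$final_post[1L],
                 success = r$success[1L], config = config),
            class = "goldilocks_result")
}

#' @export
print.goldilocks_result <- function(x, ...) {
  cat(sprintf("Goldilocks execution: %s at n = %d; %s\n",
              switch(x$stop_reason,
                     futility = "stopped for futility",
                     predicted_success = "accrual stopped for predicted success",
                     max_enrollment = "ran to maximum enrollment"),
              x$n_enrolled_final,
              if (isTRUE(x$success)) {
                sprintf("final posterior superiority %.4f -> SUCCESS",
                        x$final_posterior_superiority)
              } else if (x$stop_reason == "futility") {
                "no final analysis (binding futility)"
              } else {
                sprintf("final posterior superiority %.4f -> no success",
                        x$final_posterior_superiority)
              }))
  if (!is.null(x$decisions)) {
    cat("Interim decision log:\n")
    print(x$decisions, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
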