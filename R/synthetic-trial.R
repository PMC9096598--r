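#' Parameters for the synthetic two-arm trial generator
#'
#' Describes the data-generating process for a two-arm (1:1) randomized trial
#' with a binary primary outcome assessed 90 days after enrollment and an
#' earlier binary assessment of the same construct at 6 weeks.  The joint law
#' of the two outcomes is parameterized by the marginal 90-day favorable rate
#' per arm and the conditional 6-week favorable rates given the 90-day
#' outcome, so the predictive value of the early endpoint is directly
#' tunable.  Accrual is a homogeneous Poisson process.
#'
#' Default rates are the design values of the motivating stroke
#' glycemic-control trial (SHINE): 25\% favorable on control, 32\% on
#' treatment, maximum 1400 patients.  The default accrual rate of 0.55
#' patients/day is calibrated so that at the 500-patient interim roughly
#' 85--90\% of enrolled patients have completed 90-day follow-up, matching
#' the information pattern observed at that trial's first Goldilocks-style
#' look.  The default conditionals (0.85 / 0.15) give a strongly but not
#' perfectly predictive 6-week endpoint.
#'
#' @param p90_treatment,p90_control Marginal probability of a favorable
#'   90-day outcome in each arm.
#' @param q6_given_90 Probability of a favorable 6-week outcome given the
#'   90-day outcome is favorable.
#' @param q6_given_not90 Probability of a favorable 6-week outcome given the
#'   90-day outcome is unfavorable.  Must not exceed `q6_given_90` (the early
#'   endpoint is positively associated with the final one).
#' @param accrual_rate Poisson accrual intensity, patients per day.
#' @param n_max Total number of patients randomized.
#' @param missing_prob Probability that each of the 6-week and 90-day
#'   outcomes is independently missing at its assessment (default 0: every
#'   randomized patient eventually yields both outcomes).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return An object of class `generator_params` (a named list).
#' @export
generator_params <- function(p90_treatment = 0.32, p90_control = 0.25,
                             q6_given_90 = 0.85, q6_given_not90 = 0.15,
                             accrual_rate = 0.55, n_max = 1400L,
                             missing_prob = 0, seed = 1L) {
  assert_scalar_prob(p90_treatment, "p90_treatment")
  assert_scalar_prob(p90_control, "p90_control")
  assert_scalar_prob(q6_given_90, "q6_given_90")
  assert_scalar_prob(q6_given_not90, "q6_given_not90")
  assert_scalar_prob(missing_prob, "missing_prob")
  if (q6_given_not90 > q6_given_90) {
    stop("`q6_given_90` must be >= `q6_given_not90` (positive 6-week/90-day association)",
         call. = FALSE)
  }
  if (!is.numeric(accrual_rate) || length(accrual_rate) != 1L ||
      !is.finite(accrual_rate) || accrual_rate <= 0) {
    stop("`accrual_rate` must be a single positive number", call. = FALSE)
  }
  n_max <- assert_count(n_max, "n_max")
  if (n_max < 1L) stop("`n_max` must be >= 1", call. = FALSE)
  seed <- assert_count(abs(seed), "seed") * sign(seed)
  structure(list(p90_treatment = p90_treatment, p90_control = p90_control,
                 q6_given_90 = q6_given_90, q6_given_not90 = q6_given_not90,
                 accrual_rate = accrual_rate, n_max = n_max,
                 missing_prob = missing_prob, seed = as.integer(seed)),
            class = "generator_params")
}

#' Generate a seeded patient-level trial dataset
#'
#' Simulates `n_max` patients: enrollment times are the arrival times of a
#' Poisson process at `accrual_rate`; arms are assigned 1:1 by permuted
#' blocks of 4; each patient's 90-day outcome is Bernoulli with the arm's
#' marginal rate and the 6-week outcome is then drawn from the conditional
#' given the 90-day outcome.  Assessment times are enrollment + 42 days
#' (6 weeks) and enrollment + 90 days.
#'
#' The returned data frame holds the *eventual* outcomes of every patient;
#' use [snapshot_at()] to obtain the censored view available at an interim.
#'
#' @param params A [generator_params()] object.
#' @return A `data.frame` of class `trial_data` with columns `patient_id`,
#'   `arm`, `enroll_time`, `t6`, `y6`, `t90`, `y90` (times in days; outcomes
#'   0/1 with `NA` for never-available outcomes).
#' @export
generate_trial <- function(params) {
  if (!inherits(params, "generator_params")) {
    params <- do.call(generator_params, as.list(params))
  }
  n <- params$n_max
  with_seed(params$seed, {
    enroll <- cumsum(stats::rexp(n, rate = params$accrual_rate))
    n_blocks <- ceiling(n / 4)
    arm_codes <- unlist(lapply(seq_len(n_blocks), function(i) {
      sample(c(1L, 1L, 0L, 0L))
    }))[seq_len(n)]
    arm <- ifelse(arm_codes == 1L, "treatment", "control")
    p90 <- ifelse(arm_codes == 1L, params$p90_treatment, params$p90_control)
    y90 <- stats::rbinom(n, 1L, p90)
    q6 <- ifelse(y90 == 1L, params$q6_given_90, params$q6_given_not90)
    y6 <- stats::rbinom(n, 1L, q6)
    if (params$missing_prob > 0) {
      y6[stats::runif(n) < params$missing_prob] <- NA_integer_
      y90[stats::runif(n) < params$missing_prob] <- NA_integer_
    }
    out <- data.frame(patient_id = seq_len(n), arm = arm,
                      enroll_time = enroll, t6 = enroll + 42,
                      y6 = y6, t90 = enroll + 90, y90 = y90,
                      stringsAsFactors = FALSE)
    class(out) <- c("trial_data", "data.frame")
    out
  })
}

#' Interim snapshot of a trial dataset
#'
#' Restricts the dataset to the first `milestone` randomized patients and
#' masks every outcome whose assessment time lies beyond the snapshot time,
#' reproducing the information set a monitoring committee would have seen.
#' By default the snapshot time is the enrollment time of the milestone-th
#' patient (interims timed by the number randomized); it can be overridden,
#' e.g. `time = Inf` for complete follow-up of the included patients.
#'
#' @param dataset A `trial_data` data frame (see [generate_trial()]).
#' @param milestone Number of randomized patients included, between 1 and
#'   `nrow(dataset)`.
#' @param time Optional snapshot calendar time (days); defaults to the
#'   enrollment time of the milestone-th patient.
#' @return An object of class `trial_snapshot`: a list with `snapshot_time`,
#'   `records` (masked patient rows), `n_enrolled` and `n_complete90`.
#' @export
snapshot_at <- function(dataset, milestone, time = NULL) {
  validate_trial_data(dataset)
  milestone <- assert_count(milestone, "milestone")
  if (milestone < 1L || milestone > nrow(dataset)) {
    stop(sprintf("`milestone` must be between 1 and %d", nrow(dataset)), call. = FALSE)
  }
  rec <- dataset[seq_len(milestone), , drop = FALSE]
  snap_time <- if (is.null(time)) rec$enroll_time[milestone] else time
  rec$y6[rec$t6 > snap_time] <- NA_integer_
  rec$y90[rec$t90 > snap_time] <- NA_integer_
  structure(list(snapshot_time = snap_time, records = rec,
                 n_enrolled = milestone,
                 n_complete90 = sum(!is.na(rec$y90))),
            class = "trial_snapshot")
}

#' @export
print.trial_snapshot <- function(x, ...) {
  cat(sprintf("Trial snapshot at day %.1f: %d enrolled, %d with 90-day outcome, %d with 6-week outcome\n",
              x$snapshot_time, x$n_enrolled, x$n_complete90,
              sum(!is.na(x$records$y6))))
  invisible(x)
}

#' Read and write patient-level trial datasets
#'
#' CSV schema: columns `patient_id,arm,enroll_time,t6,y6,t90,y90`, header
#' required, empty fields for missing outcomes, times in days.
#'
#' @param dataset A `trial_data` data frame.
#' @param path File path.
#' @return `read_trial_csv()` returns a validated `trial_data` data frame;
#'   `write_trial_csv()` returns `path` invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  validate_trial_data(dataset)
  cols <- c("patient_id", "arm", "enroll_time", "t6", "y6", "t90", "y90")
  utils::write.csv(as.data.frame(dataset)[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trial_data(df)
  class(df) <- c("trial_data", "data.frame")
  df
}

#' Validate the patient-level trial schema
#'
#' Checks column presence and types, arm labels, outcome coding and
#' assessment-time consistency; malformed rows are reported by index.
#'
#' @param df A data frame in the trial CSV schema.
#' @return `df` invisibly; errors on schema violations.
#' @export
validate_trial_data <- function(df) {
  cols <- c("patient_id", "arm", "enroll_time", "t6", "y6", "t90", "y90")
  if (!is.data.frame(df)) stop("dataset must be a data frame", call. = FALSE)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("dataset is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_arm <- which(!df$arm %in% c("treatment", "control"))
  if (length(bad_arm)) {
    stop(sprintf("row %d: arm must be 'treatment' or 'control' (got '%s')",
                 bad_arm[1], df$arm[bad_arm[1]]), call. = FALSE)
  }
  for (v in c("y6", "y90")) {
    bad <- which(!(is.na(df[[v]]) | df[[v]] %in% c(0, 1)))
    if (length(bad)) {
      stop(sprintf("row %d: %s must be 0, 1 or missing", bad[1], v), call. = FALSE)
    }
  }
  bad_t <- which(!(is.finite(df$enroll_time) & is.finite(df$t6) & is.finite(df$t90) &
                     df$t6 > df$enroll_time & df$t90 > df$t6))
  if (length(bad_t)) {
    stop(sprintf("row %d: assessment times must satisfy enroll_time < t6 < t90",
                 bad_t[1]), call. = FALSE)
  }
  invisible(df)
}
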