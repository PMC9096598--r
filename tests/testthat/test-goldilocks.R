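test_that("the interim schedule runs every 100 patients from 500, excluding the maximum", {
  expect_equal(interim_schedule(goldilocks_config()), seq(500L, 1300L, 100L))
  expect_length(interim_schedule(goldilocks_config()), 9L)
  expect_equal(interim_schedule(goldilocks_config(first_interim = 1400L)), integer(0))
  expect_equal(interim_schedule(goldilocks_config(first_interim = 500L,
                                                  interim_step = 450L)),
               c(500L, 950L))
})

test_that("interim decisions follow the 99%/5% threshold rules", {
  cfg <- goldilocks_config()
  pp <- function(ppn, ppm) structure(list(pp_current = ppn, pp_max = ppm,
                                          n_draws = 1000L, seed = 1L),
                                     class = "predictive_result")
  expect_equal(interim_decide(pp(0.005, 0.211), cfg), "continue")
  expect_equal(interim_decide(pp(0.005, 0.020), cfg), "stop_futility")
  expect_equal(interim_decide(pp(0.995, 0.999), cfg), "stop_accrual_predicted_success")
  # success check precedes futility; boundary values do not trigger
  expect_equal(interim_decide(pp(0.99, 0.05), cfg), "continue")
})

test_that("the final analysis thresholds the posterior probability of superiority", {
  cfg <- goldilocks_config()
  # symmetric arms: posterior about 1/2, no success
  fa0 <- final_analysis(make_counts_trial(100, 400, 100, 400), cfg)
  expect_equal(fa0$posterior_superiority, 0.5, tolerance = 1e-6)
  expect_false(fa0$success)
  # overwhelming separation
  fa1 <- final_analysis(make_counts_trial(500, 700, 100, 700), cfg)
  expect_true(fa1$success)
  expect_gt(fa1$posterior_superiority, 0.9999)
  # the executed trial's final margin: treatment slightly behind, failure
  fa2 <- final_analysis(make_counts_trial(119, 581, 123, 570), cfg)
  expect_false(fa2$success)
  expect_lt(fa2$posterior_superiority, 0.5)
  # missing outcomes are the caller's problem
  d <- make_counts_trial(10, 40, 10, 40)
  d$y90[1] <- NA_integer_
  expect_error(final_analysis(d, cfg), "observed 90-day outcome")
})

test_that("an overwhelming effect stops accrual for predicted success at the first interim", {
  d <- generate_trial(generator_params(p90_treatment = 0.60, p90_control = 0.25,
                                       seed = 42))
  cfg <- goldilocks_config(n_draws = 1000L, seed = 42)
  r <- run_goldilocks(d, cfg)
  expect_equal(r$stop_reason, "predicted_success")
  expect_equal(r$n_enrolled_final, 500L)
  expect_true(r$success)
  expect_equal(nrow(r$decisions), 1L)
  expect_equal(r$decisions$action, "stop_accrual_predicted_success")
})

test_that("the decision log is reproducible bit for bit", {
  d <- generate_trial(generator_params(p90_treatment = 0.25, p90_control = 0.25,
                                       seed = 7))
  cfg <- goldilocks_config(n_draws = 500L, seed = 7)
  r1 <- run_goldilocks(d, cfg)
  r2 <- run_goldilocks(d, cfg)
  expect_identical(r1$decisions, r2$decisions)
  expect_identical(r1$final_posterior_superiority, r2$final_posterior_superiority)
})

test_that("futility stops are binding: no final analysis afterwards", {
  # symmetric null data stop for futility; the result carries no posterior
  found_futility <- FALSE
  for (s in 1:5) {
    d <- generate_trial(generator_params(p90_treatment = 0.25, p90_control = 0.25,
                                         seed = 700 + s))
    r <- run_goldilocks(d, goldilocks_config(n_draws = 500L, seed = 700 + s))
    if (r$stop_reason == "futility") {
      found_futility <- TRUE
      expect_false(r$success)
      expect_true(is.na(r$final_posterior_superiority))
      expect_equal(utils::tail(r$decisions$action, 1), "stop_futility")
      expect_equal(r$n_enrolled_final, utils::tail(r$decisions$milestone, 1))
      break
    }
  }
  expect_true(found_futility)
})

test_that("a null trial that never stops runs to the maximum and fails", {
  # with no interims the engine goes straight to the final analysis
  d <- generate_trial(generator_params(p90_treatment = 0.25, p90_control = 0.25,
                                       seed = 15, n_max = 600L))
  cfg <- goldilocks_config(first_interim = 600L, n_max = 600L, n_draws = 100L, seed = 15)
  r <- run_goldilocks(d, cfg)
  expect_equal(r$stop_reason, "max_enrollment")
  expect_equal(r$n_enrolled_final, 600L)
  expect_false(is.na(r$final_posterior_superiority))
})

test_that("interim margins like the published fourth look trigger the futility stop", {
  # 800 enrolled, 715 complete, 23.1% vs 22.8% favorable at 600 still to come:
  # the predictive probability of success at the maximum is below 5%
  snap <- plant_snapshot(x_obs_t = 82, n_obs_t = 357, x_obs_c = 82, n_obs_c = 358,
                         m1_t = 6, m0_t = 19, none_t = 18,
                         m1_c = 6, m0_c = 19, none_c = 17)
  expect_equal(snap$n_enrolled, 800L)
  expect_equal(snap$n_complete90, 715L)
  cfg <- goldilocks_config(n_draws = 4000L, seed = 12)
  pp <- predictive_probabilities(snap, cfg)
  expect_lt(pp$pp_current, 0.01)
  expect_lt(pp$pp_max, 0.05)
  expect_equal(interim_decide(pp, cfg), "stop_futility")
})

test_that("interim margins like the published first look continue the trial", {
  # 498 enrolled, 432 complete, 26.6% vs 24.6%: PPmax comfortably above 5%
  snap <- plant_snapshot(x_obs_t = 57, n_obs_t = 216, x_obs_c = 53, n_obs_c = 216,
                         m1_t = 4, m0_t = 13, none_t = 16,
                         m1_c = 4, m0_c = 13, none_c = 16)
  expect_equal(snap$n_enrolled, 498L)
  expect_equal(snap$n_complete90, 432L)
  cfg <- goldilocks_config(n_draws = 4000L, seed = 12)
  pp <- predictive_probabilities(snap, cfg)
  expect_lt(pp$pp_current, 0.01)
  expect_gt(pp$pp_max, 0.05)
  expect_equal(interim_decide(pp, cfg), "continue")
})

test_that("the futility decision at a matched final interim survives disabling the longitudinal model", {
  snap <- plant_snapshot(x_obs_t = 82, n_obs_t = 357, x_obs_c = 82, n_obs_c = 358,
                         m1_t = 6, m0_t = 19, none_t = 18,
                         m1_c = 6, m0_c = 19, none_c = 17)
  for (use_lm in c(TRUE, FALSE)) {
    cfg <- goldilocks_config(n_draws = 4000L, seed = 12, use_longitudinal = use_lm)
    pp <- predictive_probabilities(snap, cfg)
    expect_equal(interim_decide(pp, cfg), "stop_futility")
  }
})
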