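test_that("conjugate updates add counts to the prior", {
  expect_equal(posterior_from_counts(0, 0), beta_posterior(1, 1))
  expect_equal(posterior_from_counts(3, 1, beta_posterior(2, 2)), beta_posterior(5, 3))
  # final-analysis scale: 119 favorable of 581 -> posterior mean near 20.5%
  p <- posterior_from_counts(119, 462)
  expect_equal(p, beta_posterior(120, 463))
  expect_equal(p$a / (p$a + p$b), 120 / 583)
  expect_error(posterior_from_counts(-1, 0), "non-negative")
})

test_that("prob_superiority matches closed forms and is a proper probability", {
  # identical posteriors: exactly 1/2 by symmetry
  expect_equal(prob_superiority(beta_posterior(3, 7), beta_posterior(3, 7)), 0.5,
               tolerance = 1e-9)
  # P(X > Y), X ~ Beta(2,1), Y ~ Beta(1,2): int 2x(2x - x^2) dx = 5/6
  expect_equal(prob_superiority(beta_posterior(2, 1), beta_posterior(1, 2)), 5 / 6,
               tolerance = 1e-6)
  # observed treatment deficit: superiority below 1/2
  expect_lt(prob_superiority(beta_posterior(120, 463), beta_posterior(124, 448)), 0.5)
})

test_that("prob_superiority agrees with a Monte-Carlo oracle over a posterior grid", {
  grid <- list(c(2, 1, 1, 2), c(120, 463, 124, 448), c(30, 70, 25, 75),
               c(350, 380, 330, 400), c(5, 2, 2, 5), c(1, 1, 3, 3))
  n_mc <- 1e6
  set.seed(400)
  for (g in grid) {
    q <- prob_superiority(beta_posterior(g[1], g[2]), beta_posterior(g[3], g[4]))
    draws <- mean(rbeta(n_mc, g[1], g[2]) > rbeta(n_mc, g[3], g[4]))
    se <- sqrt(draws * (1 - draws) / n_mc)
    expect_lt(abs(q - draws), 3 * se + 1e-9)
  }
})

test_that("prob_superiority satisfies the complement identity", {
  set.seed(41)
  for (i in 1:20) {
    a <- beta_posterior(runif(1, 0.5, 500), runif(1, 0.5, 500))
    b <- beta_posterior(runif(1, 0.5, 500), runif(1, 0.5, 500))
    expect_equal(prob_superiority(a, b) + prob_superiority(b, a), 1,
                 tolerance = 1e-6)
  }
})

test_that("transition model counts doubly-observed patients per arm and state", {
  # treatment arm: 10 patients with y6 = 1 observed at 90 days, 8 favorable
  snap <- plant_snapshot(x_obs_t = 8, n_obs_t = 10, x_obs_c = 2, n_obs_c = 10,
                         q1 = 1, q0 = 0)
  m <- fit_transition_model(snap)
  expect_equal(m$treatment$cond1, beta_posterior(1 + 8, 1 + 0))
  expect_equal(m$treatment$cond0, beta_posterior(1 + 0, 1 + 2))
  expect_equal(m$treatment$marginal, beta_posterior(1 + 8, 1 + 2))
  expect_equal(m$control$cond1, beta_posterior(1 + 2, 1 + 0))
  expect_equal(m$control$marginal, beta_posterior(1 + 2, 1 + 8))
  # pooling merges the conditional counts but keeps arm-specific marginals
  mp <- fit_transition_model(snap, pooled = TRUE)
  expect_equal(mp$treatment$cond1, beta_posterior(1 + 10, 1 + 0))
  expect_equal(mp$treatment$cond1, mp$control$cond1)
  expect_equal(mp$treatment$marginal, m$treatment$marginal)
})

test_that("an empty snapshot returns the priors unchanged", {
  d <- make_trial(c("treatment", "control"), c(1L, 0L))
  snap <- snapshot_at(d, 2)  # no follow-up elapsed: everything masked
  m <- fit_transition_model(snap, prior = beta_posterior(2, 3))
  for (a in c("treatment", "control")) {
    expect_equal(m[[a]]$cond1, beta_posterior(2, 3))
    expect_equal(m[[a]]$cond0, beta_posterior(2, 3))
    expect_equal(m[[a]]$marginal, beta_posterior(2, 3))
  }
})

test_that("transition-model posteriors recover the generator conditionals", {
  p <- generator_params(p90_treatment = 0.25, p90_control = 0.25, n_max = 10000L,
                        seed = 77)
  d <- generate_trial(p)
  snap <- snapshot_at(d, nrow(d), time = max(d$t90) + 1)
  m <- fit_transition_model(snap)
  # truth: P(y90 = 1 | y6 = 1) = p q1 / (p q1 + (1 - p) q0)
  tr1 <- 0.25 * 0.85 / (0.25 * 0.85 + 0.75 * 0.15)
  tr0 <- 0.25 * 0.15 / (0.25 * 0.15 + 0.75 * 0.85)
  for (a in c("treatment", "control")) {
    n1 <- m[[a]]$cond1$a + m[[a]]$cond1$b - 2
    expect_lt(abs(m[[a]]$cond1$a / (m[[a]]$cond1$a + m[[a]]$cond1$b) - tr1),
              3 * sqrt(tr1 * (1 - tr1) / n1))
    n0 <- m[[a]]$cond0$a + m[[a]]$cond0$b - 2
    expect_lt(abs(m[[a]]$cond0$a / (m[[a]]$cond0$a + m[[a]]$cond0$b) - tr0),
              3 * sqrt(tr0 * (1 - tr0) / n0))
  }
})

test_that("imputation keeps observed outcomes and respects degenerate posteriors", {
  # fully observed snapshot: completion is the observed data
  d <- generate_trial(generator_params(seed = 8, n_max = 100L))
  snap <- snapshot_at(d, 100, time = Inf)
  m <- fit_transition_model(snap)
  expect_identical(impute_completion(snap, m), as.integer(d$y90))

  # near-degenerate conditional posterior: imputed y90 = 1 for y6 = 1 patients
  snap2 <- plant_snapshot(x_obs_t = 5, n_obs_t = 10, x_obs_c = 5, n_obs_c = 10,
                          m1_t = 20, m1_c = 20)
  m2 <- fit_transition_model(snap2)
  for (a in c("treatment", "control")) m2[[a]]$cond1 <- beta_posterior(1000, 0.001)
  set.seed(1)
  y <- impute_completion(snap2, m2)
  imp1 <- is.na(snap2$records$y90) & !is.na(snap2$records$y6) & snap2$records$y6 == 1
  expect_true(all(y[imp1] == 1L))
  expect_identical(y[!is.na(snap2$records$y90)],
                   as.integer(snap2$records$y90[!is.na(snap2$records$y90)]))
})

test_that("repeated completions average to the posterior-predictive mean", {
  snap <- plant_snapshot(x_obs_t = 30, n_obs_t = 100, x_obs_c = 30, n_obs_c = 100,
                         m1_t = 30, m0_t = 30, none_t = 40,
                         m1_c = 30, m0_c = 30, none_c = 40)
  m <- fit_transition_model(snap)
  miss_t <- is.na(snap$records$y90) & snap$records$arm == "treatment"
  # posterior-predictive mean of the imputed treatment-arm favorable count
  pm <- function(bp) bp$a / (bp$a + bp$b)
  expected <- 30 * pm(m$treatment$cond1) + 30 * pm(m$treatment$cond0) +
    40 * pm(m$treatment$marginal)
  set.seed(2)
  n_rep <- 3000
  tot <- replicate(n_rep, sum(impute_completion(snap, m)[miss_t]))
  # beta-binomial variance bound (conservative): use binomial + rate spread
  se <- sd(tot) / sqrt(n_rep)
  expect_lt(abs(mean(tot) - expected), 4 * se)
})

test_that("predictive probabilities collapse to an indicator on complete data", {
  cfg <- goldilocks_config(first_interim = 200L, n_max = 200L, n_draws = 500L, seed = 4)
  # clear separation: final posterior above threshold
  d_sep <- make_counts_trial(80, 100, 20, 100)
  snap <- snapshot_at(d_sep, 200, time = Inf)
  pp <- predictive_probabilities(snap, cfg)
  expect_equal(pp$pp_current, 1)
  expect_equal(pp$pp_max, 1)
  # symmetric data: never succeeds
  d_null <- make_counts_trial(30, 100, 30, 100)
  snap0 <- snapshot_at(d_null, 200, time = Inf)
  pp0 <- predictive_probabilities(snap0, cfg)
  expect_equal(pp0$pp_current, 0)
  expect_equal(pp0$pp_max, 0)
})

test_that("symmetric large snapshots give near-zero predictive probability of success", {
  d <- make_counts_trial(300, 1000, 300, 1000)
  snap <- snapshot_at(d, 2000, time = Inf)
  cfg <- goldilocks_config(n_max = 2000L, n_draws = 2000L, seed = 10)
  pp <- predictive_probabilities(snap, cfg)
  expect_lt(pp$pp_current, 0.01)
})

test_that("predictive probabilities are invariant to patient ordering", {
  d <- generate_trial(generator_params(seed = 31, n_max = 600L))
  snap <- snapshot_at(d, 600)
  cfg <- goldilocks_config(n_draws = 1000L, seed = 9)
  pp1 <- predictive_probabilities(snap, cfg)
  snap_perm <- snap
  set.seed(99)
  snap_perm$records <- snap_perm$records[sample(nrow(snap_perm$records)), ]
  pp2 <- predictive_probabilities(snap_perm, cfg)
  expect_equal(pp1$pp_current, pp2$pp_current)
  expect_equal(pp1$pp_max, pp2$pp_max)
})

test_that("raising the final success threshold never raises the predictive probabilities", {
  d <- generate_trial(generator_params(seed = 13, n_max = 700L))
  snap <- snapshot_at(d, 650)
  thresholds <- c(0.90, 0.95, 0.979, 0.995)
  pps <- lapply(thresholds, function(th) {
    cfg <- goldilocks_config(final_posterior_threshold = th, n_draws = 1500L, seed = 6)
    predictive_probabilities(snap, cfg)
  })
  ppn <- vapply(pps, `[[`, numeric(1), "pp_current")
  ppm <- vapply(pps, `[[`, numeric(1), "pp_max")
  expect_true(all(diff(ppn) <= 0))
  expect_true(all(diff(ppm) <= 0))
})
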