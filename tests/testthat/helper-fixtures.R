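# Fixture builders shared across test files.  All fixtures are constructed
# in code; nothing is read from disk.

# Patient-level dataset with outcomes planted directly.  Enrollment is one
# patient per `gap` days, so assessment times are fully under test control.
make_trial <- function(arm, y90, y6 = y90, gap = 1) {
  n <- length(arm)
  enroll <- cumsum(rep(gap, n))
  out <- data.frame(patient_id = seq_len(n), arm = arm, enroll_time = enroll,
                    t6 = enroll + 42, y6 = y6, t90 = enroll + 90, y90 = y90,
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_data", "data.frame")
  out
}

# Dataset from per-arm favorable counts (row order is immaterial to the
# final analysis; use generate_trial() when interim structure matters).
make_counts_trial <- function(x_t, n_t, x_c, n_c, gap = 1) {
  arm <- c(rep("treatment", n_t), rep("control", n_c))
  y <- c(rep(1L, x_t), rep(0L, n_t - x_t), rep(1L, x_c), rep(0L, n_c - x_c))
  make_trial(arm, y, gap = gap)
}

# Snapshot with specified interim margins: per arm, `x_obs` favorable of
# `n_obs` patients with observed 90-day outcome, `m1`/`m0` patients with
# only a favorable/unfavorable 6-week outcome, `m_none` with neither.
# Completed patients' 6-week outcomes follow the given conditional rates so
# the transition model sees a realistic association.
plant_snapshot <- function(x_obs_t, n_obs_t, x_obs_c, n_obs_c,
                           m1_t = 0, m0_t = 0, none_t = 0,
                           m1_c = 0, m0_c = 0, none_c = 0,
                           q1 = 0.85, q0 = 0.15) {
  snap_time <- 10000
  build_arm <- function(a, x_obs, n_obs, m1, m0, m_none) {
    y90 <- c(rep(1L, x_obs), rep(0L, n_obs - x_obs))
    y6 <- integer(n_obs)
    y6[seq_len(x_obs)] <- rep(c(1L, 0L), times = c(round(q1 * x_obs), x_obs - round(q1 * x_obs)))
    n0 <- n_obs - x_obs
    y6[x_obs + seq_len(n0)] <- rep(c(1L, 0L), times = c(round(q0 * n0), n0 - round(q0 * n0)))
    comp <- data.frame(arm = rep(a, n_obs), enroll = seq_len(n_obs) * 1e-3,
                       y6 = y6, y90 = y90)
    part <- data.frame(arm = rep(a, m1 + m0),
                       enroll = snap_time - 89 + seq_len(m1 + m0) * 1e-3,
                       y6 = c(rep(1L, m1), rep(0L, m0)),
                       y90 = rep(0L, m1 + m0))
    fresh <- data.frame(arm = rep(a, m_none),
                        enroll = snap_time - 10 + seq_len(m_none) * 1e-3,
                        y6 = rep(0L, m_none), y90 = rep(0L, m_none))
    rbind(comp, part, fresh)
  }
  d <- rbind(build_arm("treatment", x_obs_t, n_obs_t, m1_t, m0_t, none_t),
             build_arm("control", x_obs_c, n_obs_c, m1_c, m0_c, none_c))
  d <- d[order(d$enroll), ]
  ds <- data.frame(patient_id = seq_len(nrow(d)), arm = d$arm, enroll_time = d$enroll,
                   t6 = d$enroll + 42, y6 = d$y6, t90 = d$enroll + 90, y90 = d$y90,
                   stringsAsFactors = FALSE)
  class(ds) <- c("trial_data", "data.frame")
  snapshot_at(ds, nrow(ds), time = snap_time)
}
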