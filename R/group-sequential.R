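#' Gamma-family (Hwang-Shih-DeCani) error-spending function
#'
#' Cumulative error spent by information fraction `t`:
#' \deqn{\alpha (1 - e^{-\gamma t}) / (1 - e^{-\gamma}).}
#' Strongly negative `gamma` spends late and approximates an
#' O'Brien-Fleming boundary; positive `gamma` spends early (Pocock-like).
#'
#' @param alpha Total error to spend.
#' @param gamma Shape parameter (nonzero).
#' @param t Information fraction(s) in \[0, 1\].
#' @return Cumulative spent error at each `t`.
#' @export
gamma_spending <- function(alpha, gamma, t) {
  assert_scalar_prob(alpha, "alpha")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma == 0) {
    stop("`gamma` must be a single nonzero finite number", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1)) {
    stop("`t` must lie in [0, 1]", call. = FALSE)
  }
  alpha * (1 - exp(-gamma * t)) / (1 - exp(-gamma))
}

# Drift of the canonical sequential z process at full information, for a
# two-arm comparison of proportions with an unpooled variance z statistic.
.design_drift <- function(p_control, p_treatment, n_final) {
  n_arm <- n_final / 2
  (p_treatment - p_control) /
    sqrt(p_treatment * (1 - p_treatment) / n_arm + p_control * (1 - p_control) / n_arm)
}

# ---- recursive numerical integration over the canonical joint law ----
# Sequential z statistics at information fractions t have correlation
# sqrt(t_j / t_k); crossing probabilities are computed by the standard
# grid recursion on the sub-density of the still-running process
# (Armitage-McPherson-Rowe), with Simpson weights.  First-look quantities
# use the exact normal cdf.  Transition kernels depend only on (t, delta,
# grid), so a workspace caches them across repeated boundary solves (e.g.
# during spending-shape calibration).

.gs_workspace <- function(t, delta = 0, h = 0.01, zmax = 8.5) {
  lo <- -zmax
  hi <- zmax + max(0, delta)
  npts <- ceiling((hi - lo) / h)
  if (npts %% 2L == 1L) npts <- npts + 1L
  z <- seq(lo, hi, length.out = npts + 1L)
  hh <- z[2L] - z[1L]
  w <- rep(c(2, 4), length.out = npts + 1L)
  w[1L] <- 1; w[npts + 1L] <- 1
  w <- w * hh / 3
  K <- length(t)
  kernels <- vector("list", K)
  if (K > 1L) {
    for (k in 2:K) {
      s <- sqrt((t[k] - t[k - 1]) / t[k])
      m <- z * sqrt(t[k - 1] / t[k]) + delta * (t[k] - t[k - 1]) / sqrt(t[k])
      kernels[[k]] <- outer(z, m, function(zo, mi) stats::dnorm((zo - mi) / s) / s)
    }
  }
  list(t = t, delta = delta, z = z, w = w, kernels = kernels)
}

.ws_cache_get <- function(t, delta) {
  key <- paste0("gsws|", paste(signif(t, 12), collapse = ","), "|", signif(delta, 12))
  ws <- .adaptsim_env[[key]]
  if (is.null(ws)) {
    ws <- .gs_workspace(t, delta)
    .adaptsim_env[[key]] <- ws
  }
  ws
}

# Cumulative integral of a grid function, as a smooth interpolator.
.cumfun <- function(z, f) {
  cf <- c(0, cumsum((f[-1L] + f[-length(f)]) / 2 * diff(z)))
  stats::splinefun(z, cf, method = "monoH.FC")
}

# Solve for u with int_{|z|>u} h = target (grid sub-density h).
.solve_tail <- function(z, h, target) {
  F <- .cumfun(z, h)
  ftail <- function(u) (F(max(z)) - F(u)) + F(max(-u, min(z)))
  if (target <= ftail(max(abs(z)))) return(Inf)
  stats::uniroot(function(u) ftail(u) - target, c(0, max(abs(z))), tol = 1e-10)$root
}

# Solve for l with int_{|z|<=l} h = target.
.solve_central <- function(z, h, target) {
  if (target <= 0) return(0)
  F <- .cumfun(z, h)
  fcen <- function(l) F(min(l, max(z))) - F(max(-l, min(z)))
  if (target >= fcen(max(abs(z)))) {
    stop("futility spending increment exceeds available probability mass", call. = FALSE)
  }
  stats::uniroot(function(l) fcen(l) - target, c(0, max(abs(z))), tol = 1e-10)$root
}

# Symmetric two-sided efficacy bounds matching cumulative spending alpha_cum
# at information fractions t, under drift delta (0 for type I spending).
.solve_efficacy_bounds <- function(t, alpha_cum, delta = 0) {
  ws <- .ws_cache_get(t, delta)
  K <- length(t)
  incr <- diff(c(0, alpha_cum))
  if (any(incr < -1e-12)) stop("cumulative spending must be nondecreasing", call. = FALSE)
  u <- numeric(K)
  m1 <- delta * sqrt(t[1L])
  tail1 <- function(uu) stats::pnorm(uu, m1, lower.tail = FALSE) + stats::pnorm(-uu, m1)
  u[1L] <- if (incr[1L] <= tail1(40)) Inf else
    stats::uniroot(function(uu) tail1(uu) - incr[1L], c(0, 40), tol = 1e-12)$root
  if (K == 1L) return(u)
  h <- stats::dnorm(ws$z - m1)
  for (k in 2:K) {
    h <- h * (abs(ws$z) < u[k - 1L])
    h <- drop(ws$kernels[[k]] %*% (ws$w * h))
    u[k] <- .solve_tail(ws$z, h, incr[k])
  }
  u
}

# Inner futility bounds matching cumulative beta spending at the interim
# fractions t_fut (a leading subset of t), under drift delta, with efficacy
# bounds u in place.
.solve_futility_bounds <- function(t, u, beta_cum, delta) {
  ws <- .ws_cache_get(t, delta)
  Kf <- length(beta_cum)
  incr <- diff(c(0, beta_cum))
  l <- numeric(Kf)
  m1 <- delta * sqrt(t[1L])
  cen1 <- function(ll) stats::pnorm(ll, m1) - stats::pnorm(-ll, m1)
  l[1L] <- if (incr[1L] <= 0) 0 else
    stats::uniroot(function(ll) cen1(ll) - incr[1L], c(0, 40), tol = 1e-12)$root
  if (Kf >= 2L) {
    h <- stats::dnorm(ws$z - m1)
    for (k in 2:Kf) {
      h <- h * (abs(ws$z) < u[k - 1L] & abs(ws$z) > l[k - 1L])
      h <- drop(ws$kernels[[k]] %*% (ws$w * h))
      l[k] <- .solve_central(ws$z, h, incr[k])
    }
  }
  if (any(l >= u[seq_len(Kf)])) {
    stop("futility bound crossed the efficacy bound; spending shapes are incompatible",
         call. = FALSE)
  }
  l
}

#' Per-look boundary crossing probabilities
#'
#' Computes, by the canonical-joint-distribution recursion, the incremental
#' probability of first crossing the two-sided efficacy bound (and, if
#' supplied, the inner futility bound, treated as binding) at each look.
#'
#' @param t Information fractions (increasing, in (0, 1\]).
#' @param z_efficacy Two-sided efficacy z bounds, one per look.
#' @param z_futility Optional inner futility z bounds (recycled with `NA`
#'   for looks without a futility bound, e.g. the final analysis).
#' @param delta Drift of the z process at full information (0 under the
#'   null).
#' @return A data frame with columns `look`, `t`, `p_cross_efficacy`,
#'   `p_cross_futility` (incremental first-crossing probabilities).
#' @export
gs_crossing_probs <- function(t, z_efficacy, z_futility = NULL, delta = 0) {
  K <- length(t)
  stopifnot(length(z_efficacy) == K)
  if (is.null(z_futility)) z_futility <- rep(NA_real_, K)
  z_futility <- rep_len(z_futility, K)
  ws <- .ws_cache_get(t, delta)
  p_eff <- p_fut <- numeric(K)
  m1 <- delta * sqrt(t[1L])
  h <- NULL
  for (k in seq_len(K)) {
    u <- z_efficacy[k]
    l <- if (is.na(z_futility[k])) 0 else z_futility[k]
    if (k == 1L) {
      p_eff[k] <- stats::pnorm(u, m1, lower.tail = FALSE) + stats::pnorm(-u, m1)
      p_fut[k] <- if (l > 0) stats::pnorm(l, m1) - stats::pnorm(-l, m1) else 0
      h <- stats::dnorm(ws$z - m1) * (abs(ws$z) < u & abs(ws$z) >= l)
    } else {
      h <- drop(ws$kernels[[k]] %*% (ws$w * h))
      F <- .cumfun(ws$z, h)
      zm <- max(ws$z); zl <- min(ws$z)
      p_eff[k] <- (F(zm) - F(min(u, zm))) + F(max(-u, zl))
      p_fut[k] <- if (l > 0) F(min(l, zm)) - F(max(-l, zl)) else 0
      h <- h * (abs(ws$z) < u & abs(ws$z) >= l)
    }
  }
  data.frame(look = seq_len(K), t = t, p_cross_efficacy = p_eff,
             p_cross_futility = p_fut)
}

#' Configuration of the group-sequential comparator design
#'
#' Defaults mirror the executed frequentist trial: interim analyses when
#' 500, 700, 900 and 1100 consecutively randomized patients have completed
#' 90-day follow-up, a final analysis at 1400, total two-sided type I error
#' 5\%, 80\% power for an improvement from 25\% to 32\% favorable, and
#' Gamma-family (Hwang-Shih-DeCani) spending for both the efficacy and the
#' (nonbinding) futility boundary.  The published design did not print its
#' spending shape parameters; the defaults here are least-squares
#' calibrations of the spending recursion to the published per-look z
#' boundaries (see [calibrate_gamma_spending()]), and [shine_boundaries()]
#' can be supplied as `boundary_table` to bypass spending entirely.
#'
#' @param analysis_milestones Completer counts at the interim looks.
#' @param n_final Maximum (final-analysis) sample size.
#' @param alpha_total Total two-sided type I error.
#' @param power Design power (1 - total futility/beta spending).
#' @param p_control,p_treatment Design favorable rates, used for the drift
#'   under which futility (beta) spending is computed.
#' @param gamma_efficacy,gamma_futility Spending shape parameters.
#' @param futility_binding Is a futility crossing binding?  The executed
#'   trial's was not; operating-characteristic simulation treats it as
#'   binding (see [simulate_ocs()]).
#' @param boundary_table Optional externally supplied boundaries: a data
#'   frame with columns `look`, `t`, `z_efficacy`, `z_futility` for the
#'   interim looks (the final bound is completed from the residual spent
#'   error).
#' @return An object of class `gs_config`.
#' @export
gs_config <- function(analysis_milestones = c(500L, 700L, 900L, 1100L),
                      n_final = 1400L, alpha_total = 0.05, power = 0.80,
                      p_control = 0.25, p_treatment = 0.32,
                      gamma_efficacy = -3.995, gamma_futility = -4.202,
                      futility_binding = FALSE, boundary_table = NULL) {
  if (any(diff(analysis_milestones) <= 0) || any(analysis_milestones >= n_final)) {
    stop("`analysis_milestones` must be strictly increasing and below `n_final`",
         call. = FALSE)
  }
  assert_scalar_prob(alpha_total, "alpha_total")
  assert_scalar_prob(power, "power")
  structure(list(analysis_milestones = as.integer(analysis_milestones),
                 n_final = assert_count(n_final, "n_final"),
                 alpha_total = alpha_total, power = power,
                 p_control = p_control, p_treatment = p_treatment,
                 gamma_efficacy = gamma_efficacy, gamma_futility = gamma_futility,
                 futility_binding = isTRUE(futility_binding),
                 boundary_table = boundary_table),
            class = "gs_config")
}

#' Published boundary table of the executed trial
#'
#' The per-look two-sided efficacy and (nonbinding) inner futility z
#' boundaries of the executed group-sequential stroke glycemic-control
#' trial, at its four interim looks (500, 700, 900, 1100 completers of a
#' 1400 maximum).  Supplied as a ready-made `boundary_table` for
#' [gs_config()], so operating characteristics can be reproduced without
#' knowing the unpublished spending shape parameters.
#'
#' @return A data frame with columns `look`, `n_complete`, `t`,
#'   `z_efficacy`, `z_futility`.
#' @export
shine_boundaries <- function() {
  data.frame(look = 1:4, n_complete = c(500L, 700L, 900L, 1100L),
             t = c(500, 700, 900, 1100) / 1400,
             z_efficacy = c(2.97, 2.86, 2.65, 2.42),
             z_futility = c(0.06, 0.13, 0.45, 1.05))
}

#' Compute group-sequential boundaries
#'
#' Either derives the per-look two-sided efficacy and inner futility z
#' boundaries from the configured Gamma-family spending functions (efficacy
#' spending under the null; futility/beta spending under the design
#' alternative's drift), or completes a supplied interim `boundary_table`
#' with the final-analysis bound.  In both cases the final bound is chosen
#' so that the total two-sided efficacy crossing probability under the null,
#' ignoring futility (the executed design's futility was nonbinding),
#' equals `alpha_total`.
#'
#' @param config A [gs_config()].
#' @return An object of class `gs_boundaries`: a data frame with one row
#'   per look (interims plus final) and columns `look`, `n_complete`, `t`,
#'   `z_efficacy`, `z_futility` (`NA` at the final look).
#' @export
boundaries_from_spending <- function(config) {
  stopifnot(inherits(config, "gs_config"))
  t_int <- config$analysis_milestones / config$n_final
  t_all <- c(t_int, 1)
  K <- length(t_all)
  delta <- .design_drift(config$p_control, config$p_treatment, config$n_final)
  if (!is.null(config$boundary_table)) {
    bt <- config$boundary_table
    u_int <- bt$z_efficacy
    l_int <- bt$z_futility
    spent <- sum(gs_crossing_probs(t_int, u_int, delta = 0)$p_cross_efficacy)
    resid <- config$alpha_total - spent
    if (resid <= 0) stop("interim boundaries already spend the full alpha", call. = FALSE)
    # residual spending at the final look, given the interim bounds
    alpha_cum <- c(cumsum(gs_crossing_probs(t_int, u_int, delta = 0)$p_cross_efficacy),
                   config$alpha_total)
    u <- .solve_efficacy_bounds(t_all, alpha_cum, delta = 0)
    u[seq_along(u_int)] <- u_int  # keep the printed values verbatim
  } else {
    alpha_cum <- gamma_spending(config$alpha_total, config$gamma_efficacy, t_all)
    u <- .solve_efficacy_bounds(t_all, alpha_cum, delta = 0)
    beta_cum <- gamma_spending(1 - config$power, config$gamma_futility, t_int)
    l_int <- .solve_futility_bounds(t_all, u, beta_cum, delta = delta)
  }
  out <- data.frame(look = seq_len(K),
                    n_complete = c(config$analysis_milestones, config$n_final),
                    t = t_all, z_efficacy = u,
                    z_futility = c(l_int, NA_real_))
  class(out) <- c("gs_boundaries", "data.frame")
  out
}

#' Calibrate Gamma-family spending shapes to a printed boundary table
#'
#' Least-squares fit of the Hwang-Shih-DeCani shape parameters so that the
#' spending recursion reproduces a set of published per-look z boundaries:
#' the efficacy shape is fitted to the efficacy bounds under the null, then
#' the futility shape to the inner futility bounds under the design drift
#' with the fitted efficacy bounds in place.
#'
#' @param boundary_table Interim boundary table (see [shine_boundaries()]).
#' @param config A [gs_config()] supplying the error rates, design rates
#'   and sample sizes.
#' @return A list with `gamma_efficacy`, `gamma_futility`, and the fitted
#'   per-look bounds.
#' @export
calibrate_gamma_spending <- function(boundary_table = shine_boundaries(),
                                     config = gs_config()) {
  t_int <- boundary_table$t
  t_all <- c(t_int, 1)
  k_int <- seq_along(t_int)
  eff_obj <- function(g) {
    u <- .solve_efficacy_bounds(t_all, gamma_spending(config$alpha_total, g, t_all))
    sum((u[k_int] - boundary_table$z_efficacy)^2)
  }
  ge <- stats::optimize(eff_obj, c(-15, -0.2), tol = 1e-4)$minimum
  u_fit <- .solve_efficacy_bounds(t_all, gamma_spending(config$alpha_total, ge, t_all))
  delta <- .design_drift(config$p_control, config$p_treatment, config$n_final)
  fut_obj <- function(g) {
    l <- tryCatch(.solve_futility_bounds(t_all, u_fit,
                                         gamma_spending(1 - config$power, g, t_int),
                                         delta = delta),
                  error = function(e) rep(10, length(t_int)))
    sum((l - boundary_table$z_futility)^2)
  }
  gf <- stats::optimize(fut_obj, c(-10, 3), tol = 1e-4)$minimum
  l_fit <- .solve_futility_bounds(t_all, u_fit,
                                  gamma_spending(1 - config$power, gf, t_int),
                                  delta = delta)
  list(gamma_efficacy = ge, gamma_futility = gf,
       z_efficacy = u_fit[k_int], z_futility = l_fit)
}

#' Interim decision of the group-sequential design
#'
#' @param z Observed z statistic at the look.
#' @param look Look index (into `bounds`).
#' @param bounds A [boundaries_from_spending()] object (or any data frame
#'   with `z_efficacy`, `z_futility` per look).
#' @param binding Convert a futility crossing into a mandatory stop?  When
#'   `FALSE` the crossing is reported as `"futility_signal"` and the caller
#'   decides whether to continue.
#' @return One of `"stop_efficacy"`, `"stop_futility"`,
#'   `"futility_signal"`, `"continue"`.
#' @export
gs_interim_decide <- function(z, look, bounds, binding = TRUE) {
  if (look < 1L || look > nrow(bounds)) stop("invalid look index", call. = FALSE)
  u <- bounds$z_efficacy[look]
  l <- bounds$z_futility[look]
  if (abs(z) >= u) return("stop_efficacy")
  if (!is.na(l) && abs(z) <= l) {
    return(if (binding) "stop_futility" else "futility_signal")
  }
  "continue"
}

#' Unpooled two-proportion z statistic
#'
#' Difference in proportions divided by the unpooled standard error;
#' positive when the treatment rate exceeds the control rate.  Defined as 0
#' when the two observed proportions are equal (including the degenerate
#' all-zero case).
#'
#' @param x_t,n_t Events and total on treatment.
#' @param x_c,n_c Events and total on control.
#' @return The z statistic.
#' @export
two_prop_z <- function(x_t, n_t, x_c, n_c) {
  if (n_t <= 0 || n_c <= 0) stop("arm totals must be positive", call. = FALSE)
  pt <- x_t / n_t; pc <- x_c / n_c
  if (pt == pc) return(0)
  se <- sqrt(pt * (1 - pt) / n_t + pc * (1 - pc) / n_c)
  (pt - pc) / se
}

#' Virtually execute the group-sequential design on a patient-level dataset
#'
#' At each completer milestone the analysis happens when the milestone-th
#' consecutively randomized patient reaches 90-day follow-up: the z
#' statistic is computed on those patients (complete cases), the boundary
#' rule applied, and the number enrolled by that calendar time recorded
#' (patients accrued while the milestone-th completer finished follow-up
#' are the overrun).  If no boundary stops the trial, the final analysis at
#' `n_final` uses the completed final bound.
#'
#' @param dataset A `trial_data` data frame.
#' @param config A [gs_config()].
#' @param stop_on_futility Stop when a futility bound is crossed?  Defaults
#'   to `config$futility_binding`; operating-characteristic simulation sets
#'   it to `TRUE`.
#' @param bounds Optional precomputed [boundaries_from_spending()] result
#'   (avoids re-solving the boundary recursion in simulation loops).
#' @return An object of class `gs_result`: list with `decisions` (per-look
#'   log), `stop_reason` (`"efficacy"`, `"futility"` or `"final"`),
#'   `n_enrolled_final`, `z_final`, `success` (two-sided efficacy
#'   significance at any look or at the final analysis).
#' @export
run_gs <- function(dataset, config, stop_on_futility = config$futility_binding,
                   bounds = NULL) {
  validate_trial_data(dataset)
  stopifnot(inherits(config, "gs_config"))
  n_avail <- nrow(dataset)
  if (n_avail < config$analysis_milestones[1L]) {
    stop("dataset too small to reach the first interim milestone", call. = FALSE)
  }
  if (is.null(bounds)) bounds <- boundaries_from_spending(config)
  mil <- config$analysis_milestones[config$analysis_milestones <= n_avail]
  rows <- list()
  stop_reason <- NA_character_
  n_enrolled_final <- NA_integer_
  z_final <- NA_real_
  success <- FALSE
  zstat <- function(d) {
    d <- d[!is.na(d$y90), , drop = FALSE]
    tt <- d$arm == "treatment"
    list(z = two_prop_z(sum(d$y90[tt]), sum(tt), sum(d$y90[!tt]), sum(!tt)),
         x_t = sum(d$y90[tt]), n_t = sum(tt),
         x_c = sum(d$y90[!tt]), n_c = sum(!tt))
  }
  for (k in seq_along(mil)) {
    m <- mil[k]
    analysis_time <- dataset$t90[m]
    d <- dataset[seq_len(m), , drop = FALSE]
    s <- zstat(d)
    n_enr <- sum(dataset$enroll_time <= analysis_time)
    action <- gs_interim_decide(s$z, k, bounds, binding = stop_on_futility)
    rows[[k]] <- data.frame(look = k, n_complete = m, n_enrolled = n_enr,
                            x_t = s$x_t, n_t = s$n_t, x_c = s$x_c, n_c = s$n_c,
                            z = s$z, action = action, stringsAsFactors = FALSE)
    if (action == "stop_efficacy") {
      stop_reason <- "efficacy"; success <- TRUE
      n_enrolled_final <- n_enr; z_final <- s$z
      break
    }
    if (action == "stop_futility") {
      stop_reason <- "futility"
      n_enrolled_final <- n_enr; z_final <- s$z
      break
    }
  }
  if (is.na(stop_reason)) {
    n_fin <- min(config$n_final, n_avail)
    s <- zstat(dataset[seq_len(n_fin), , drop = FALSE])
    u_final <- bounds$z_efficacy[nrow(bounds)]
    success <- abs(s$z) >= u_final
    stop_reason <- "final"
    n_enrolled_final <- n_fin
    z_final <- s$z
    rows[[length(rows) + 1L]] <- data.frame(
      look = nrow(bounds), n_complete = n_fin, n_enrolled = n_fin,
      x_t = s$x_t, n_t = s$n_t, x_c = s$x_c, n_c = s$n_c, z = s$z,
      action = if (success) "final_success" else "final_no_success",
      stringsAsFactors = FALSE)
  }
  structure(list(decisions = do.call(rbind, rows), stop_reason = stop_reason,
                 n_enrolled_final = as.integer(n_enrolled_final),
                 z_final = z_final, success = success, bounds = bounds),
            class = "gs_result")
}

#' @export
print.gs_result <- function(x, ...) {
  cat(sprintf("Group-sequential execution: %s at n = %d (z = %.3f); success = %s\n",
              x$stop_reason, x$n_enrolled_final, x$z_final, x$success))
  print(x$decisions, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simulate canonical sequential z paths through a boundary
#'
#' Draws correlated sequential z statistics (correlation
#' \eqn{\sqrt{t_j/t_k}}) at the boundary's information fractions under a
#' given drift, applies the two-sided efficacy and (binding) inner futility
#' bounds look by look, and tallies stopping.  A final row with an `NA`
#' futility bound is treated as the final analysis (efficacy only).
#'
#' @param bounds A [boundaries_from_spending()] object (or any data frame
#'   with `t`, `z_efficacy`, `z_futility`).
#' @param n_sims Number of simulated paths.
#' @param delta Drift at full information (0 under the null).
#' @param seed Seed.
#' @return A list with crossing fractions `p_futility`, `p_efficacy`,
#'   `p_no_stop` (reached the end without efficacy), the per-look stop
#'   table, and `n_sims`.
#' @export
simulate_gs_zpaths <- function(bounds, n_sims = 10000L, delta = 0, seed = 1L) {
  t <- bounds$t
  K <- length(t)
  with_seed(seed, {
    dt <- diff(c(0, t))
    incr <- matrix(stats::rnorm(n_sims * K, mean = rep(delta * dt, each = n_sims),
                                sd = rep(sqrt(dt), each = n_sims)),
                   nrow = n_sims)
    B <- t(apply(incr, 1L, cumsum))
    if (n_sims == 1L) B <- matrix(B, nrow = 1L)
    Z <- sweep(B, 2L, sqrt(t), "/")
    state <- rep("running", n_sims)
    stop_look <- rep(NA_integer_, n_sims)
    for (k in seq_len(K)) {
      run <- state == "running"
      u <- bounds$z_efficacy[k]; l <- bounds$z_futility[k]
      eff <- run & abs(Z[, k]) >= u
      state[eff] <- "efficacy"; stop_look[eff] <- k
      if (!is.na(l)) {
        fut <- run & !eff & abs(Z[, k]) <= l
        state[fut] <- "futility"; stop_look[fut] <- k
      }
    }
    list(p_futility = mean(state == "futility"),
         p_efficacy = mean(state == "efficacy"),
         p_no_stop = mean(state == "running"),
         stop_table = table(factor(stop_look, levels = seq_len(K)),
                            factor(state, levels = c("efficacy", "futility"))),
         n_sims = n_sims)
  })
}
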