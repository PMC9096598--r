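#' Two-by-two event table for a two-arm comparison
#'
#' @param x_t,n_t Events and total on treatment.
#' @param x_c,n_c Events and total on control.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(x_t, n_t, x_c, n_c) {
  x_t <- assert_count(x_t, "x_t"); n_t <- assert_count(n_t, "n_t")
  x_c <- assert_count(x_c, "x_c"); n_c <- assert_count(n_c, "n_c")
  if (n_t <= 0L || n_c <= 0L) stop("arm totals must be positive", call. = FALSE)
  if (x_t > n_t || x_c > n_c) stop("events cannot exceed totals", call. = FALSE)
  structure(list(x_t = x_t, n_t = n_t, x_c = x_c, n_c = n_c), class = "two_by_two")
}

#' Unadjusted risk difference with Wald confidence interval
#'
#' Risk difference in percentage points, treatment minus control, with a
#' Wald interval using the unpooled standard error and the normal quantile
#' 1.959964 (95\% by default).  No continuity correction.  Values are kept
#' at full precision; [format()] and [print()] round half-away-from-zero to
#' one decimal, matching journal-table formatting.
#'
#' @param table A [two_by_two()].
#' @param level Confidence level.
#' @return An object of class `risk_difference` with elements `rd`,
#'   `ci_low`, `ci_high` (percentage points, full precision) and `level`.
#' @export
risk_difference <- function(table, level = 0.95) {
  stopifnot(inherits(table, "two_by_two"))
  assert_scalar_prob(level, "level")
  pt <- table$x_t / table$n_t
  pc <- table$x_c / table$n_c
  se <- sqrt(pt * (1 - pt) / table$n_t + pc * (1 - pc) / table$n_c)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  rd <- 100 * (pt - pc)
  structure(list(rd = rd, ci_low = rd - 100 * zq * se, ci_high = rd + 100 * zq * se,
                 level = level, table = table),
            class = "risk_difference")
}

#' @export
format.risk_difference <- function(x, ...) {
  sprintf("%.1f (%.1f to %.1f)", round_half_up(x$rd, 1),
          round_half_up(x$ci_low, 1), round_half_up(x$ci_high, 1))
}

#' @export
print.risk_difference <- function(x, ...) {
  cat(sprintf("Risk difference, %% (%d%% CI): %s\n", round(100 * x$level),
              format(x)))
  invisible(x)
}

#' Percentage at one decimal, rounded half-up
#'
#' @param events,total Non-negative counts, `total > 0`.
#' @return `100 * events / total` rounded half-away-from-zero to one
#'   decimal.
#' @export
proportion_report <- function(events, total) {
  events <- assert_count(events, "events")
  total <- assert_count(total, "total")
  if (total <= 0L) stop("`total` must be positive", call. = FALSE)
  if (events > total) stop("`events` cannot exceed `total`", call. = FALSE)
  round_half_up(100 * events / total, 1)
}

#' Outcome report at a design-based stopping point
#'
#' Restricts the dataset to the first `n_cut` randomized patients and
#' summarizes the primary outcome per arm — favorable counts and
#' percentages over the full arm denominators, missing counts — together
#' with the unadjusted risk difference and Wald 95\% CI.  Additional binary
#' safety/secondary endpoints can be appended as pre-tabulated
#' [two_by_two()] tables (named list), each reported with its own risk
#' difference.
#'
#' @param dataset A `trial_data` data frame.
#' @param n_cut Number of randomized patients included.
#' @param safety Optional named list of [two_by_two()] tables.
#' @return A data frame of class `snapshot_report`, one row per endpoint,
#'   with per-arm counts/percentages and the risk difference with CI (full
#'   precision in numeric columns, journal rounding in `formatted`).
#' @export
snapshot_report <- function(dataset, n_cut, safety = NULL) {
  validate_trial_data(dataset)
  n_cut <- assert_count(n_cut, "n_cut")
  if (n_cut > nrow(dataset)) stop("`n_cut` exceeds the dataset size", call. = FALSE)
  d <- dataset[seq_len(n_cut), , drop = FALSE]
  tt <- d$arm == "treatment"
  n_t <- sum(tt); n_c <- sum(!tt)
  x_t <- sum(d$y90[tt] == 1, na.rm = TRUE)
  x_c <- sum(d$y90[!tt] == 1, na.rm = TRUE)
  miss_t <- sum(is.na(d$y90[tt])); miss_c <- sum(is.na(d$y90[!tt]))
  row_of <- function(endpoint, tbl) {
    rdo <- risk_difference(tbl)
    data.frame(endpoint = endpoint,
               x_t = tbl$x_t, n_t = tbl$n_t, pct_t = proportion_report(tbl$x_t, tbl$n_t),
               x_c = tbl$x_c, n_c = tbl$n_c, pct_c = proportion_report(tbl$x_c, tbl$n_c),
               rd = rdo$rd, ci_low = rdo$ci_low, ci_high = rdo$ci_high,
               formatted = format(rdo), stringsAsFactors = FALSE)
  }
  rows <- list(row_of("favorable_90day", two_by_two(x_t, n_t, x_c, n_c)))
  for (nm in names(safety)) rows[[length(rows) + 1L]] <- row_of(nm, safety[[nm]])
  out <- do.call(rbind, rows)
  attr(out, "missing") <- data.frame(arm = c("treatment", "control"),
                                     n = c(n_t, n_c), missing = c(miss_t, miss_c),
                                     pct = c(proportion_report(miss_t, n_t),
                                             proportion_report(miss_c, n_c)))
  attr(out, "n_cut") <- n_cut
  class(out) <- c("snapshot_report", "data.frame")
  out
}

#' @export
print.snapshot_report <- function(x, ...) {
  cat(sprintf("Outcome report, first %d randomized patients\n", attr(x, "n_cut")))
  print(as.data.frame(x)[, c("endpoint", "x_t", "n_t", "pct_t", "x_c", "n_c",
                             "pct_c", "formatted")], row.names = FALSE)
  m <- attr(x, "missing")
  cat(sprintf("Missing 90-day outcome: treatment %d/%d (%.1f%%), control %d/%d (%.1f%%)\n",
              m$missing[1], m$n[1], m$pct[1], m$missing[2], m$n[2], m$pct[2]))
  invisible(x)
}
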