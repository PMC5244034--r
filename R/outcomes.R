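# Effect measures: depression-free years and QALYs by area under the curve.

#' Resolve a reported onset period to a day index
#'
#' Onset dating follows a life-chart convention: when the exact day is
#' known it is used; when only the week or month could be established, the
#' midpoint of that period is used - the 4th day of a 7-day week window and
#' day 15 of a month window.
#'
#' @param anchor_day first day of the reported period (day index from
#'   randomization).
#' @param granularity `"day"`, `"week"` or `"month"`.
#' @param horizon_days follow-up horizon; anchors outside it are invalid.
#' @return resolved day index.
#' @export
#' @examples
#' resolve_onset_day(100, "day")   # 100
#' resolve_onset_day(140, "week")  # 143
#' resolve_onset_day(180, "month") # 195
resolve_onset_day <- function(anchor_day,
                              granularity = c("day", "week", "month"),
                              horizon_days = DAYS_PER_YEAR) {
  granularity <- match.arg(granularity)
  if (any(anchor_day < 0) || any(anchor_day > horizon_days)) {
    stop("invalid report: anchor outside the follow-up horizon")
  }
  offset <- switch(granularity, day = 0, week = 3, month = 15)
  anchor_day + offset
}

#' Depression-free years from onset timing
#'
#' The fraction of the 365.25-day follow-up year spent free of major
#' depression: `min(onset_day, horizon) / 365.25`, with censored
#' participants (no onset) scoring exactly 1. An onset after 43 weeks (301
#' days) gives 0.824, displayed as 0.82.
#'
#' @param onset_day day of onset (NA = censored; vectorised).
#' @param horizon_days follow-up horizon (default 365.25 days).
#' @return depression-free years in `[0, 1]`.
#' @export
depression_free_years <- function(onset_day, horizon_days = DAYS_PER_YEAR) {
  if (any(onset_day < 0, na.rm = TRUE)) {
    stop("invalid record: negative onset day")
  }
  dfy <- pmin(onset_day, horizon_days) / horizon_days
  dfy[is.na(onset_day)] <- 1
  dfy
}

#' QALYs as the area under linearly interpolated utilities
#'
#' Trapezoid rule over the four assessment waves (baseline, 6 weeks, 6
#' months, 12 months). With wave times spanning exactly one year, a
#' constant utility of 1 yields a QALY of 1 (full health throughout the
#' trial year). No baseline adjustment is applied.
#'
#' @param utilities numeric vector (one trajectory) or matrix with one row
#'   per participant and one column per wave; must be complete
#'   (post-imputation).
#' @param times wave times in years since randomization.
#' @return QALY per trajectory (years).
#' @export
#' @examples
#' qaly_auc(c(0.74, 0.76, 0.78, 0.80)) # 0.7777
qaly_auc <- function(utilities,
                     times = c(0, 6 / WEEKS_PER_YEAR, 0.5, 1.0)) {
  if (is.null(dim(utilities))) utilities <- matrix(utilities, nrow = 1)
  if (ncol(utilities) != length(times)) {
    stop("utilities and wave times differ in length")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("wave times must be strictly increasing")
  }
  if (anyNA(utilities)) {
    stop("missing utility values: run imputation before computing QALYs")
  }
  dt <- diff(times)
  k <- length(times)
  mids <- (utilities[, -1, drop = FALSE] +
             utilities[, -k, drop = FALSE]) / 2
  as.numeric(mids %*% dt)
}

#' Arm-level summary of an effect measure
#'
#' Per-arm mean and SD of an effect plus the intervention-minus-control
#' difference with a pooled-variance two-sample t statistic and 95%
#' confidence interval (intention-to-treat, all participants).
#'
#' @param effect numeric per-participant effect values.
#' @param arm factor with levels `intervention`, `control`.
#' @param conf_level confidence level (default 0.95).
#' @return list with `by_arm` (data.frame of n/mean/sd), `difference`,
#'   `ci`, `t`, `df`, `p_value`.
#' @export
arm_effect_summary <- function(effect, arm, conf_level = 0.95) {
  stopifnot(length(effect) == length(arm))
  arm <- factor(arm, levels = c("intervention", "control"))
  n <- tapply(effect, arm, length)
  if (any(is.na(n)) || any(n < 2)) {
    stop("insufficient data: each arm needs at least 2 records")
  }
  m <- tapply(effect, arm, mean)
  s <- tapply(effect, arm, stats::sd)
  df <- sum(n) - 2
  sp2 <- ((n[1] - 1) * s[1]^2 + (n[2] - 1) * s[2]^2) / df
  se <- sqrt(sp2 * (1 / n[1] + 1 / n[2]))
  diff <- m[["intervention"]] - m[["control"]]
  tstat <- if (se == 0) 0 else diff / se
  crit <- stats::qt(1 - (1 - conf_level) / 2, df)
  list(
    by_arm = data.frame(arm = names(n), n = as.integer(n),
                        mean = as.numeric(m), sd = as.numeric(s)),
    difference = unname(diff),
    ci = unname(c(diff - crit * se, diff + crit * se)),
    t = unname(tstat),
    df = df,
    p_value = unname(2 * stats::pt(-abs(tstat), df))
  )
}
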