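# Incremental cost-effectiveness estimation with bootstrapped seemingly
# unrelated regressions, cost-effectiveness plane and acceptability curves.

#' Incremental cost and effect point estimates
#'
#' Differences of arm means (intervention minus control) of annual
#' per-participant costs under a perspective and of an effect measure.
#'
#' @param table output of [participant_analysis_table()].
#' @param perspective `"societal"` or `"health_care"`.
#' @param effect `"dfy"`, `"qaly_eq5d"` or `"qaly_sf6d"`.
#' @return list with `delta_cost`, `delta_effect` and per-arm means.
#' @export
incremental_estimates <- function(table,
                                  perspective = c("societal", "health_care"),
                                  effect = c("dfy", "qaly_eq5d",
                                             "qaly_sf6d")) {
  perspective <- match.arg(perspective)
  effect <- match.arg(effect)
  cost_col <- paste0("cost_", perspective)
  arm <- factor(table$arm, levels = c("intervention", "control"))
  if (any(tabulate(arm, 2) == 0)) {
    stop("insufficient data: both arms are required")
  }
  mc <- tapply(table[[cost_col]], arm, mean)
  me <- tapply(table[[effect]], arm, mean)
  list(delta_cost = unname(mc[["intervention"]] - mc[["control"]]),
       delta_effect = unname(me[["intervention"]] - me[["control"]]),
       mean_cost = mc, mean_effect = me)
}

# Closed-form two-equation FGLS core on the design [1, arm]. With
# identical regressors in both equations, feasible GLS coincides with
# per-equation OLS, so the treatment coefficients equal the arm
# difference in means; the cross-equation residual correlation is still
# estimated and reported.
sur_core <- function(cost, effect, arm01) {
  n <- length(arm01)
  n1 <- sum(arm01)
  n0 <- n - n1
  m1c <- sum(cost * arm01) / n1
  m0c <- sum(cost * (1 - arm01)) / n0
  m1e <- sum(effect * arm01) / n1
  m0e <- sum(effect * (1 - arm01)) / n0
  rc <- cost - ifelse(arm01 == 1, m1c, m0c)
  re <- effect - ifelse(arm01 == 1, m1e, m0e)
  scc <- sum(rc * rc) / n
  see <- sum(re * re) / n
  sce <- sum(rc * re) / n
  rho <- if (scc > 0 && see > 0) sce / sqrt(scc * see) else NA_real_
  list(delta_cost = m1c - m0c, delta_effect = m1e - m0e,
       intercept_cost = m0c, intercept_effect = m0e,
       residual_correlation = rho)
}

#' Seemingly unrelated regressions of cost and effect on treatment
#'
#' Joint two-equation system - cost on arm, effect on arm - estimated by
#' feasible generalized least squares, allowing correlated residuals
#' across the cost and effect equations. Because both equations share the
#' same regressors, the FGLS treatment coefficients coincide with the
#' per-equation difference in means; the cross-equation residual
#' correlation quantifies the dependence the bootstrap propagates.
#'
#' @param cost,effect per-participant annual cost and effect vectors.
#' @param arm factor/character with levels `intervention`, `control`, or a
#'   0/1 indicator for intervention.
#' @return list with class `sur_fit`: treatment coefficients
#'   (`delta_cost`, `delta_effect`), equation intercepts (control-arm
#'   means) and `residual_correlation`.
#' @export
fit_sur <- function(cost, effect, arm) {
  stopifnot(length(cost) == length(effect), length(cost) == length(arm))
  arm01 <- if (is.numeric(arm)) as.numeric(arm != 0)
           else as.numeric(arm == "intervention")
  if (length(unique(arm01)) < 2) {
    stop("design error: treatment indicator is constant")
  }
  if (anyNA(cost) || anyNA(effect)) {
    stop("cost and effect vectors must be complete")
  }
  structure(sur_core(cost, effect, arm01), class = "sur_fit")
}

#' Bootstrap the incremental cost-effect pair
#'
#' Resamples participants with replacement - stratified within arm so that
#' every replicate preserves the original arm sizes - and re-estimates
#' (delta effect, delta cost) by the SUR system on each replicate.
#'
#' @param table output of [participant_analysis_table()].
#' @param B number of bootstrap replicates (default 2500).
#' @param seed RNG seed; the replicate set is a pure function of
#'   `(table, B, seed)`.
#' @inheritParams incremental_estimates
#' @param stratified resample within arm (default) or over the pooled
#'   sample.
#' @return object of class `cea_bootstrap`: list with `replicates`
#'   (data.frame `delta_effect`, `delta_cost`), the point `estimate`,
#'   `B`, `seed`, `perspective`, `effect`, `stratified`.
#' @export
bootstrap_cea <- function(table, B = 2500, seed = 1L,
                          perspective = c("societal", "health_care"),
                          effect = c("dfy", "qaly_eq5d", "qaly_sf6d"),
                          stratified = TRUE) {
  perspective <- match.arg(perspective)
  effect <- match.arg(effect)
  if (B <= 0) stop("configuration error: B must be positive")
  cost <- table[[paste0("cost_", perspective)]]
  eff <- table[[effect]]
  arm01 <- as.numeric(table$arm == "intervention")
  if (length(unique(arm01)) < 2) {
    stop("design error: both arms are required")
  }
  point <- sur_core(cost, eff, arm01)
  i1 <- which(arm01 == 1)
  i0 <- which(arm01 == 0)
  n1 <- length(i1)
  n0 <- length(i0)
  n <- n1 + n0
  set.seed(substream_seed(seed, "bootstrap"))
  dC <- numeric(B)
  dE <- numeric(B)
  for (b in seq_len(B)) {
    idx <- if (stratified) {
      c(i1[sample.int(n1, n1, replace = TRUE)],
        i0[sample.int(n0, n0, replace = TRUE)])
    } else {
      sample.int(n, n, replace = TRUE)
    }
    a <- arm01[idx]
    if (length(unique(a)) < 2) { # pooled resample missed an arm: redraw
      b_ok <- FALSE
      while (!b_ok) {
        idx <- sample.int(n, n, replace = TRUE)
        a <- arm01[idx]
        b_ok <- length(unique(a)) == 2
      }
    }
    fit <- sur_core(cost[idx], eff[idx], a)
    dC[b] <- fit$delta_cost
    dE[b] <- fit$delta_effect
  }
  structure(list(
    replicates = data.frame(delta_effect = dE, delta_cost = dC),
    estimate = point, B = as.integer(B), seed = as.integer(seed),
    perspective = perspective, effect = effect, stratified = stratified
  ), class = "cea_bootstrap")
}

#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_effect`; undefined (NA) when the incremental effect
#' is zero. Display rounding is to whole euro.
#'
#' @param delta_cost,delta_effect incremental cost and effect.
#' @return the ratio, or NA when `delta_effect == 0`.
#' @export
#' @examples
#' icer(134, 0.12) # 1116.67 -> displays as 1117
icer <- function(delta_cost, delta_effect) {
  ifelse(delta_effect == 0, NA_real_, delta_cost / delta_effect)
}

#' Quadrant shares of a bootstrap cloud on the cost-effectiveness plane
#'
#' North-east: more effect at more cost; north-west: less effect at more
#' cost; south-east: more effect at lower (or equal) cost (dominance);
#' south-west: less effect at lower cost. Replicates with exactly zero
#' incremental effect are assigned east.
#'
#' @param dist a `cea_bootstrap` or a data.frame with `delta_effect`,
#'   `delta_cost`.
#' @return named numeric vector of shares (NE, NW, SE, SW) summing to 1.
#' @export
quadrant_shares <- function(dist) {
  r <- replicates_of(dist)
  if (!nrow(r)) stop("empty bootstrap distribution")
  east <- r$delta_effect >= 0
  north <- r$delta_cost > 0
  c(NE = mean(east & north), NW = mean(!east & north),
    SE = mean(east & !north), SW = mean(!east & !north))
}

replicates_of <- function(dist) {
  if (inherits(dist, "cea_bootstrap")) dist$replicates
  else as.data.frame(dist)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay ceiling `lambda`, the probability that the
#' intervention is cost-effective: the fraction of replicates with
#' positive net benefit `lambda * delta_effect - delta_cost`.
#'
#' @param dist a `cea_bootstrap` or replicate data.frame.
#' @param lambda_grid non-negative willingness-to-pay values (euro per
#'   effect unit); default 0 to 50,000 in steps of 50.
#' @return data.frame of class `ceac_curve` with columns `lambda`,
#'   `probability`.
#' @export
ceac <- function(dist, lambda_grid = seq(0, 50000, by = 50)) {
  if (any(lambda_grid < 0)) {
    stop("configuration error: willingness-to-pay must be non-negative")
  }
  r <- replicates_of(dist)
  if (!nrow(r)) stop("empty bootstrap distribution")
  prob <- vapply(lambda_grid, function(l) {
    mean(l * r$delta_effect - r$delta_cost > 0)
  }, numeric(1))
  structure(data.frame(lambda = lambda_grid, probability = prob),
            class = c("ceac_curve", "data.frame"))
}

#' Percentile confidence interval for the ICER by angular ordering
#'
#' Replicates are ordered by their angle about the origin of the
#' (delta effect, delta cost) plane and the interval spans the central
#' `1 - alpha` mass, each bound reported as the cost-to-effect ratio of
#' the replicate at the corresponding angular order statistic. When the
#' replicate cloud straddles zero incremental effect - operationalised as
#' the `alpha/2` and `1 - alpha/2` percentiles of the incremental effect
#' bracketing 0 - no ray through the origin excludes `alpha/2` of the
#' distribution on each side and the interval is undefined (both bounds
#' NA).
#'
#' @param dist a `cea_bootstrap` or replicate data.frame.
#' @param alpha two-sided error rate (default 0.05).
#' @return list with `lower`, `upper` (NA when undefined) and logical
#'   `defined`.
#' @export
icer_percentile_ci <- function(dist, alpha = 0.05) {
  r <- replicates_of(dist)
  if (!nrow(r)) stop("empty bootstrap distribution")
  qE <- stats::quantile(r$delta_effect, c(alpha / 2, 1 - alpha / 2),
                        names = FALSE, type = 1)
  if (qE[1] <= 0 && qE[2] >= 0) {
    return(list(lower = NA_real_, upper = NA_real_, defined = FALSE))
  }
  ang <- atan2(r$delta_cost, r$delta_effect)
  ord <- order(ang)
  B <- nrow(r)
  lo_i <- ord[max(1L, ceiling(B * alpha / 2))]
  hi_i <- ord[min(B, ceiling(B * (1 - alpha / 2)))]
  list(lower = r$delta_cost[lo_i] / r$delta_effect[lo_i],
       upper = r$delta_cost[hi_i] / r$delta_effect[hi_i],
       defined = TRUE)
}

#' Percentile confidence interval of a bootstrap margin
#'
#' Plain percentile interval for incremental cost or incremental effect.
#'
#' @param x numeric replicate vector.
#' @param alpha two-sided error rate.
#' @return length-2 numeric vector.
#' @export
percentile_ci <- function(x, alpha = 0.05) {
  stats::quantile(x, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
}
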