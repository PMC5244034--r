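# Shared helpers: seed streams, truncated normals, display rounding.

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' Every stochastic stage of the pipeline (onset sampling, resource-use
#' draws, utility trajectories, dropout, bootstrap) seeds its own RNG stream
#' from the master seed plus a fixed label, so stages are individually
#' reproducible and inserting a new stage does not perturb the others.
#'
#' @param seed master integer seed.
#' @param stream character label of the stream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid R integers
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

#' Truncated-normal draws with exact marginals via inverse CDF
#'
#' @param p probabilities in `[0,1]` (e.g. `pnorm` of a latent Gaussian, so
#'   cross-wave correlation survives the marginal transform).
#' @param mean,sd location and scale of the untruncated normal.
#' @param lower,upper truncation bounds.
#' @return quantiles of the truncated normal at `p`.
#' @keywords internal
qtruncnorm <- function(p, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  a <- stats::pnorm(lower, mean, sd)
  b <- stats::pnorm(upper, mean, sd)
  stats::qnorm(a + p * (b - a), mean, sd)
}

rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  qtruncnorm(stats::runif(n), mean, sd, lower, upper)
}

#' Mean of a truncated normal distribution
#' @keywords internal
truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Location that yields a requested truncated-normal mean
#'
#' Solves for the pre-truncation location so that after truncation to
#' `[lower, upper]` the expectation equals `target`. Used to calibrate
#' utility-trajectory generators whose index values are capped at 1.
#'
#' @keywords internal
truncnorm_location_for_mean <- function(target, sd, lower, upper) {
  stopifnot(target > lower, target < upper)
  stats::uniroot(function(m) truncnorm_mean(m, sd, lower, upper) - target,
                 interval = c(lower - 6 * sd, upper + 6 * sd),
                 tol = 1e-10)$root
}

#' Display rounding helpers matching the reporting conventions
#'
#' Costs and ICERs are shown in whole euro (or pound), effects with two
#' decimals, and percentages with one decimal; `pct()` reproduces ratios such
#' as 286/406 -> 70.4.
#'
#' @param x numeric value.
#' @param numer,denom numerator and denominator of a proportion.
#' @param digits decimals kept.
#' @return rounded numeric value.
#' @export
euro_round <- function(x) round(x)

#' @rdname euro_round
#' @export
effect_round <- function(x, digits = 2) round(x, digits)

#' @rdname euro_round
#' @export
pct <- function(numer, denom, digits = 1) round(100 * numer / denom, digits)
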