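# CEA engine: SUR identity, bootstrap, ICER, plane quadrants, CEAC,
# angular percentile intervals.

test_that("SUR treatment coefficients equal differences in means", {
  set.seed(61)
  for (i in 1:20) {
    n1 <- sample(5:60, 1)
    n0 <- sample(5:60, 1)
    cost <- c(rlnorm(n1, 6, 1), rlnorm(n0, 6.2, 0.8))
    eff <- c(rnorm(n1, 0.8, 0.2), rnorm(n0, 0.7, 0.2))
    arm <- rep(c("intervention", "control"), c(n1, n0))
    fit <- fit_sur(cost, eff, arm)
    expect_equal(fit$delta_cost,
                 mean(cost[1:n1]) - mean(cost[-(1:n1)]), tolerance = 1e-8)
    expect_equal(fit$delta_effect,
                 mean(eff[1:n1]) - mean(eff[-(1:n1)]), tolerance = 1e-8)
  }
  expect_error(fit_sur(1:4, 1:4, rep("control", 4)), "constant")
})

test_that("SUR residual correlation is estimated consistently", {
  set.seed(62)
  n <- 100000
  arm <- rep(c("intervention", "control"), each = n / 2)
  cost <- rnorm(n, ifelse(arm == "intervention", 100, 90), 10)
  eff <- rnorm(n, 0.5, 0.1) # independent of cost
  expect_lt(abs(fit_sur(cost, eff, arm)$residual_correlation), 0.01)
  # degenerate: effect identical to cost -> perfect residual correlation
  expect_equal(fit_sur(cost, cost, arm)$residual_correlation, 1,
               tolerance = 1e-12)
})

test_that("bootstrap is deterministic and degenerate on constant arms", {
  tab <- toy_cea_table(rep(500, 8), rep(400, 9), rep(0.8, 8), rep(0.7, 9))
  bt <- bootstrap_cea(tab, B = 25, seed = 3)
  expect_true(all(bt$replicates$delta_cost == 100))
  expect_true(all(bt$replicates$delta_effect == 0.8 - 0.7))
  bt2 <- bootstrap_cea(tab, B = 25, seed = 3)
  expect_identical(bt$replicates, bt2$replicates)
  bt3 <- bootstrap_cea(tab, B = 25, seed = 4)
  expect_identical(bt3$replicates, bt$replicates) # still zero-variance
  expect_error(bootstrap_cea(tab, B = 0), "positive")
})

test_that("bootstrap spread matches the analytic standard error", {
  set.seed(63)
  tab <- toy_cea_table(rnorm(200, 1000, 300), rnorm(200, 900, 250),
                       rnorm(200, 0.8, 0.15), rnorm(200, 0.7, 0.12))
  bt <- bootstrap_cea(tab, B = 5000, seed = 8)
  v <- function(x) var(x) * (length(x) - 1) / length(x)^2
  se_eff <- sqrt(v(tab$dfy[tab$arm == "intervention"]) +
                   v(tab$dfy[tab$arm == "control"]))
  se_cost <- sqrt(v(tab$cost_societal[tab$arm == "intervention"]) +
                    v(tab$cost_societal[tab$arm == "control"]))
  expect_equal(sd(bt$replicates$delta_effect), se_eff, tolerance = 0.05)
  expect_equal(sd(bt$replicates$delta_cost), se_cost, tolerance = 0.05)
})

test_that("ICER arithmetic and the zero-effect guard", {
  expect_equal(euro_round(icer(134, 0.12)), 1117)
  expect_equal(icer(0, 0.12), 0)
  expect_true(is.na(icer(134, 0)))
})

test_that("quadrant shares match hand counts and sum to one", {
  four <- data.frame(delta_effect = c(0.1, -0.1, 0.1, -0.1),
                     delta_cost = c(50, 50, -50, -50))
  expect_equal(quadrant_shares(four),
               c(NE = 0.25, NW = 0.25, SE = 0.25, SW = 0.25))
  dominant <- data.frame(delta_effect = rep(0.2, 5),
                         delta_cost = rep(-10, 5))
  expect_equal(quadrant_shares(dominant)[["SE"]], 1)
  set.seed(64)
  r <- data.frame(delta_effect = rnorm(20), delta_cost = rnorm(20))
  hand <- c(NE = sum(r$delta_effect >= 0 & r$delta_cost > 0),
            NW = sum(r$delta_effect < 0 & r$delta_cost > 0),
            SE = sum(r$delta_effect >= 0 & r$delta_cost <= 0),
            SW = sum(r$delta_effect < 0 & r$delta_cost <= 0)) / 20
  expect_equal(quadrant_shares(r), hand)
  expect_equal(sum(quadrant_shares(r)), 1)
})

test_that("CEAC equals net-benefit enumeration and endpoint identities", {
  one <- data.frame(delta_effect = 0.1, delta_cost = -50)
  expect_true(all(ceac(one, c(0, 100, 1e6))$probability == 1))
  two <- data.frame(delta_effect = c(0.1, 0.1), delta_cost = c(100, 300))
  # at lambda = 2000 the net benefits are +100 and -100
  expect_equal(ceac(two, 2000)$probability, 0.5)
  set.seed(65)
  r <- data.frame(delta_effect = rnorm(500, 0.05, 0.1),
                  delta_cost = rnorm(500, 50, 200))
  curve <- ceac(r, c(0, 500, 1e9))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  expect_equal(curve$probability[1], mean(r$delta_cost < 0))
  expect_equal(curve$probability[1],
               sum(quadrant_shares(r)[c("SE", "SW")]))
  expect_equal(curve$probability[3], mean(r$delta_effect > 0))
  # brute-force enumeration on a hand-listed replicate set
  small <- data.frame(delta_effect = c(0.2, -0.1, 0.05, 0.3, 0.0),
                      delta_cost = c(100, -50, 400, -20, 10))
  for (l in c(0, 1000, 5000)) {
    expect_equal(ceac(small, l)$probability,
                 mean(l * small$delta_effect - small$delta_cost > 0))
  }
  expect_error(ceac(small, -5), "non-negative")
})

test_that("ICER interval follows the angular ordering of the plane", {
  # replicates placed at known angles: sorted order is by construction
  ang <- sort(c(-60, -40, -20, -5, 5, 15, 25, 35, 45, 60, 70)) * pi / 180
  r <- data.frame(delta_effect = cos(ang), delta_cost = sin(ang))
  ci <- icer_percentile_ci(r, alpha = 0.05)
  expect_true(ci$defined)
  # ceiling(11 * 0.025) = 1st and ceiling(11 * 0.975) = 11th by angle
  expect_equal(ci$lower, tan(ang[1]), tolerance = 1e-12)
  expect_equal(ci$upper, tan(ang[11]), tolerance = 1e-12)

  # tight north-east cloud: interval contains the point ICER
  set.seed(66)
  ne <- data.frame(delta_effect = rnorm(2000, 0.12, 0.01),
                   delta_cost = rnorm(2000, 140, 10))
  ci_ne <- icer_percentile_ci(ne)
  expect_true(ci_ne$defined)
  point <- icer(mean(ne$delta_cost), mean(ne$delta_effect))
  expect_gt(point, ci_ne$lower)
  expect_lt(point, ci_ne$upper)

  # effect distribution symmetric about zero: no defining ray exists
  sym <- data.frame(delta_effect = rnorm(1000, 0, 0.05),
                    delta_cost = rnorm(1000, 100, 50))
  expect_false(icer_percentile_ci(sym)$defined)
})

test_that("incremental estimates reduce to arm mean differences", {
  tab <- toy_cea_table(c(300, 500), c(100, 300), c(0.9, 0.7), c(0.6, 0.8))
  inc <- incremental_estimates(tab, "societal", "dfy")
  expect_equal(inc$delta_cost, 400 - 200)
  expect_equal(inc$delta_effect, 0.8 - 0.7)
  same <- toy_cea_table(c(10, 20), c(10, 20), c(0.5, 0.6), c(0.5, 0.6))
  inc0 <- incremental_estimates(same, "health_care", "qaly_eq5d")
  expect_equal(inc0$delta_cost, 0)
  expect_equal(inc0$delta_effect, 0)
  # program-cost-only arms: constant 299 vs 10 gives delta 289
  prog <- toy_cea_table(rep(299, 4), rep(10, 4), rep(1, 4), rep(1, 4))
  expect_equal(incremental_estimates(prog, "societal", "dfy")$delta_cost, 289)
})
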