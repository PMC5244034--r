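# Synthetic cohort generator: determinism, calibration, missingness.

test_that("cohort generation is a pure function of config and seed", {
  cfg <- small_config(40)
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(a$participants, b$participants)
  expect_identical(a$waves, b$waves)
  c2 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a$participants, c2$participants))
  expect_equal(sum(a$participants$arm == "intervention"), 40)
  expect_equal(sum(a$participants$arm == "control"), 40)

  empty_int <- synthetic_trial_config(n_intervention = 0, n_control = 25)
  co <- generate_cohort(empty_int, seed = 1)
  expect_equal(sum(co$participants$arm == "intervention"), 0)
  expect_equal(nrow(co$participants), 25)
})

test_that("onset sampling matches the exponential restricted mean", {
  horizon_w <- 365.25 / 7
  set.seed(900)
  none <- sample_onset_days(500, hazard_per_week = 0)
  expect_true(all(!none$event))
  expect_true(all(is.na(none$onset_day)))

  lam <- 0.02
  set.seed(901)
  d <- sample_onset_days(100000, lam)
  weeks <- ifelse(d$event, d$onset_day, 365.25) / 7
  weeks <- pmin(weeks, horizon_w)
  expect_equal(mean(weeks), rmst_exponential(lam, horizon_w),
               tolerance = 0.01)
  expect_true(all(d$onset_day[d$event] >= 0 &
                    d$onset_day[d$event] <= 365.25))
  expect_error(sample_onset_days(10, -0.1), "non-negative")
})

test_that("default hazards reproduce 43 and 37 depression-free weeks", {
  cfg <- small_config()
  horizon_w <- 365.25 / 7
  expect_equal(rmst_exponential(cfg$onset_hazard_per_week[["intervention"]],
                                horizon_w), 43, tolerance = 1e-8)
  expect_equal(rmst_exponential(cfg$onset_hazard_per_week[["control"]],
                                horizon_w), 37, tolerance = 1e-8)
  set.seed(902)
  for (arm in c("intervention", "control")) {
    d <- sample_onset_days(50000, cfg$onset_hazard_per_week[[arm]])
    weeks <- pmin(ifelse(d$event, d$onset_day, 365.25), 365.25) / 7
    expect_equal(mean(weeks), cfg$target_mean_dfw[[arm]], tolerance = 0.005)
  }
})

test_that("two-part cost draws have the configured zero fraction and skew", {
  cfg <- small_config(4000)
  co <- generate_cohort(cfg, seed = 7)
  w3 <- co$waves[co$waves$wave == 3, ]
  arm <- co$participants$arm[match(w3$id, co$participants$id)]
  qp <- cfg$quantity_params
  for (f in c("gp_visits", "informal_care_hours", "psychotherapist_sessions")) {
    for (a in c("intervention", "control")) {
      p0 <- qp$p_zero[qp$field == f & qp$arm == a]
      frac <- mean(w3[[f]][arm == a] == 0)
      se <- sqrt(p0 * (1 - p0) / 4000)
      expect_lt(abs(frac - p0), 4 * se)
    }
  }
  quant_cols <- setdiff(prevcea:::panel_fields(), "efficiency_rating")
  expect_true(all(as.matrix(w3[quant_cols]) >= 0))
  expect_true(all(w3$efficiency_rating >= 0 & w3$efficiency_rating <= 10))
})

test_that("generated utilities respect instrument ranges and baseline mean", {
  cfg <- small_config(4000)
  co <- generate_cohort(cfg, seed = 8)
  w <- co$waves
  expect_true(all(w$utility_eq5d >= -0.594 & w$utility_eq5d <= 1))
  expect_true(all(w$utility_sf6d >= 0.30 & w$utility_sf6d <= 1))
  base <- w[w$wave == 1, ]
  arm <- co$participants$arm[match(base$id, co$participants$id)]
  for (a in c("intervention", "control")) {
    expect_equal(mean(base$utility_eq5d[arm == a]), 0.74, tolerance = 0.01)
  }
})

test_that("arm-level cost expectations match the calibration targets", {
  cfg <- small_config(10000)
  co <- generate_cohort(cfg, seed = 12)
  tab <- participant_analysis_table(co, impute = FALSE)
  # control-arm primary-care (GP + internist) annual mean near EUR 117
  ctr <- tab[tab$arm == "control", ]
  expect_equal(mean(ctr$gp_internist), 117, tolerance = 0.10 * 117)
  expect_equal(mean(ctr$informal_care), 384, tolerance = 0.10 * 384)
  int <- tab[tab$arm == "intervention", ]
  expect_equal(mean(int$absenteeism), 1475, tolerance = 0.10 * 1475)
})

test_that("missingness is monotone, MAR and hits configured retention", {
  cfg <- small_config(3000)
  co <- apply_missingness(generate_cohort(cfg, seed = 31), seed = 31)
  obs <- matrix(co$waves$observed[order(co$waves$id, co$waves$wave)],
                ncol = 4, byrow = TRUE)
  expect_true(all(obs[, 1]))
  expect_true(all(obs[, 2] >= obs[, 3]))
  expect_true(all(obs[, 3] >= obs[, 4]))
  # ~70% observed at 12 months, lower in the intervention arm
  w4 <- co$waves[co$waves$wave == 4, ]
  arm <- co$participants$arm[match(w4$id, co$participants$id)]
  expect_equal(mean(w4$observed), 0.704, tolerance = 0.03)
  expect_lt(mean(w4$observed[arm == "intervention"]),
            mean(w4$observed[arm == "control"]))

  no_drop <- apply_missingness(generate_cohort(small_config(50), seed = 2),
                               matrix(0, 3, 2), seed = 2)
  expect_true(all(no_drop$waves$observed))
})

test_that("dropout regression recovers the generating symptom coefficient", {
  cfg <- synthetic_trial_config(n_intervention = 25000, n_control = 25000)
  co <- apply_missingness(generate_cohort(cfg, seed = 55), seed = 55)
  p <- co$participants
  # rows in id order, matching the participants table
  obs <- matrix(co$waves$observed[order(co$waves$id, co$waves$wave)],
                ncol = 4, byrow = TRUE)
  # wave-3 dropout among those observed at wave 2 follows the generating
  # logistic model exactly
  at_risk <- obs[, 2]
  drop3 <- as.integer(!obs[, 3])[at_risk]
  fit <- glm(drop3 ~ p$symptom_z[at_risk], family = binomial())
  est <- coef(summary(fit))[2, ]
  expect_lt(abs(est["Estimate"] - cfg$dropout_symptom_beta),
            3 * est["Std. Error"])
})

test_that("cohort CSV round trip preserves the analysis", {
  cfg <- small_config(60)
  co <- apply_missingness(generate_cohort(cfg, seed = 77), seed = 77)
  stem <- file.path(withr::local_tempdir(), "cohort")
  write_cohort(co, stem)
  back <- read_cohort(stem)
  t1 <- participant_analysis_table(co)
  t2 <- participant_analysis_table(back)
  expect_equal(t1$cost_societal, t2$cost_societal, tolerance = 1e-12)
  expect_equal(t1$dfy, t2$dfy, tolerance = 1e-12)
  expect_equal(t1$qaly_eq5d, t2$qaly_eq5d, tolerance = 1e-12)
  expect_error(read_cohort(file.path(tempdir(), "nope")), "not found")
})
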