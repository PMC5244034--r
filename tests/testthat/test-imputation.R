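# Regression imputation: predictor screening, conditional-mean filling,
# hospitalization exclusion and bias reduction under MAR dropout.

test_that("predictor screening has the nominal false-retention rate", {
  set.seed(41)
  n <- 2000
  k <- 100
  frame <- as.data.frame(matrix(rnorm(n * k), n, k,
                                dimnames = list(NULL, paste0("x", 1:k))))
  frame$y <- rnorm(n)
  frame$y[sample(n, 300)] <- NA
  kept_out <- select_predictors(frame, paste0("x", 1:k), "y", "outcome")
  kept_drop <- select_predictors(frame, paste0("x", 1:k), "y", "dropout")
  # pure-noise candidates: ~5% spurious retention per candidate
  expect_lt(length(kept_out) / k, 0.12)
  expect_lt(length(kept_drop) / k, 0.12)

  # a candidate generating the target with a large effect is always kept
  frame$strong <- rnorm(n)
  frame$y2 <- 5 * frame$strong + rnorm(n, sd = 0.5)
  frame$y2[sample(n, 300)] <- NA
  expect_true("strong" %in%
                select_predictors(frame, c("strong", "x1"), "y2", "outcome"))
  expect_identical(select_predictors(frame, character(0), "y", "outcome"),
                   character(0))
  frame$x1[1] <- NA
  expect_error(select_predictors(frame, "x1", "y", "outcome"),
               "fully observed")
})

test_that("conditional-mean imputation recovers exact linear structure", {
  set.seed(42)
  n <- 200
  frame <- data.frame(a = rnorm(n), b = rnorm(n))
  frame$y <- 2 + 3 * frame$a - 1.5 * frame$b # noiseless
  truth <- frame$y
  masked <- sample(n, 40)
  frame$y[masked] <- NA
  models <- fit_imputation_models(frame, "y", c("a", "b"))
  done <- impute_conditional_mean(frame, models)
  expect_equal(done$y[masked], truth[masked], tolerance = 1e-10)
  expect_identical(done$y[-masked], frame$y[-masked])
  # idempotence
  again <- impute_conditional_mean(done,
                                   fit_imputation_models(done, "y",
                                                         c("a", "b")))
  expect_identical(again$y, done$y)
  audit <- attr(done, "imputation_audit")
  expect_equal(audit$n_imputed, 40)
  expect_match(audit$predictors, "a")
})

test_that("a frame with no missing values passes through unchanged", {
  frame <- data.frame(a = rnorm(20), y = rnorm(20))
  models <- fit_imputation_models(frame, "y", "a")
  expect_length(models, 0)
  done <- impute_conditional_mean(frame, models)
  expect_identical(done$y, frame$y)
})

test_that("hospitalization costs are never imputed and contribute zero", {
  cfg <- small_config(120)
  co <- apply_missingness(generate_cohort(cfg, seed = 5), seed = 5)
  frame <- build_analysis_frame(co)
  any_missing_w4 <- anyNA(frame$cost_inpatient_w4)
  completed <- impute_analysis_frame(frame)
  # inpatient wave costs keep their NAs; everything else is complete
  if (any_missing_w4) expect_true(anyNA(completed$cost_inpatient_w4))
  other <- grep("^cost_(?!inpatient)", names(completed), perl = TRUE,
                value = TRUE)
  expect_false(anyNA(completed[other]))
  expect_false(anyNA(completed[grep("^u_", names(completed))]))
  # annualisation treats the never-imputed hospital NAs as zero
  ann <- annual_cost_breakdown(completed)
  expect_false(anyNA(ann$inpatient))
  masked <- is.na(completed$cost_inpatient_w3) &
    is.na(completed$cost_inpatient_w4)
  expect_true(all(ann$inpatient[masked] == 0))
})

test_that("imputed arm means beat complete-case means under MAR dropout", {
  cfg <- synthetic_trial_config(n_intervention = 5000, n_control = 5000)
  co <- generate_cohort(cfg, seed = 7)
  full <- participant_analysis_table(co, impute = FALSE)
  dropped <- apply_missingness(co, seed = 7)
  imputed <- participant_analysis_table(dropped)
  all_obs <- tapply(dropped$waves$observed, dropped$waves$id, all)
  cc <- full[all_obs[full$id], ]
  for (a in c("intervention", "control")) {
    for (v in c("cost_societal", "qaly_eq5d")) {
      truth <- mean(full[[v]][full$arm == a])
      bias_imp <- abs(mean(imputed[[v]][imputed$arm == a]) - truth)
      bias_cc <- abs(mean(cc[[v]][cc$arm == a]) - truth)
      expect_lt(bias_imp, bias_cc)
    }
  }
})
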