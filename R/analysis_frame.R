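# Participant-level analysis frame: wave-level category costs and
# utilities in wide form, imputation orchestration, annualisation and the
# final per-participant cost/effect table the CEA consumes.

wave_cost_categories <- function() {
  setdiff(cost_categories(), "intervention")
}

hospital_cost_columns <- function() {
  c("cost_inpatient_w3", "cost_inpatient_w4")
}

#' Build the wide participant-level analysis frame
#'
#' One row per participant: baseline covariates (with sex and arm coded as
#' 0/1 indicators for modelling), baseline utilities and baseline 3-month
#' societal cost as fully observed predictors, and the imputation targets -
#' per-category costs at the 6- and 12-month questionnaire waves
#' (`cost_<category>_w3/4`) and utilities at the three follow-up waves
#' (`u_eq5d_w2/3/4`, `u_sf6d_w2/3/4`).
#'
#' @param cohort a `trial_cohort`.
#' @param prices a [unit_price_table()].
#' @return data.frame, one row per participant.
#' @export
build_analysis_frame <- function(cohort, prices = unit_price_table()) {
  p <- cohort$participants
  w <- cohort$waves
  idx_wave <- function(ww) w[w$wave == ww, ][match(p$id, w$id[w$wave == ww]), ]
  frame <- data.frame(
    id = p$id, arm = p$arm,
    arm_intervention = as.integer(p$arm == "intervention"),
    age = p$age, female = as.integer(p$sex == "female"),
    employed = as.integer(p$employed),
    gross_daily_wage = p$gross_daily_wage,
    baseline_symptoms = p$baseline_symptoms,
    antidepressant_use = as.integer(p$antidepressant_use),
    onset_day = p$onset_day, event = p$event,
    stringsAsFactors = FALSE
  )
  wage <- p$gross_daily_wage
  for (ww in c(1, 3, 4)) {
    panel <- idx_wave(ww)
    bd <- panel_cost_breakdown(panel, prices, wage)
    if (ww == 1) {
      frame$baseline_cost <- aggregate_costs(bd, "societal")
    } else {
      names(bd) <- sprintf("cost_%s_w%d", names(bd), ww)
      frame <- cbind(frame, bd)
    }
  }
  for (ww in 1:4) {
    panel <- idx_wave(ww)
    frame[[sprintf("u_eq5d_w%d", ww)]] <- panel$utility_eq5d
    frame[[sprintf("u_sf6d_w%d", ww)]] <- panel$utility_sf6d
  }
  frame
}

#' Default baseline candidate predictors for imputation
#' @return character vector of column names in the analysis frame.
#' @export
default_imputation_candidates <- function() {
  c("arm_intervention", "age", "female", "employed", "gross_daily_wage",
    "baseline_symptoms", "antidepressant_use", "baseline_cost",
    "u_eq5d_w1", "u_sf6d_w1")
}

#' Impute all missing cost and utility targets of an analysis frame
#'
#' Fixed order per target: dropout-predictor selection, outcome-predictor
#' selection, joint fit, prediction. Hospitalization (in-patient) wave
#' costs are excluded from imputation; their missing values contribute
#' zero when annualised.
#'
#' @param frame output of [build_analysis_frame()].
#' @param candidates candidate predictor columns (fully observed).
#' @param alpha per-candidate retention threshold.
#' @return completed frame with an `imputation_audit` attribute.
#' @export
impute_analysis_frame <- function(frame,
                                  candidates = default_imputation_candidates(),
                                  alpha = 0.05) {
  targets <- c(
    as.vector(outer(wave_cost_categories(),
                    c("w3", "w4"), function(a, b) sprintf("cost_%s_%s", a, b))),
    as.vector(outer(c("u_eq5d", "u_sf6d"), c("w2", "w3", "w4"), paste,
                    sep = "_"))
  )
  targets <- intersect(targets, names(frame))
  models <- fit_imputation_models(frame, targets, candidates, alpha,
                                  exclude = hospital_cost_columns())
  impute_conditional_mean(frame, models)
}

#' Annual per-participant cost breakdown from a (completed) frame
#'
#' Each category's annual cost is the extrapolated sum of the 6- and
#' 12-month wave costs (each wave covers a 3-month recall window scaled by
#' the extrapolation factor to its 6-month interval). Program cost is a
#' per-arm constant. Participant time on the program (`opportunity_time`)
#' is a one-off and is not extrapolated. Missing in-patient wave costs
#' (never imputed) contribute zero.
#'
#' @param frame completed analysis frame.
#' @param prices a [unit_price_table()].
#' @param extrapolation_factor recall-window scaling (default 2).
#' @param drop_hospital zero out the in-patient category (sensitivity
#'   analysis).
#' @return data.frame with one euro column per category of
#'   [cost_categories()].
#' @export
annual_cost_breakdown <- function(frame, prices = unit_price_table(),
                                  extrapolation_factor = 2,
                                  drop_hospital = FALSE) {
  out <- data.frame(
    intervention = ifelse(frame$arm == "intervention",
                          prices$intervention_cost,
                          prices$control_program_cost)
  )
  for (cat in wave_cost_categories()) {
    w3 <- frame[[sprintf("cost_%s_w3", cat)]]
    w4 <- frame[[sprintf("cost_%s_w4", cat)]]
    if (cat == "inpatient") {
      w3[is.na(w3)] <- 0
      w4[is.na(w4)] <- 0
    }
    fac <- if (cat == "opportunity_time") 1 else extrapolation_factor
    out[[cat]] <- fac * (w3 + w4)
  }
  if (drop_hospital) out$inpatient <- 0 * out$inpatient
  out
}

#' Per-participant cost and effect table for the economic evaluation
#'
#' Runs costing, (optionally) imputation, annualisation and effect
#' construction, returning the table the bootstrap resamples: one row per
#' participant with annual category costs, perspective totals, depression
#' -free years and both QALY measures.
#'
#' @param cohort a `trial_cohort` (with or without missingness applied).
#' @param prices a [unit_price_table()].
#' @param impute run regression imputation on missing cost/utility values.
#' @param extrapolation_factor recall-window scaling (default 2).
#' @param drop_hospital zero out in-patient costs (sensitivity analysis).
#' @param include_opportunity include participant program time in totals.
#' @param alpha imputation predictor retention threshold.
#' @return data.frame with an `imputation_audit` attribute.
#' @export
participant_analysis_table <- function(cohort,
                                       prices = unit_price_table(),
                                       impute = TRUE,
                                       extrapolation_factor = 2,
                                       drop_hospital = FALSE,
                                       include_opportunity = FALSE,
                                       alpha = 0.05) {
  frame <- build_analysis_frame(cohort, prices)
  audit <- data.frame()
  if (impute) {
    frame <- impute_analysis_frame(frame, alpha = alpha)
    audit <- attr(frame, "imputation_audit")
  }
  costs <- annual_cost_breakdown(frame, prices, extrapolation_factor,
                                 drop_hospital)
  utils_ok <- !anyNA(frame[grep("^u_(eq5d|sf6d)_w", names(frame))])
  if (!utils_ok) {
    stop("missing utility values remain: run imputation first")
  }
  eq5d <- as.matrix(frame[sprintf("u_eq5d_w%d", 1:4)])
  sf6d <- as.matrix(frame[sprintf("u_sf6d_w%d", 1:4)])
  out <- data.frame(
    id = frame$id, arm = frame$arm,
    age = frame$age, female = frame$female, employed = frame$employed,
    baseline_symptoms = frame$baseline_symptoms,
    antidepressant_use = frame$antidepressant_use,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, costs)
  out$cost_societal <- aggregate_costs(costs, "societal",
                                       include_opportunity)
  out$cost_health_care <- aggregate_costs(costs, "health_care",
                                          include_opportunity)
  out$dfy <- depression_free_years(frame$onset_day)
  out$qaly_eq5d <- qaly_auc(eq5d)
  out$qaly_sf6d <- qaly_auc(sf6d)
  attr(out, "imputation_audit") <- audit
  out
}
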