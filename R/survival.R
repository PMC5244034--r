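# Time-to-onset analysis: Cox proportional hazards with post-hoc covariate
# pruning, and restricted mean depression-free survival per arm.

#' Survival records from a cohort
#'
#' Time to onset of major depression in weeks, censored at the 52.18-week
#' horizon.
#'
#' @param cohort a `trial_cohort`.
#' @return data.frame with `id`, `arm`, `time` (weeks), `event`,
#'   `antidepressant_use`.
#' @export
survival_records <- function(cohort) {
  p <- cohort$participants
  time <- pmin(ifelse(is.na(p$onset_day), Inf, p$onset_day),
               DAYS_PER_YEAR) / 7
  data.frame(id = p$id, arm = p$arm, time = time, event = p$event,
             antidepressant_use = as.integer(p$antidepressant_use),
             stringsAsFactors = FALSE)
}

#' Cox proportional-hazards comparison with post-hoc covariate pruning
#'
#' Fits a partial-likelihood Cox model of time to onset on treatment plus
#' the supplied covariates (Breslow tie handling; week-resolution times
#' produce ties). Covariates that are not predictors of the outcome
#' (p >= `alpha`) are dropped and the treatment-only model is refitted.
#'
#' @param records output of [survival_records()] (columns `time`, `event`,
#'   `arm`, plus covariates).
#' @param covariates covariate column names (default concurrent
#'   antidepressant use).
#' @param alpha pruning threshold (default 0.05).
#' @return list with `fit` (the final `coxph` fit), `hr_table`
#'   (data.frame: term, HR, CI, p) and `pruned` (dropped covariates).
#' @export
fit_cox <- function(records, covariates = "antidepressant_use",
                    alpha = 0.05) {
  if (sum(records$event) == 0) {
    stop("inestimable model: no onset events")
  }
  records$arm <- factor(records$arm, levels = c("control", "intervention"))
  if (nlevels(droplevels(records$arm)) < 2) {
    stop("both arms are required")
  }
  covariates <- intersect(covariates, names(records))
  form <- stats::reformulate(c("arm", covariates),
                             response = "survival::Surv(time, event)")
  fit <- survival::coxph(form, data = records, ties = "breslow")
  pruned <- character(0)
  if (length(covariates)) {
    ps <- summary(fit)$coefficients[, "Pr(>|z|)"]
    cov_terms <- setdiff(names(ps), grep("^arm", names(ps), value = TRUE))
    drop <- cov_terms[ps[cov_terms] >= alpha]
    if (length(drop)) {
      pruned <- covariates[vapply(covariates, function(cv) {
        any(startsWith(drop, cv))
      }, logical(1))]
      keep <- setdiff(covariates, pruned)
      form <- stats::reformulate(c("arm", keep),
                                 response = "survival::Surv(time, event)")
      fit <- survival::coxph(form, data = records, ties = "breslow")
    }
  }
  s <- summary(fit)
  hr_table <- data.frame(
    term = rownames(s$coefficients),
    hr = s$conf.int[, "exp(coef)"],
    ci_lower = s$conf.int[, "lower .95"],
    ci_upper = s$conf.int[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(fit = fit, hr_table = hr_table, pruned = pruned)
}

#' Restricted mean depression-free survival per arm
#'
#' Area under the Kaplan-Meier curve up to the horizon, per arm, with
#' Greenwood-based standard errors.
#'
#' @param records output of [survival_records()].
#' @param horizon_weeks restriction time (default the 52.18-week year).
#' @param conf_level confidence level.
#' @return data.frame: arm, n, events, `rmean` (weeks), `se`, CI bounds.
#' @export
restricted_mean_survival <- function(records,
                                     horizon_weeks = WEEKS_PER_YEAR,
                                     conf_level = 0.95) {
  arm <- factor(records$arm, levels = c("intervention", "control"))
  arm <- droplevels(arm)
  if (!nlevels(arm)) stop("insufficient data: no records")
  fit <- survival::survfit(survival::Surv(time, event) ~ arm,
                           data = transform(records, arm = arm))
  tab <- summary(fit, rmean = horizon_weeks)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list(levels(arm),
                                                       names(tab)))
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  rmean <- tab[, "rmean"]
  se <- tab[, "se(rmean)"]
  data.frame(
    arm = sub("^arm=", "", rownames(tab)),
    n = as.integer(tab[, "records"]),
    events = as.integer(tab[, "events"]),
    rmean = as.numeric(rmean),
    se = as.numeric(se),
    ci_lower = as.numeric(rmean - crit * se),
    ci_upper = as.numeric(rmean + crit * se),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
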