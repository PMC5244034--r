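# Conditional-mean regression imputation of missing cost and utility values.
#
# Missing wave-level category costs and wave utilities are replaced by
# predictions from linear models whose predictors are screened among fully
# observed baseline variables: predictors of the outcome (linear regression
# on observed target values) and predictors of dropout (logistic regression
# on the missingness indicator), each retained at p < 0.05, taken as a
# union. Observed values are never altered, and in-patient (hospitalization)
# cost columns are never imputed because hospital admissions are too rare to
# support a stable model.

#' Screen candidate predictors for an imputation target
#'
#' @param frame participant-level data.frame (see
#'   [build_analysis_frame()]).
#' @param candidates names of fully observed numeric candidate columns.
#' @param target name of the target column.
#' @param mode `"outcome"` screens by linear regression of the observed
#'   target on each candidate; `"dropout"` screens by logistic regression
#'   of the target's missingness indicator on each candidate.
#' @param alpha per-candidate retention threshold (default 0.05).
#' @return character vector of retained candidate names.
#' @export
select_predictors <- function(frame, candidates, target,
                              mode = c("outcome", "dropout"),
                              alpha = 0.05) {
  mode <- match.arg(mode)
  if (!length(candidates)) return(character(0))
  bad <- candidates[vapply(frame[candidates], anyNA, logical(1))]
  if (length(bad)) {
    stop("candidate predictors must be fully observed: ",
         paste(bad, collapse = ", "))
  }
  y <- frame[[target]]
  keep <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    x <- frame[[candidates[i]]]
    p <- if (mode == "outcome") {
      obs <- !is.na(y)
      if (sum(obs) < 3 || stats::sd(x[obs]) == 0) {
        NA_real_
      } else {
        fit <- stats::lm(y[obs] ~ x[obs])
        stats::coef(summary(fit))[2, 4]
      }
    } else {
      miss <- as.integer(is.na(y))
      if (length(unique(miss)) < 2 || stats::sd(x) == 0) {
        NA_real_
      } else {
        fit <- stats::glm(miss ~ x, family = stats::binomial())
        stats::coef(summary(fit))[2, 4]
      }
    }
    keep[i] <- isTRUE(p < alpha)
  }
  candidates[keep]
}

#' Fit imputation models for a set of targets
#'
#' For each target, dropout predictors are selected first, then outcome
#' predictors; the union defines the joint linear model fitted on rows with
#' an observed target.
#'
#' @inheritParams select_predictors
#' @param targets names of target columns.
#' @param exclude target columns never to be imputed (hospitalization
#'   costs).
#' @return named list of model records (`target`, `predictors`,
#'   `coefficients`, `n_observed`, `n_missing`).
#' @export
fit_imputation_models <- function(frame, targets, candidates,
                                  alpha = 0.05, exclude = character(0)) {
  targets <- setdiff(targets, exclude)
  models <- list()
  drop_cache <- list()
  for (tg in targets) {
    y <- frame[[tg]]
    if (!anyNA(y)) next
    # targets sharing a missingness pattern (same wave) share the dropout
    # screen, so it is computed once per pattern
    pattern <- is.na(y)
    pred_drop <- NULL
    for (entry in drop_cache) {
      if (identical(entry$pattern, pattern)) {
        pred_drop <- entry$predictors
        break
      }
    }
    if (is.null(pred_drop)) {
      pred_drop <- select_predictors(frame, candidates, tg, "dropout", alpha)
      drop_cache[[length(drop_cache) + 1]] <-
        list(pattern = pattern, predictors = pred_drop)
    }
    pred_out <- select_predictors(frame, candidates, tg, "outcome", alpha)
    predictors <- union(pred_drop, pred_out)
    obs <- !is.na(y)
    if (length(predictors)) {
      x <- as.matrix(frame[obs, predictors, drop = FALSE])
      if (qr(cbind(1, x))$rank < ncol(x) + 1) {
        stop("collinear candidates in imputation model for ", tg)
      }
      fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x), y[obs])
      coefs <- fit$coefficients
    } else {
      coefs <- c(`(Intercept)` = mean(y[obs]))
    }
    models[[tg]] <- list(target = tg, predictors = predictors,
                         coefficients = coefs,
                         n_observed = sum(obs), n_missing = sum(!obs))
  }
  models
}

#' Replace missing target values by conditional-mean predictions
#'
#' Observed values are never altered; the operation is idempotent. An error
#' is raised if a prediction would need a missing predictor value.
#'
#' @param frame participant-level data.frame.
#' @param models output of [fit_imputation_models()].
#' @return the completed frame, with an `imputation_audit` attribute
#'   (data.frame: target, n observed, n imputed, retained predictors,
#'   coefficients).
#' @export
impute_conditional_mean <- function(frame, models) {
  audit <- list()
  for (m in models) {
    y <- frame[[m$target]]
    miss <- which(is.na(y))
    if (length(miss)) {
      if (length(m$predictors)) {
        x <- as.matrix(frame[miss, m$predictors, drop = FALSE])
        if (anyNA(x)) {
          stop("ordering error: predictor missing when imputing ", m$target)
        }
        pred <- as.numeric(cbind(1, x) %*% m$coefficients)
      } else {
        pred <- rep(m$coefficients[["(Intercept)"]], length(miss))
      }
      y[miss] <- pred
      frame[[m$target]] <- y
    }
    audit[[m$target]] <- data.frame(
      target = m$target, n_observed = m$n_observed,
      n_imputed = length(miss),
      predictors = paste(m$predictors, collapse = "+"),
      coefficients = paste(sprintf("%s=%.6g", names(m$coefficients),
                                   m$coefficients), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  attr(frame, "imputation_audit") <-
    if (length(audit)) do.call(rbind, c(audit, make.row.names = FALSE))
    else data.frame()
  frame
}
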