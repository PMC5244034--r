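# Synthetic two-arm prevention-trial cohorts.
#
# The generator emulates the data structure of a 12-month indicated
# depression-prevention trial: ~200 participants per arm, a constant
# onset hazard per arm calibrated to mean depression-free survival of 43
# (intervention) vs 37 (control) weeks, zero-inflated right-skewed
# resource-use quantities whose arm-level annual cost expectations match a
# published cost table, truncated-normal utility trajectories (EQ-5D-3L and
# SF-6D) correlated across waves, and monotone missing-at-random dropout
# that is higher in the intervention arm at 12 months (~70% retention
# overall).

WEEKS_PER_YEAR <- 365.25 / 7
DAYS_PER_YEAR <- 365.25

#' Restricted mean of an exponential time-to-event distribution
#'
#' Closed form `(1 - exp(-lambda * horizon)) / lambda`, the expected time to
#' event censored at `horizon`; equals `horizon` when `lambda = 0`.
#'
#' @param lambda hazard rate (per week when `horizon` is in weeks).
#' @param horizon restriction time.
#' @return restricted mean in the units of `horizon`.
#' @export
rmst_exponential <- function(lambda, horizon) {
  stopifnot(all(lambda >= 0), horizon > 0)
  ifelse(lambda == 0, horizon, (1 - exp(-lambda * horizon)) / lambda)
}

#' Hazard whose restricted mean survival equals a target
#'
#' Inverts [rmst_exponential()] numerically; used to calibrate the per-arm
#' onset hazards to the trial's mean depression-free weeks.
#'
#' @param target_mean target restricted mean (same units as `horizon`).
#' @param horizon restriction time (default the 52.18-week year).
#' @return hazard rate per unit time.
#' @export
hazard_for_restricted_mean <- function(target_mean,
                                       horizon = WEEKS_PER_YEAR) {
  stopifnot(target_mean > 0, target_mean < horizon)
  stats::uniroot(function(l) rmst_exponential(l, horizon) - target_mean,
                 interval = c(1e-9, 10), tol = 1e-12)$root
}

# Intercept l such that E_z[plogis(l + beta * z)] = p for z ~ N(0,1);
# calibrates marginal dropout probabilities under the symptom link.
logit_intercept_for_mean <- function(p, beta) {
  if (p <= 0) return(-Inf)
  f <- function(l) {
    stats::integrate(function(z) stats::plogis(l + beta * z) * stats::dnorm(z),
                     -8, 8, rel.tol = 1e-10)$value - p
  }
  stats::uniroot(f, interval = c(-20, 20), tol = 1e-10)$root
}

# Per-category annual cost calibration targets (euro, arm means) defining
# the default study conditions. `intervention` is a program-cost constant.
default_annual_cost_targets <- function() {
  t <- rbind(
    gp_internist      = c(142, 117),
    mental_health     = c(117, 175),
    other_specialist  = c(243, 236),
    inpatient         = c(48, 123),
    daycare           = c(0, 35),
    antidepressants   = c(12, 20),
    private_therapist = c(137, 117),
    copayments        = c(27, 30),
    otc               = c(17, 22),
    informal_care     = c(323, 384),
    domestic_help     = c(143, 120),
    travel            = c(29, 28),
    absenteeism       = c(1475, 1172),
    presenteeism      = c(1696, 2021)
  )
  colnames(t) <- c("intervention", "control")
  t
}

# Two-part model settings per resource-use field: which cost category the
# field belongs to, its share of that category's euro target, the per-wave
# probability of no use, the gamma shape of the positive part, and whether
# the quantity only arises for employed participants.
quantity_field_table <- function() {
  tbl <- read.csv(text = "
field,category,share,p_zero,shape,employed_only
gp_visits,gp_internist,0.6,0.45,1.0,FALSE
internist_visits,gp_internist,0.4,0.80,1.0,FALSE
psychiatrist_sessions,mental_health,0.4,0.92,0.8,FALSE
psychotherapist_sessions,mental_health,0.6,0.90,0.8,FALSE
other_specialist_contacts,other_specialist,1.0,0.55,0.8,FALSE
inpatient_mental_days,inpatient,0.6,0.9965,1.2,FALSE
inpatient_psychosomatic_days,inpatient,0.4,0.9975,1.2,FALSE
daycare_days,daycare,1.0,0.998,1.2,FALSE
antidepressant_days,antidepressants,1.0,0.95,1.0,FALSE
private_therapist_spend,private_therapist,1.0,0.90,0.7,FALSE
copayments_spend,copayments,1.0,0.60,0.8,FALSE
otc_spend,otc,1.0,0.55,0.8,FALSE
informal_care_hours,informal_care,1.0,0.85,0.6,FALSE
domestic_help_hours,domestic_help,1.0,0.92,0.7,FALSE
travel_km,travel,1.0,0.40,0.9,FALSE
absent_days,absenteeism,1.0,0.70,0.6,TRUE
presenteeism_days,presenteeism,1.0,0.55,0.8,TRUE
", strip.white = TRUE)
  tbl
}

# Euro price per unit of each resource-use field, resolved from the price
# table; pass-through euro amounts have unit price 1.
field_unit_price <- function(field, prices) {
  switch(field,
    gp_visits = prices$gp,
    internist_visits = prices$internist,
    psychiatrist_sessions = prices$psychiatrist,
    psychotherapist_sessions = prices$psychotherapist,
    other_specialist_contacts = prices$other_specialist,
    inpatient_mental_days = prices$inpatient_mental,
    inpatient_psychosomatic_days = prices$inpatient_psychosomatic,
    daycare_days = prices$daycare,
    antidepressant_days = medication_daily_price(
      prices$antidepressant_packages, prices$statutory_share),
    private_therapist_spend = 1,
    copayments_spend = 1,
    otc_spend = 1,
    informal_care_hours = prices$informal_care,
    domestic_help_hours = prices$domestic_help,
    travel_km = prices$travel,
    absent_days = NA_real_, # valued at the individual wage
    presenteeism_days = NA_real_,
    stop("no unit price mapping for field ", field)
  )
}

#' Configuration of the synthetic prevention-trial generator
#'
#' Builds the full parameter set of the generator and calibrates it so that
#' arm-level expectations reproduce the study conditions: onset hazards are
#' solved from target mean depression-free weeks, per-wave positive-part
#' quantity means are solved from target annual per-category euro costs
#' (two questionnaire waves per year, each extrapolated from a 3-month
#' recall window by `extrapolation_factor`), utility-trajectory locations
#' are solved so post-truncation wave means hit their targets, and dropout
#' intercepts are solved so marginal wave retention matches its targets
#' under the baseline-symptom link.
#'
#' @param n_intervention,n_control arm sizes (default 202 / 204).
#' @param prices a [unit_price_table()] used to translate euro calibration
#'   targets into quantity scales.
#' @param target_mean_dfw target mean depression-free weeks per arm within
#'   the 52.18-week year, named `intervention` / `control` (default 43/37).
#' @param annual_cost_targets 14 x 2 matrix of per-category annual euro cost
#'   targets (rows as in [default_annual_cost_targets()]).
#' @param dropout_prob_by_wave_and_arm 3 x 2 matrix of marginal conditional
#'   dropout probabilities at the post-treatment, 6- and 12-month waves
#'   (rows) per arm (columns); defaults give ~90/80/70% retention overall
#'   with differentially higher 12-month dropout in the intervention arm.
#' @param dropout_symptom_beta log-odds of dropping out per SD of baseline
#'   symptom severity (missing-at-random mechanism; default 0.4).
#' @param cost_symptom_gamma relative increase in positive-part quantity
#'   means per SD of baseline symptom severity (default 0.3).
#' @param utility_symptom_slope named per-instrument utility decrement per
#'   SD of baseline symptom severity.
#' @param utility_ar_rho cross-wave AR(1) correlation of the latent utility
#'   process (default 0.7).
#' @param p_employed employment probability (default 0.72).
#' @param mean_daily_wage,wage_sdlog gross daily wage: lognormal mean
#'   (EUR/day) and log-scale SD.
#' @param extrapolation_factor recall-window extrapolation: each 3-month
#'   questionnaire wave is scaled by this factor to cover a 6-month
#'   interval (default 2).
#' @param seed default master seed used when none is passed to
#'   [generate_cohort()].
#' @return object of class `synthetic_trial_config`.
#' @export
synthetic_trial_config <- function(n_intervention = 202,
                                   n_control = 204,
                                   prices = unit_price_table(),
                                   target_mean_dfw = c(intervention = 43,
                                                       control = 37),
                                   annual_cost_targets =
                                     default_annual_cost_targets(),
                                   dropout_prob_by_wave_and_arm =
                                     rbind(post = c(0.099, 0.099),
                                           m6   = c(0.111, 0.111),
                                           m12  = c(0.201, 0.039)),
                                   dropout_symptom_beta = 0.4,
                                   cost_symptom_gamma = 0.3,
                                   utility_symptom_slope = c(EQ5D = -0.03,
                                                             SF6D = -0.02),
                                   utility_ar_rho = 0.7,
                                   p_employed = 0.72,
                                   mean_daily_wage = 120,
                                   wage_sdlog = 0.4,
                                   extrapolation_factor = 2,
                                   seed = 20130301L) {
  stopifnot(n_intervention >= 0, n_control >= 0,
            all(target_mean_dfw > 0),
            all(annual_cost_targets >= 0),
            all(dropout_prob_by_wave_and_arm >= 0),
            all(dropout_prob_by_wave_and_arm <= 1),
            utility_ar_rho >= 0, utility_ar_rho < 1,
            p_employed >= 0, p_employed <= 1,
            mean_daily_wage >= 0, extrapolation_factor > 0)
  colnames(dropout_prob_by_wave_and_arm) <- c("intervention", "control")

  hazards <- c(
    intervention = hazard_for_restricted_mean(target_mean_dfw[["intervention"]]),
    control = hazard_for_restricted_mean(target_mean_dfw[["control"]])
  )

  # Utility wave means (post-truncation targets): equal at baseline, then a
  # sustained arm separation sized so the AUC over the year reproduces the
  # study's QALY means (EQ-5D 0.78 vs 0.77, SF-6D 0.71 vs 0.67).
  utility <- list(
    EQ5D = list(
      mean = rbind(intervention = c(0.74, 0.785, 0.785, 0.785),
                   control      = c(0.74, 0.772, 0.772, 0.772)),
      sd = 0.15, floor = -0.594,
      slope = utility_symptom_slope[["EQ5D"]]
    ),
    SF6D = list(
      mean = rbind(intervention = c(0.69, 0.711, 0.711, 0.711),
                   control      = c(0.69, 0.669, 0.669, 0.669)),
      sd = 0.075, floor = 0.30,
      slope = utility_symptom_slope[["SF6D"]]
    )
  )
  for (ins in names(utility)) {
    u <- utility[[ins]]
    utility[[ins]]$location <- apply(
      u$mean, 1:2,
      function(m) truncnorm_location_for_mean(m, u$sd, u$floor, 1)
    )
  }

  qp <- calibrate_quantity_params(
    prices, annual_cost_targets, p_employed, mean_daily_wage,
    extrapolation_factor
  )

  structure(list(
    n_intervention = as.integer(n_intervention),
    n_control = as.integer(n_control),
    horizon_days = DAYS_PER_YEAR,
    wave_times = c(0, 6 / WEEKS_PER_YEAR, 0.5, 1.0),
    target_mean_dfw = target_mean_dfw,
    onset_hazard_per_week = hazards,
    annual_cost_targets = annual_cost_targets,
    quantity_params = qp,
    utility = utility,
    utility_ar_rho = utility_ar_rho,
    dropout_prob_by_wave_and_arm = dropout_prob_by_wave_and_arm,
    dropout_symptom_beta = dropout_symptom_beta,
    dropout_intercepts = apply(dropout_prob_by_wave_and_arm, 1:2,
                               logit_intercept_for_mean,
                               beta = dropout_symptom_beta),
    cost_symptom_gamma = cost_symptom_gamma,
    p_employed = p_employed,
    wage_meanlog = log(mean_daily_wage) - wage_sdlog^2 / 2,
    wage_sdlog = wage_sdlog,
    mean_daily_wage = mean_daily_wage,
    intervention_time_hours = c(intervention = 6, control = 0.5),
    p_antidepressant_use = 0.12,
    extrapolation_factor = extrapolation_factor,
    prices = prices,
    seed = as.integer(seed)
  ), class = "synthetic_trial_config")
}

# Solve per-wave positive-part quantity means from annual euro targets:
# target = n_waves(2) * extrapolation * (1 - p_zero) * pos_mean * price
#          [* p_employed * wage terms for productivity fields].
calibrate_quantity_params <- function(prices, targets, p_employed,
                                      mean_daily_wage, extrapolation_factor) {
  qp <- quantity_field_table()
  presenteeism_mult <- 1 - truncnorm_mean(6, 2, 0, 10) / 10
  rows <- lapply(c("intervention", "control"), function(arm) {
    out <- qp
    out$arm <- arm
    out$pos_mean <- NA_real_
    for (i in seq_len(nrow(qp))) {
      f <- qp$field[i]
      target <- targets[qp$category[i], arm] * qp$share[i]
      price <- field_unit_price(f, prices)
      denom <- 2 * extrapolation_factor * (1 - qp$p_zero[i])
      if (qp$employed_only[i]) {
        denom <- denom * p_employed * mean_daily_wage
        if (f == "presenteeism_days") denom <- denom * presenteeism_mult
      } else {
        denom <- denom * price
      }
      out$pos_mean[i] <- if (target == 0) 0 else target / denom
      if (target == 0) out$p_zero[i] <- 1
    }
    out
  })
  do.call(rbind, rows)
}

#' Sample days to depression onset under a constant hazard
#'
#' Exponential onset times censored at the follow-up horizon; a
#' one-parameter stand-in per arm for the trial's empirical onset process.
#'
#' @param n number of participants.
#' @param hazard_per_week onset hazard (events per week).
#' @param horizon_days follow-up horizon (default 365.25).
#' @return data.frame with `onset_day` (NA when censored) and logical
#'   `event`.
#' @export
sample_onset_days <- function(n, hazard_per_week, horizon_days = DAYS_PER_YEAR) {
  if (hazard_per_week < 0) stop("onset hazard must be non-negative")
  stopifnot(n >= 0)
  if (n == 0 || hazard_per_week == 0) {
    return(data.frame(onset_day = rep(NA_real_, n), event = rep(FALSE, n)))
  }
  t_days <- stats::rexp(n, rate = hazard_per_week / 7)
  event <- t_days <= horizon_days
  data.frame(onset_day = ifelse(event, t_days, NA_real_), event = event)
}

#' Generate a synthetic prevention-trial cohort
#'
#' Pure function of `(config, seed)`: every stage draws from its own
#' sub-seeded stream (see [substream_seed()]). Returns a complete cohort;
#' apply [apply_missingness()] to superimpose dropout.
#'
#' @param config a [synthetic_trial_config()].
#' @param seed master seed (defaults to `config$seed`).
#' @return object of class `trial_cohort`: list with `participants` (one
#'   row per participant) and `waves` (one row per participant-wave;
#'   resource-use panels at the baseline, 6- and 12-month waves, utilities
#'   at all four waves).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_trial_config"))
  n_int <- config$n_intervention
  n_ctr <- config$n_control
  n <- n_int + n_ctr
  arm <- factor(rep(c("intervention", "control"), c(n_int, n_ctr)),
                levels = c("intervention", "control"))
  id <- sprintf("P%05d", seq_len(n))

  set.seed(substream_seed(seed, "participants"))
  z <- stats::rnorm(n)
  participants <- data.frame(
    id = id, arm = arm,
    age = round(rtruncnorm(n, 45, 12, 18, 80)),
    sex = ifelse(stats::runif(n) < 0.72, "female", "male"),
    employed = stats::runif(n) < config$p_employed,
    baseline_symptoms = round(qtruncnorm(stats::pnorm(z), 25, 7, 16, 60), 1),
    symptom_z = z,
    antidepressant_use = stats::runif(n) < config$p_antidepressant_use,
    stringsAsFactors = FALSE
  )
  participants$gross_daily_wage <- ifelse(
    participants$employed,
    stats::rlnorm(n, config$wage_meanlog, config$wage_sdlog), 0)

  set.seed(substream_seed(seed, "onset"))
  onset <- rbind(
    sample_onset_days(n_int, config$onset_hazard_per_week[["intervention"]],
                      config$horizon_days),
    sample_onset_days(n_ctr, config$onset_hazard_per_week[["control"]],
                      config$horizon_days)
  )
  participants$onset_day <- onset$onset_day
  participants$event <- onset$event

  set.seed(substream_seed(seed, "resource_use"))
  waves <- expand.grid(wave = 1:4, id = id, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)[, c("id", "wave")]
  waves <- waves[order(waves$wave, waves$id), ]
  rownames(waves) <- NULL
  waves$time_years <- config$wave_times[waves$wave]
  waves$observed <- TRUE
  idx <- match(waves$id, participants$id)
  w_arm <- as.character(participants$arm)[idx]
  w_z <- participants$symptom_z[idx]
  w_emp <- participants$employed[idx]
  mult <- pmax(0, 1 + config$cost_symptom_gamma * w_z)
  panel_wave <- waves$wave %in% c(1, 3, 4)
  # Baseline panels describe pre-randomization use: control-arm parameters
  # for everyone.
  param_arm <- ifelse(waves$wave == 1, "control", w_arm)
  qp <- config$quantity_params
  for (f in setdiff(panel_fields(),
                    c("efficiency_rating", "intervention_time_hours"))) {
    waves[[f]] <- NA_real_
    for (a in c("intervention", "control")) {
      rows <- which(panel_wave & param_arm == a)
      if (!length(rows)) next
      p <- qp[qp$field == f & qp$arm == a, ]
      m <- length(rows)
      any_use <- stats::runif(m) >= p$p_zero
      q <- numeric(m)
      if (p$pos_mean > 0 && any(any_use)) {
        q[any_use] <- stats::rgamma(sum(any_use), shape = p$shape,
                                    scale = p$pos_mean / p$shape)
      }
      q <- q * mult[rows]
      if (p$employed_only) q <- q * w_emp[rows]
      waves[[f]][rows] <- q
    }
  }
  waves$efficiency_rating <- NA_real_
  waves$efficiency_rating[panel_wave] <-
    rtruncnorm(sum(panel_wave), 6, 2, 0, 10)
  waves$intervention_time_hours <- NA_real_
  waves$intervention_time_hours[panel_wave] <- 0
  at_w3 <- which(waves$wave == 3)
  hrs_mean <- config$intervention_time_hours[w_arm[at_w3]]
  waves$intervention_time_hours[at_w3] <-
    stats::rgamma(length(at_w3), shape = 4, scale = hrs_mean / 4)

  set.seed(substream_seed(seed, "utilities"))
  rho <- config$utility_ar_rho
  latent <- matrix(stats::rnorm(n * 4), n, 4)
  for (w in 2:4) {
    latent[, w] <- rho * latent[, w - 1] +
      sqrt(1 - rho^2) * latent[, w]
  }
  for (ins in c("EQ5D", "SF6D")) {
    u <- config$utility[[ins]]
    vals <- matrix(NA_real_, n, 4)
    for (w in 1:4) {
      loc <- u$location[as.character(participants$arm), w] +
        u$slope * participants$symptom_z
      vals[, w] <- qtruncnorm(stats::pnorm(latent[, w]), loc, u$sd,
                              u$floor, 1)
    }
    col <- paste0("utility_", tolower(ins))
    waves[[col]] <- vals[cbind(idx, waves$wave)]
  }

  structure(list(participants = participants, waves = waves,
                 config = config, seed = as.integer(seed)),
            class = "trial_cohort")
}

#' @export
print.trial_cohort <- function(x, ...) {
  n <- table(x$participants$arm)
  cat("Synthetic prevention-trial cohort:",
      sum(n), "participants (",
      paste(names(n), n, sep = " = ", collapse = ", "), ")\n")
  cat("Waves:", length(unique(x$waves$wave)),
      "| observed participant-waves:", sum(x$waves$observed), "\n")
  invisible(x)
}

#' Superimpose monotone missing-at-random dropout on a cohort
#'
#' Dropout at each follow-up wave is Bernoulli with a logit linear in
#' baseline symptom severity; once a participant drops out all later waves
#' are missing. Unobserved waves have their utilities and resource-use
#' quantities set to NA. Onset interviews are treated as complete
#' (intention-to-treat effect data).
#'
#' @param cohort a `trial_cohort`.
#' @param dropout_prob_by_wave_and_arm 3 x 2 matrix of marginal conditional
#'   dropout probabilities (defaults to the cohort's config).
#' @param seed seed for the dropout stream (default: cohort seed).
#' @return the cohort with updated `observed` flags and masked values.
#' @export
apply_missingness <- function(cohort,
                              dropout_prob_by_wave_and_arm = NULL,
                              seed = cohort$seed) {
  stopifnot(inherits(cohort, "trial_cohort"))
  config <- cohort$config
  if (is.null(dropout_prob_by_wave_and_arm)) {
    intercepts <- config$dropout_intercepts
  } else {
    stopifnot(all(dropout_prob_by_wave_and_arm >= 0),
              all(dropout_prob_by_wave_and_arm <= 1))
    colnames(dropout_prob_by_wave_and_arm) <- c("intervention", "control")
    intercepts <- apply(dropout_prob_by_wave_and_arm, 1:2,
                        logit_intercept_for_mean,
                        beta = config$dropout_symptom_beta)
  }
  p <- cohort$participants
  n <- nrow(p)
  set.seed(substream_seed(seed, "dropout"))
  observed <- matrix(TRUE, n, 4)
  beta <- config$dropout_symptom_beta
  for (w in 2:4) {
    l <- intercepts[w - 1, as.character(p$arm)]
    p_drop <- ifelse(is.finite(l), stats::plogis(l + beta * p$symptom_z), 0)
    drop_now <- stats::runif(n) < p_drop
    observed[, w] <- observed[, w - 1] & !drop_now
  }
  waves <- cohort$waves
  idx <- match(waves$id, p$id)
  waves$observed <- observed[cbind(idx, waves$wave)]
  mask_cols <- c(panel_fields(), "utility_eq5d", "utility_sf6d")
  for (col in mask_cols) {
    waves[[col]][!waves$observed] <- NA_real_
  }
  cohort$waves <- waves
  cohort
}

#' Closed-form expectations implied by a generator configuration
#'
#' `expected_annual_costs()` returns the per-arm expected annual cost per
#' category (the calibration targets plus the program-cost constants);
#' `expected_delta_cost()` and `expected_delta_dfy()` give the implied
#' incremental cost (per perspective) and incremental depression-free
#' years, used as ground truth in parameter-recovery checks.
#'
#' @param config a [synthetic_trial_config()].
#' @return matrix (categories x arms) of euro expectations.
#' @export
expected_annual_costs <- function(config) {
  prices <- config$prices
  rbind(intervention = c(intervention = prices$intervention_cost,
                         control = prices$control_program_cost),
        config$annual_cost_targets)
}

#' @rdname expected_annual_costs
#' @param perspective `"societal"` or `"health_care"`.
#' @export
expected_delta_cost <- function(config, perspective = "societal") {
  costs <- expected_annual_costs(config)
  keep <- intersect(rownames(costs), switch(perspective,
    societal = societal_categories(),
    health_care = health_care_categories(),
    stop("unknown perspective: ", perspective)))
  sum(costs[keep, "intervention"]) - sum(costs[keep, "control"])
}

#' @rdname expected_annual_costs
#' @export
expected_delta_dfy <- function(config) {
  m <- rmst_exponential(config$onset_hazard_per_week, WEEKS_PER_YEAR)
  unname((m[["intervention"]] - m[["control"]]) / WEEKS_PER_YEAR)
}

#' Write or read a cohort as plain CSV files
#'
#' Two files are written: `<stem>_participants.csv` (one row per
#' participant) and `<stem>_waves.csv` (one row per participant-wave).
#'
#' @param cohort a `trial_cohort`.
#' @param stem path stem for the two CSV files.
#' @return `write_cohort()` the paths invisibly; `read_cohort()` a
#'   `trial_cohort` (without generator config).
#' @export
write_cohort <- function(cohort, stem) {
  pp <- file.path(paste0(stem, "_participants.csv"))
  wp <- file.path(paste0(stem, "_waves.csv"))
  p <- cohort$participants
  p$arm <- as.character(p$arm)
  utils::write.csv(p, pp, row.names = FALSE)
  utils::write.csv(cohort$waves, wp, row.names = FALSE)
  invisible(c(participants = pp, waves = wp))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(stem) {
  pp <- paste0(stem, "_participants.csv")
  wp <- paste0(stem, "_waves.csv")
  for (f in c(pp, wp)) {
    if (!file.exists(f)) stop("cohort file not found: ", f)
  }
  p <- utils::read.csv(pp, stringsAsFactors = FALSE)
  need <- c("id", "arm", "onset_day", "event")
  if (!all(need %in% names(p))) {
    stop("participant file lacks columns: ",
         paste(setdiff(need, names(p)), collapse = ", "))
  }
  p$arm <- factor(p$arm, levels = c("intervention", "control"))
  w <- utils::read.csv(wp, stringsAsFactors = FALSE)
  structure(list(participants = p, waves = w, config = NULL, seed = NA),
            class = "trial_cohort")
}
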