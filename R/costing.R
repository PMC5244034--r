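# Costing: resource-use quantities -> per-category euro amounts.
#
# Categories mirror the cost table of the evaluation: one program-cost row,
# direct medical rows, patient/family rows and productivity rows. Participant
# time spent on the program (opportunity cost) is computed as its own
# category but excluded from both perspective totals by default.

#' Cost-category names and perspective membership
#'
#' @return character vector of category names.
#' @export
cost_categories <- function() {
  c("intervention", "gp_internist", "mental_health", "other_specialist",
    "inpatient", "daycare", "antidepressants", "private_therapist",
    "copayments", "otc", "informal_care", "domestic_help", "travel",
    "absenteeism", "presenteeism", "opportunity_time")
}

health_care_categories <- function() {
  c("intervention", "gp_internist", "mental_health", "other_specialist",
    "inpatient", "daycare", "antidepressants", "copayments", "otc")
}

societal_categories <- function() {
  setdiff(cost_categories(), "opportunity_time")
}

# Resource-use panel columns expected by the costing functions.
panel_fields <- function() {
  c("gp_visits", "internist_visits", "psychiatrist_sessions",
    "psychotherapist_sessions", "other_specialist_contacts",
    "inpatient_mental_days", "inpatient_psychosomatic_days", "daycare_days",
    "antidepressant_days", "private_therapist_spend", "copayments_spend",
    "otc_spend", "informal_care_hours", "domestic_help_hours", "travel_km",
    "absent_days", "presenteeism_days", "efficiency_rating",
    "intervention_time_hours")
}

#' Cost health-care contacts, hospital stays, day care and travel
#'
#' Each category is the reported quantity multiplied by its unit price:
#' GP and internal-medicine visits form one combined primary-care category,
#' psychiatrist and psychotherapist sessions form the mental-health category,
#' and the two hospital settings (mental hospital, psychosomatic medicine)
#' form the in-patient category.
#'
#' @param panel data.frame with the resource-use quantity columns (see
#'   [panel_fields()]); rows are participant-waves.
#' @param prices a [unit_price_table()].
#' @return data.frame with columns `gp_internist`, `mental_health`,
#'   `other_specialist`, `inpatient`, `daycare`, `travel` (euro).
#' @export
cost_contacts <- function(panel, prices) {
  need <- c("gp_visits", "internist_visits", "psychiatrist_sessions",
            "psychotherapist_sessions", "other_specialist_contacts",
            "inpatient_mental_days", "inpatient_psychosomatic_days",
            "daycare_days", "travel_km")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    stop("resource-use panel lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  check_nonneg(panel[need])
  data.frame(
    gp_internist = panel$gp_visits * prices$gp +
      panel$internist_visits * prices$internist,
    mental_health = panel$psychiatrist_sessions * prices$psychiatrist +
      panel$psychotherapist_sessions * prices$psychotherapist,
    other_specialist = panel$other_specialist_contacts *
      prices$other_specialist,
    inpatient = panel$inpatient_mental_days * prices$inpatient_mental +
      panel$inpatient_psychosomatic_days * prices$inpatient_psychosomatic,
    daycare = panel$daycare_days * prices$daycare,
    travel = panel$travel_km * prices$travel
  )
}

check_nonneg <- function(df) {
  bad <- vapply(df, function(x) any(x < 0, na.rm = TRUE), logical(1))
  if (any(bad)) {
    stop("negative resource-use quantities in: ",
         paste(names(df)[bad], collapse = ", "))
  }
  invisible(df)
}

#' Price antidepressant use from package prices
#'
#' The per-day price of the agent is the mean over the three largest
#' packages of the statutory/private-weighted pharmacy retail price divided
#' by the days covered by the package (its defined daily doses). Medication
#' cost is the per-day price times the days of use.
#'
#' @param packages data.frame with columns `price_statutory`,
#'   `price_private` (euro per package) and `ddd` (defined daily doses per
#'   package); exactly three rows by convention.
#' @param days_supplied days of antidepressant use (vectorised).
#' @param statutory_share statutorily insured population share (default 0.89).
#' @return euro amount, same length as `days_supplied`.
#' @export
cost_medication <- function(packages, days_supplied, statutory_share = 0.89) {
  stopifnot(all(c("price_statutory", "price_private", "ddd") %in%
                  names(packages)))
  if (any(packages$ddd <= 0)) stop("invalid price record: zero daily dose")
  if (any(days_supplied < 0, na.rm = TRUE)) {
    stop("days supplied must be non-negative")
  }
  per_day <- medication_daily_price(packages, statutory_share)
  per_day * days_supplied
}

medication_daily_price <- function(packages, statutory_share = 0.89) {
  weighted <- statutory_share * packages$price_statutory +
    (1 - statutory_share) * packages$price_private
  mean(weighted / packages$ddd)
}

#' Value productivity losses under the human capital approach
#'
#' Absenteeism: work days lost times the participant's gross daily wage.
#' Presenteeism: work days with reduced functioning, weighted by the
#' inefficiency on those days (one minus the 0-10 efficiency rating divided
#' by 10), times the gross daily wage.
#'
#' @param absent_days,presenteeism_days day counts (vectorised).
#' @param gross_daily_wage euro per work day.
#' @param efficiency_rating self-rated efficiency on affected days, 0 (no
#'   output) to 10 (fully efficient).
#' @return euro amount.
#' @export
value_absenteeism <- function(absent_days, gross_daily_wage) {
  if (any(absent_days < 0, na.rm = TRUE) ||
      any(gross_daily_wage < 0, na.rm = TRUE)) {
    stop("absenteeism inputs must be non-negative")
  }
  absent_days * gross_daily_wage
}

#' @rdname value_absenteeism
#' @export
value_presenteeism <- function(presenteeism_days, efficiency_rating,
                               gross_daily_wage) {
  if (any(efficiency_rating < 0 | efficiency_rating > 10, na.rm = TRUE)) {
    stop("invalid record: efficiency rating outside [0, 10]")
  }
  if (any(presenteeism_days < 0, na.rm = TRUE)) {
    stop("presenteeism days must be non-negative")
  }
  presenteeism_days * (1 - efficiency_rating / 10) * gross_daily_wage
}

#' Value unpaid work at a shadow price
#'
#' Used for informal care by family and friends and for paid-for domestic
#' help alike, at EUR 18.33 per hour by default.
#'
#' @param hours hours of unpaid work (vectorised).
#' @param shadow_price euro per hour.
#' @return euro amount.
#' @export
value_unpaid <- function(hours, shadow_price = 18.33) {
  if (any(hours < 0, na.rm = TRUE)) stop("hours must be non-negative")
  hours * shadow_price
}

#' Full per-wave cost breakdown of a resource-use panel
#'
#' Applies all costing rules to a panel of participant-wave quantities.
#' The program-cost category (`intervention`) is a per-participant annual
#' constant and is therefore not part of the wave-level breakdown; it is
#' added when annualising (see [annual_cost_breakdown()]).
#'
#' @inheritParams cost_contacts
#' @param gross_daily_wage euro per work day, one value per panel row.
#' @return data.frame with one euro column per wave-level category.
#' @export
panel_cost_breakdown <- function(panel, prices, gross_daily_wage) {
  out <- cost_contacts(panel, prices)
  out$antidepressants <- cost_medication(prices$antidepressant_packages,
                                         panel$antidepressant_days,
                                         prices$statutory_share)
  out$private_therapist <- pass_through_amount(panel$private_therapist_spend)
  out$copayments <- pass_through_amount(panel$copayments_spend)
  out$otc <- pass_through_amount(panel$otc_spend)
  out$informal_care <- value_unpaid(panel$informal_care_hours,
                                    prices$informal_care)
  out$domestic_help <- value_unpaid(panel$domestic_help_hours,
                                    prices$domestic_help)
  out$absenteeism <- value_absenteeism(panel$absent_days, gross_daily_wage)
  out$presenteeism <- value_presenteeism(panel$presenteeism_days,
                                         panel$efficiency_rating,
                                         gross_daily_wage)
  out$opportunity_time <- value_unpaid(panel$intervention_time_hours,
                                       prices$opportunity_cost)
  out
}

pass_through_amount <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("euro amounts must be non-negative")
  x
}

#' Total a cost breakdown under a costing perspective
#'
#' The health-care perspective totals the direct medical categories
#' (program cost, primary care, mental health care, other specialists,
#' in-patient, day care, antidepressants, co-payments and over-the-counter
#' drugs). The societal perspective adds patient/family categories and
#' productivity losses. Participant time on the program is excluded from
#' both unless `include_opportunity` is set.
#'
#' @param breakdown data.frame or named vector with one entry per category
#'   of [cost_categories()] (missing categories count as zero).
#' @param perspective `"societal"` or `"health_care"`.
#' @param include_opportunity include the participant-time category.
#' @return numeric total, one per breakdown row.
#' @export
#' @examples
#' ctrl <- c(intervention = 10, gp_internist = 117, mental_health = 175,
#'           other_specialist = 236, inpatient = 123, daycare = 35,
#'           antidepressants = 20, copayments = 30, otc = 22)
#' aggregate_costs(ctrl, "health_care") # 768
aggregate_costs <- function(breakdown, perspective = c("societal",
                                                       "health_care"),
                            include_opportunity = FALSE) {
  perspective <- match.arg(perspective)
  if (is.null(dim(breakdown))) breakdown <- as.data.frame(as.list(breakdown))
  unknown <- setdiff(names(breakdown), cost_categories())
  if (length(unknown)) {
    stop("unknown cost categories: ", paste(unknown, collapse = ", "))
  }
  keep <- switch(perspective,
                 societal = societal_categories(),
                 health_care = health_care_categories())
  if (include_opportunity) keep <- c(keep, "opportunity_time")
  keep <- intersect(keep, names(breakdown))
  if (!length(keep)) return(rep(0, nrow(breakdown)))
  rowSums(as.matrix(breakdown[keep]), na.rm = FALSE)
}
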