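# Shared fixtures: small configurations and hand-constructed tables.

small_config <- function(n = 150, ...) {
  synthetic_trial_config(n_intervention = n, n_control = n, ...)
}

# Minimal per-participant cost/effect table for the CEA engine, with
# hand-settable values.
toy_cea_table <- function(cost_int, cost_ctr, eff_int, eff_ctr) {
  n1 <- length(cost_int)
  n0 <- length(cost_ctr)
  data.frame(
    id = sprintf("T%03d", seq_len(n1 + n0)),
    arm = factor(rep(c("intervention", "control"), c(n1, n0)),
                 levels = c("intervention", "control")),
    cost_societal = c(cost_int, cost_ctr),
    cost_health_care = c(cost_int, cost_ctr),
    dfy = c(eff_int, eff_ctr),
    qaly_eq5d = c(eff_int, eff_ctr),
    qaly_sf6d = c(eff_int, eff_ctr)
  )
}

# All-zero resource-use panel with n rows; individual fields can be set.
zero_panel <- function(n = 1, ...) {
  panel <- as.data.frame(
    matrix(0, nrow = n, ncol = length(prevcea:::panel_fields()),
           dimnames = list(NULL, prevcea:::panel_fields()))
  )
  panel$efficiency_rating <- 10
  over <- list(...)
  for (nm in names(over)) panel[[nm]] <- over[[nm]]
  panel
}

# Arm-mean cost breakdowns of the published cost table (euro), used for
# perspective-composition checks.
reference_cost_means <- function(arm = c("control", "intervention")) {
  arm <- match.arg(arm)
  if (arm == "control") {
    c(intervention = 10, gp_internist = 117, mental_health = 175,
      other_specialist = 236, inpatient = 123, daycare = 35,
      antidepressants = 20, private_therapist = 117, copayments = 30,
      otc = 22, informal_care = 384, domestic_help = 120, travel = 28,
      absenteeism = 1172, presenteeism = 2021)
  } else {
    c(intervention = 299, gp_internist = 142, mental_health = 117,
      other_specialist = 243, inpatient = 48, daycare = 0,
      antidepressants = 12, private_therapist = 137, copayments = 27,
      otc = 17, informal_care = 323, domestic_help = 143, travel = 29,
      absenteeism = 1475, presenteeism = 1696)
  }
}
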