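# Pipeline orchestration and table rendering: simulate -> cost -> impute ->
# effects -> CEA -> report.

#' Analysis configuration for the evaluation pipeline
#'
#' @param perspectives costing perspectives to analyse.
#' @param effects effect measures for the main analysis (`dfy` for the
#'   cost-effectiveness analysis, `qaly_eq5d` for the cost-utility
#'   analysis).
#' @param B bootstrap replicates (default 2500).
#' @param seed master seed.
#' @param lambda_grid willingness-to-pay grid (euro; default 0-50,000 by
#'   50, covering every ceiling quoted in the results).
#' @param sensitivity_sf6d add the SF-6D QALY sensitivity analysis.
#' @param sensitivity_drop_hospital add the analysis with hospitalization
#'   costs removed.
#' @param extrapolation_factor recall-window scaling (default 2).
#' @param include_opportunity include participant program time in totals.
#' @param prices a [unit_price_table()].
#' @param cohort_config a [synthetic_trial_config()] used when no cohort
#'   is supplied to [run_pipeline()].
#' @param currency `"eur"` or `"gbp"` for displayed totals.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(perspectives = c("societal", "health_care"),
                            effects = c("dfy", "qaly_eq5d"),
                            B = 2500,
                            seed = 20130301L,
                            lambda_grid = seq(0, 50000, by = 50),
                            sensitivity_sf6d = TRUE,
                            sensitivity_drop_hospital = TRUE,
                            extrapolation_factor = 2,
                            include_opportunity = FALSE,
                            prices = unit_price_table(),
                            cohort_config = NULL,
                            currency = c("eur", "gbp")) {
  stopifnot(B > 0, all(lambda_grid >= 0), extrapolation_factor > 0)
  perspectives <- match.arg(perspectives, several.ok = TRUE)
  effects <- match.arg(effects, c("dfy", "qaly_eq5d", "qaly_sf6d"),
                       several.ok = TRUE)
  if (is.null(cohort_config)) {
    cohort_config <- synthetic_trial_config(prices = prices, seed = seed)
  }
  structure(list(
    perspectives = perspectives, effects = effects,
    B = as.integer(B), seed = as.integer(seed),
    lambda_grid = lambda_grid,
    sensitivity_sf6d = isTRUE(sensitivity_sf6d),
    sensitivity_drop_hospital = isTRUE(sensitivity_drop_hospital),
    extrapolation_factor = extrapolation_factor,
    include_opportunity = isTRUE(include_opportunity),
    prices = prices, cohort_config = cohort_config,
    currency = match.arg(currency)
  ), class = "analysis_config")
}

#' Cost table: per-category arm means, SDs and incremental costs
#'
#' The Table-1-style report of mean annual per-participant costs by
#' condition: per-category means and SDs per arm, the intervention-minus-
#' control incremental column and perspective totals, plus whole-euro
#' display columns.
#'
#' @param table output of [participant_analysis_table()].
#' @return data.frame with raw and display-rounded columns.
#' @export
build_cost_table <- function(table) {
  arm <- factor(table$arm, levels = c("intervention", "control"))
  rows <- c(cost_categories(), "total_health_care", "total_societal")
  vals <- table[cost_categories()]
  vals$total_health_care <- table$cost_health_care
  vals$total_societal <- table$cost_societal
  out <- data.frame(category = rows, stringsAsFactors = FALSE)
  for (a in levels(arm)) {
    sub <- vals[arm == a, , drop = FALSE]
    out[[paste0("mean_", a)]] <- vapply(rows, function(r) mean(sub[[r]]),
                                        numeric(1))
    out[[paste0("sd_", a)]] <- vapply(rows, function(r) stats::sd(sub[[r]]),
                                      numeric(1))
  }
  out$incremental <- out$mean_intervention - out$mean_control
  for (col in c("mean_intervention", "mean_control", "incremental")) {
    out[[paste0("display_", col)]] <- euro_round(out[[col]])
  }
  out
}

#' CEA summary table over analysis variants
#'
#' One row per analysis x perspective: incremental cost and effect with
#' percentile intervals, the mean ICER with its angular-percentile
#' interval (or an undefined-interval marker when no ray through the
#' origin excludes alpha/2 of the replicates on each side), and the
#' quadrant distribution of the bootstrap cloud.
#'
#' @param boots named list of `cea_bootstrap` objects; names label the
#'   analysis variants.
#' @param alpha two-sided error rate for intervals.
#' @return data.frame with raw columns and display-rounded columns
#'   (whole-euro costs and ICERs, two-decimal effects, whole-percent
#'   quadrant shares; `icer_ci` shows `"undefined"` when footnoted).
#' @export
build_cea_table <- function(boots, alpha = 0.05) {
  rows <- lapply(names(boots), function(nm) {
    bt <- boots[[nm]]
    est <- bt$estimate
    ciC <- percentile_ci(bt$replicates$delta_cost, alpha)
    ciE <- percentile_ci(bt$replicates$delta_effect, alpha)
    ciI <- icer_percentile_ci(bt, alpha)
    q <- quadrant_shares(bt)
    point_icer <- icer(est$delta_cost, est$delta_effect)
    data.frame(
      analysis = nm, perspective = bt$perspective, effect = bt$effect,
      delta_cost = est$delta_cost,
      delta_cost_lo = ciC[1], delta_cost_hi = ciC[2],
      delta_effect = est$delta_effect,
      delta_effect_lo = ciE[1], delta_effect_hi = ciE[2],
      icer = point_icer,
      icer_lo = ciI$lower, icer_hi = ciI$upper,
      icer_ci_defined = ciI$defined,
      share_ne = q[["NE"]], share_nw = q[["NW"]],
      share_se = q[["SE"]], share_sw = q[["SW"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$display_delta_cost <- sprintf(
    "%d (%d to %d)", euro_round(out$delta_cost),
    euro_round(out$delta_cost_lo), euro_round(out$delta_cost_hi))
  out$display_delta_effect <- sprintf(
    "%.2f (%.2f to %.2f)", out$delta_effect,
    out$delta_effect_lo, out$delta_effect_hi)
  out$display_icer <- ifelse(
    is.na(out$icer), "undefined",
    ifelse(out$icer_ci_defined,
           sprintf("%d (%d to %d)", euro_round(out$icer),
                   euro_round(out$icer_lo), euro_round(out$icer_hi)),
           sprintf("%d (undefined)", euro_round(out$icer))))
  for (qn in c("ne", "nw", "se", "sw")) {
    out[[paste0("display_share_", qn)]] <-
      round(100 * out[[paste0("share_", qn)]])
  }
  out
}

variant_plan <- function(config) {
  plan <- expand.grid(effect = config$effects,
                      perspective = config$perspectives,
                      drop_hospital = FALSE,
                      stringsAsFactors = FALSE)
  if (config$sensitivity_sf6d) {
    plan <- rbind(plan, expand.grid(effect = "qaly_sf6d",
                                    perspective = config$perspectives,
                                    drop_hospital = FALSE,
                                    stringsAsFactors = FALSE))
  }
  if (config$sensitivity_drop_hospital) {
    plan <- rbind(plan, expand.grid(effect = intersect(config$effects,
                                                       c("dfy", "qaly_eq5d")),
                                    perspective = config$perspectives,
                                    drop_hospital = TRUE,
                                    stringsAsFactors = FALSE))
  }
  plan$label <- paste0(plan$effect,
                       ifelse(plan$drop_hospital, "_no_hospital", ""),
                       "_", plan$perspective)
  plan
}

#' Run the full economic-evaluation pipeline
#'
#' Simulates (or takes) a cohort, applies costing and regression
#' imputation, constructs effects, bootstraps every configured analysis
#' variant and writes the report bundle: cost table, CEA table, one
#' replicate-scatter CSV and one CEAC CSV per variant, the survival
#' summary, the imputation audit log and a run log. Deterministic per
#' `(config, cohort, seed)`.
#'
#' @param config an [analysis_config()].
#' @param cohort optional `trial_cohort`; when NULL a synthetic cohort is
#'   generated from `config$cohort_config` and missingness applied.
#' @param out_dir output directory (created if needed); when NULL nothing
#'   is written.
#' @return list with `cohort`, `table` (participant analysis table),
#'   `cost_table`, `cea_table`, `boots`, `ceac_curves`, `survival`,
#'   `files`.
#' @export
run_pipeline <- function(config = analysis_config(), cohort = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$cohort_config, seed = config$seed)
    cohort <- apply_missingness(cohort, seed = config$seed)
  }
  tables <- list(
    main = participant_analysis_table(
      cohort, config$prices,
      extrapolation_factor = config$extrapolation_factor,
      drop_hospital = FALSE,
      include_opportunity = config$include_opportunity),
    no_hospital = NULL
  )
  plan <- variant_plan(config)
  if (any(plan$drop_hospital)) {
    tables$no_hospital <- participant_analysis_table(
      cohort, config$prices,
      extrapolation_factor = config$extrapolation_factor,
      drop_hospital = TRUE,
      include_opportunity = config$include_opportunity)
  }
  boots <- list()
  ceac_curves <- list()
  for (i in seq_len(nrow(plan))) {
    tab <- if (plan$drop_hospital[i]) tables$no_hospital else tables$main
    bseed <- substream_seed(config$seed, paste0("cea_", plan$label[i]))
    boots[[plan$label[i]]] <- bootstrap_cea(
      tab, B = config$B, seed = bseed,
      perspective = plan$perspective[i], effect = plan$effect[i])
    ceac_curves[[plan$label[i]]] <- ceac(boots[[plan$label[i]]],
                                         config$lambda_grid)
  }
  cost_table <- build_cost_table(tables$main)
  cea_table <- build_cea_table(boots)
  surv <- restricted_mean_survival(survival_records(cohort))
  cox <- tryCatch(fit_cox(survival_records(cohort)),
                  error = function(e) NULL)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      path <- file.path(out_dir, name)
      utils::write.csv(df, path, row.names = FALSE)
      path
    }
    files <- c(files, wr(cost_table, "cost_table.csv"))
    files <- c(files, wr(cea_table, "cea_table.csv"))
    files <- c(files, wr(surv, "survival_summary.csv"))
    if (!is.null(cox)) files <- c(files, wr(cox$hr_table, "cox_hr.csv"))
    audit <- attr(tables$main, "imputation_audit")
    if (!is.null(audit) && nrow(audit)) {
      files <- c(files, wr(audit, "imputation_audit.csv"))
    }
    for (nm in names(boots)) {
      files <- c(files, wr(boots[[nm]]$replicates,
                           sprintf("scatter_%s.csv", nm)))
      files <- c(files, wr(as.data.frame(ceac_curves[[nm]]),
                           sprintf("ceac_%s.csv", nm)))
    }
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(c(
      sprintf("prevcea %s", as.character(utils::packageVersion("prevcea"))),
      sprintf("seed %d", config$seed),
      sprintf("B %d", config$B),
      sprintf("participants %d", nrow(tables$main)),
      sprintf("variants %s", paste(plan$label, collapse = " "))
    ), log_path)
    files <- c(files, log_path)
  }
  list(cohort = cohort, table = tables$main, cost_table = cost_table,
       cea_table = cea_table, boots = boots, ceac_curves = ceac_curves,
       survival = surv, cox = cox, files = files)
}
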