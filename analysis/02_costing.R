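#!/usr/bin/env Rscript
# Step 2: value the observed resource use. Produces the complete-case view
# of annual per-participant costs by category (before imputation), for
# comparison with the post-imputation cost table of step 3.

library(prevcea)

cohort <- read_cohort("results/analysis/cohort")
prices <- read_price_table("results/analysis/unit_prices.yaml")

frame <- build_analysis_frame(cohort, prices)
complete <- !is.na(frame$cost_gp_internist_w4) &
  !is.na(frame$cost_gp_internist_w3)
message(sprintf("complete cost data: %d of %d participants (%.1f%%)",
                sum(complete), nrow(frame),
                pct(sum(complete), nrow(frame))))

cc <- cohort
cc$participants <- cc$participants[cc$participants$id %in%
                                     frame$id[complete], ]
cc$waves <- cc$waves[cc$waves$id %in% frame$id[complete], ]
tab_cc <- participant_analysis_table(cc, prices, impute = FALSE)
cost_cc <- build_cost_table(tab_cc)
write.csv(cost_cc, "results/analysis/cost_table_complete_case.csv",
          row.names = FALSE)

hc <- cost_cc[cost_cc$category == "total_health_care", ]
soc <- cost_cc[cost_cc$category == "total_societal", ]
message(sprintf("complete-case annual health-care costs: %d vs %d EUR",
                euro_round(hc$mean_intervention),
                euro_round(hc$mean_control)))
message(sprintf("complete-case annual societal costs: %d vs %d EUR",
                euro_round(soc$mean_intervention),
                euro_round(soc$mean_control)))
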