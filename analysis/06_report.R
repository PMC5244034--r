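#!/usr/bin/env Rscript
# Step 6: headline report. Pulls the machine-readable outputs of steps 3-5
# into the two display tables (annual costs by category; CEA summary per
# analysis x perspective) and prints the decision-relevant quantities:
# ICER per depression-free year, plane quadrant shares and the probability
# of cost-effectiveness at quoted willingness-to-pay ceilings.

library(prevcea)

cost <- read.csv("results/analysis/cost_table.csv")
cea <- read.csv("results/analysis/cea/cea_table.csv")

disp <- cost[c("category", "display_mean_intervention", "sd_intervention",
               "display_mean_control", "sd_control",
               "display_incremental")]
names(disp) <- c("category", "mean_intervention_eur", "sd_intervention",
                 "mean_control_eur", "sd_control", "incremental_eur")
disp$sd_intervention <- round(disp$sd_intervention)
disp$sd_control <- round(disp$sd_control)
write.csv(disp, "results/analysis/table_costs_display.csv",
          row.names = FALSE)

cea_disp <- cea[c("analysis", "perspective", "effect",
                  "display_delta_cost", "display_delta_effect",
                  "display_icer", "display_share_ne", "display_share_nw",
                  "display_share_se", "display_share_sw")]
write.csv(cea_disp, "results/analysis/table_cea_display.csv",
          row.names = FALSE)

message("Mean annual per-participant costs (EUR):")
for (r in c("intervention", "total_health_care", "total_societal")) {
  row <- disp[disp$category == r, ]
  message(sprintf("  %-18s %6s vs %6s (incremental %s)", r,
                  row$mean_intervention_eur, row$mean_control_eur,
                  row$incremental_eur))
}

message("CEA summary (per analysis x perspective):")
for (i in seq_len(nrow(cea_disp))) {
  message(sprintf("  %-28s ICER %s  NE/SE %s%%/%s%%", cea_disp$analysis[i],
                  cea_disp$display_icer[i], cea_disp$display_share_ne[i],
                  cea_disp$display_share_se[i]))
}

for (variant in c("dfy_societal", "dfy_health_care")) {
  curve <- read.csv(sprintf("results/analysis/cea/ceac_%s.csv", variant))
  for (wtp in c(0, 7350, 9680, 20000)) {
    j <- which.min(abs(curve$lambda - wtp)) # nearest grid point
    message(sprintf(
      "  P(cost-effective | WTP %5d EUR/DFY, %s) = %.0f%%",
      wtp, sub("dfy_", "", variant), 100 * curve$probability[j]))
  }
}
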