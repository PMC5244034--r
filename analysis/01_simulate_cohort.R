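#!/usr/bin/env Rscript
# Step 1: simulate the two-arm prevention trial at the study conditions
# (202 intervention / 204 control, 12-month horizon) and superimpose
# monotone missing-at-random dropout. Writes the cohort CSVs that the
# later steps read.

library(prevcea)

seed <- 20130301L
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_trial_config(seed = seed)
cohort <- apply_missingness(generate_cohort(cfg), seed = seed)
write_cohort(cohort, "results/analysis/cohort")
write_price_table(cfg$prices, "results/analysis/unit_prices.yaml")

p <- cohort$participants
w4 <- cohort$waves[cohort$waves$wave == 4, ]
message(sprintf("simulated %d participants (%d intervention, %d control)",
                nrow(p), sum(p$arm == "intervention"),
                sum(p$arm == "control")))
message(sprintf("onsets: %d (%.1f%%); 12-month retention %.1f%%",
                sum(p$event), pct(sum(p$event), nrow(p)),
                pct(sum(w4$observed), nrow(p))))
message(sprintf("configured mean depression-free weeks: %.0f vs %.0f",
                cfg$target_mean_dfw[["intervention"]],
                cfg$target_mean_dfw[["control"]]))
message("cohort written to results/analysis/cohort_{participants,waves}.csv")
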