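#!/usr/bin/env Rscript
# Stage 1 -- simulate a deforestation-frontier landscape with known truth.
#
# A 100 x 100 pixel landscape (0.09 ha Landsat pixels, 21 irregular dates
# 1984-2011) evolves per pixel as MF -> clearance -> active use (NF) ->
# abandonment -> SF, with SF facing reclearance. Defaults emulate a
# Rondonia-style frontier: 4%/yr MF clearance, ~2 yr of active use, 15%/yr
# SF reclearance, 91/1/9% initial MF/NF/SF mix.

library(lcctraj)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- simulation_config(shape = c(100, 100), seed = 42)
sim <- simulate_stack(cfg)

prop <- landcover_proportion_table(sim$stack)
write.csv(prop, "results/01_true_landcover_proportions.csv",
          row.names = FALSE)

cat("Simulated", n_dates(sim$stack), "dates over",
    round(decimal_years(sim$stack$dates[1],
                        sim$stack$dates[n_dates(sim$stack)]), 1),
    "years\n")
cat(sprintf("MF declined from %.0f%% to %.0f%%; SF grew from %.0f%% to %.0f%%\n",
            prop$MF[1], prop$MF[nrow(prop)], prop$SF[1], prop$SF[nrow(prop)]))

# persist the true stack and truth tables for the later stages
write_stack(sim$stack, "scratch/true_stack", prefix = "true")
truth_df <- as_trajectory_df(sim$truth)
write.csv(truth_df, "scratch/trajectory_truth.csv", row.names = FALSE)
cat("Wrote true stack to scratch/true_stack and",
    nrow(truth_df), "truth rows\n")
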