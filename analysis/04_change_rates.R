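#!/usr/bin/env Rscript
# Stage 4 -- deforestation and regrowth rates, summaries and period typology.
#
# Per consecutive-date pair: MF clearance (log-area rate), SF reclearance
# and NF -> SF regrowth (transition-fraction rates), absolute rates in
# ha/yr, distribution summaries, and the a-f land-use dynamics indicators.

library(lcctraj)

stack <- read_stack("scratch/corrected_stack/corr_manifest.csv")

rates <- period_rate_table(stack)
summ <- summarize_rates(rates)
write.csv(rates, "results/04_period_rates.csv", row.names = FALSE)
write.csv(summ, "results/04_rate_summary.csv", row.names = FALSE)
cat("Rate summary (magnitudes):\n")
print(summ[summ$unit == "pct_yr", c("process", "min", "max", "mean",
                                    "median", "iqr", "sd")], digits = 3)

indicators <- do.call(rbind, lapply(seq_len(n_dates(stack) - 1), function(k) {
  ind <- classify_period_indicator(
    transition_areas(stack_map(stack, k), stack_map(stack, k + 1)))
  data.frame(t1 = format_ymd(stack$dates[k]),
             t2 = format_ymd(stack$dates[k + 1]),
             clearance = ind$clearance, balance = ind$balance, tie = ind$tie)
}))
write.csv(indicators, "results/04_period_indicators.csv", row.names = FALSE)
cat("\nPeriod typology counts:\n")
print(table(indicators$clearance, indicators$balance))

# proportion trends over the series
prop <- landcover_proportion_table(stack)
trends <- do.call(rbind, lapply(c("MF", "NF", "SF"), function(cl) {
  tr <- ols_trend(prop$year, prop[[cl]])
  data.frame(class = cl, slope_pct_yr = tr$slope, r_squared = tr$r_squared)
}))
write.csv(trends, "results/04_proportion_trends.csv", row.names = FALSE)
cat("\nProportion trends (% per year):\n")
print(trends, digits = 3)
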