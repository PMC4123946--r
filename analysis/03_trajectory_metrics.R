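#!/usr/bin/env Rscript
# Stage 3 -- per-pixel trajectory metrics on the corrected stack.
#
# ASF / PALU / FC are computed for every pixel and date, binned into the
# standard three-class schemes, cross-tabulated (PALU x FC, a land-use
# intensity proxy) and tracked through time as class-share curves.

library(lcctraj)

stack <- read_stack("scratch/corrected_stack/corr_manifest.csv")
metrics <- compute_trajectory_metrics(stack)

ct <- crosstab_palu_fc(stack, metrics)
write.csv(as.data.frame.table(ct, responseName = "pct"),
          "results/03_palu_fc_crosstab.csv", row.names = FALSE)
cat("PALU x FC cross-tab (% of SF area at the last date):\n")
print(round(ct, 1))

for (m in c("asf", "palu", "fc")) {
  cv <- sf_class_proportion_curves(stack, metrics, bin_spec(m))
  write.csv(cv, sprintf("results/03_%s_class_curves.csv", m),
            row.names = FALSE)
}
k <- n_dates(stack)
asf_cls <- bin_metric(metrics$asf[, , k], bin_spec("asf"))
sf_now <- stack$codes[, , k] == LCC_CODES[["SF"]]
shares <- 100 * table(factor(asf_cls[sf_now], bin_spec("asf")$labels)) /
  sum(sf_now)
cat("ASF class shares at the last date (%):\n")
print(round(shares, 1))
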