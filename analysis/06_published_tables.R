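#!/usr/bin/env Rscript
# Stage 6 -- statistics recomputed from the bundled published tables of the
# three Amazon Landsat sites (Manaus, Santarem, Machadinho d'Oeste):
# error-matrix accuracies, crop-overlay incidence and proportion trends.

library(lcctraj)

em <- amazon_error_matrices()
acc <- do.call(rbind, lapply(names(em), function(site) {
  st <- accuracy_stats(em[[site]])
  data.frame(site = site, class = em[[site]]$classes,
             omission = unname(st$omission),
             commission = unname(st$commission), overall = st$overall)
}))
write.csv(acc, "results/06_published_accuracy.csv", row.names = FALSE)
cat("overall accuracies:\n")
print(unique(acc[, c("site", "overall")]), digits = 3)

# Manaus tree-crop overlay: share of the TC area mapped as each class
tc <- amazon_crop_overlay()
tc_man <- tc[tc$site == "manaus", ]
tc_man$share_of_crop_pct <- 100 * tc_man$overlap_ha / sum(tc_man$overlap_ha)
write.csv(tc_man, "results/06_manaus_tc_overlay.csv", row.names = FALSE)
cat(sprintf("\nManaus tree crops: %.0f%% of the %d ha mapped as SF (RI %.1f%% of SF area)\n",
            tc_man$share_of_crop_pct[tc_man$class == "SF"],
            sum(tc_man$overlap_ha), tc_man$ri_pct[tc_man$class == "SF"]))

lc <- amazon_landcover_proportions()
trends <- do.call(rbind, lapply(unique(lc$site), function(site) {
  d <- lc[lc$site == site, ]
  do.call(rbind, lapply(c("MF", "NF", "SF"), function(cl) {
    tr <- ols_trend(d$year, d[[cl]])
    data.frame(site = site, class = cl, slope_pct_yr = tr$slope,
               r_squared = tr$r_squared)
  }))
}))
write.csv(trends, "results/06_published_trends.csv", row.names = FALSE)
cat("\naverage annual change in class proportions (% / yr):\n")
print(trends, digits = 3)
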