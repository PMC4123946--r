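yrs <- function(stack, k1, k2) decimal_years(stack$dates[k1], stack$dates[k2])

one_pixel_metrics <- function(labels, dates = NULL) {
  s <- seq_stack(list(labels), dates)
  list(stack = s, m = compute_trajectory_metrics(s))
}

test_that("ASF accumulates since the onset of the current SF run", {
  r <- one_pixel_metrics(c("MF", "NF", "SF", "SF"),
                         mid_year_dates(2000:2003))
  expect_equal(r$m$asf[1, 1, 3], 0)
  expect_equal(r$m$asf[1, 1, 4], yrs(r$stack, 3, 4))
  expect_equal(r$m$asf[1, 1, 4], 1, tolerance = 0.01)
  expect_false(r$m$asf_censored[1, 1, 4])
  expect_true(is.na(r$m$asf[1, 1, 1]))
})

test_that("SF present since the first date gives a censored minimum age", {
  r <- one_pixel_metrics(c("SF", "SF", "SF"))
  expect_equal(r$m$asf[1, 1, 3], yrs(r$stack, 1, 3))
  expect_true(r$m$asf_censored[1, 1, 3])
  expect_equal(r$m$palu[1, 1, 3], 0)
  expect_true(r$m$palu_zero[1, 1, 3])
})

test_that("ASF resets to zero when an SF run restarts after clearance", {
  r <- one_pixel_metrics(c("SF", "NF", "SF"))
  expect_equal(r$m$asf[1, 1, 3], 0)
  expect_false(r$m$asf_censored[1, 1, 3])
})

test_that("PALU is the duration of the preceding NF run", {
  r <- one_pixel_metrics(c("MF", "NF", "NF", "SF"),
                         mid_year_dates(2000:2003))
  expect_equal(r$m$palu[1, 1, 4], yrs(r$stack, 2, 4))
  expect_equal(r$m$palu[1, 1, 4], 2, tolerance = 0.01)
  expect_false(r$m$palu_zero[1, 1, 4])
  # only the most recent NF run counts after reclearance
  r2 <- one_pixel_metrics(c("MF", "NF", "SF", "NF", "NF", "SF"),
                          mid_year_dates(2000:2005))
  expect_equal(r2$m$palu[1, 1, 6], yrs(r2$stack, 4, 6))
  expect_equal(r2$m$palu[1, 1, 6], 2, tolerance = 0.01)
  expect_equal(r2$m$palu[1, 1, 3], yrs(r2$stack, 2, 3))
})

test_that("FC counts observed clearance transitions cumulatively", {
  r <- one_pixel_metrics(c("MF", "NF", "SF", "NF", "SF"))
  expect_equal(r$m$fc[1, 1, ], c(0L, 1L, 1L, 2L, 2L))
  r0 <- one_pixel_metrics(c("MF", "MF", "MF"))
  expect_equal(r0$m$fc[1, 1, 3], 0L)
  # FC is monotone non-decreasing per pixel
  s <- random_stack(nr = 12, nc = 12, nd = 8, seed = 21)
  m <- compute_trajectory_metrics(s)
  fc <- matrix(m$fc, 144, 8)
  expect_true(all(apply(fc, 1, function(v) all(diff(v[!is.na(v)]) >= 0))))
})

test_that("NF at the first date with no later clearance is flagged", {
  r <- one_pixel_metrics(c("NF", "SF", "SF"))
  expect_equal(r$m$fc[1, 1, 3], 0L)
  expect_true(r$m$fc_nf_start[1, 1, 3])
  expect_false(r$m$palu_zero[1, 1, 3])
  # binned into the low FC class
  expect_equal(bin_metric(r$m$fc[1, 1, 3], bin_spec("fc")), "low")
})

test_that("runs continue across NODATA and changes are dated post-gap", {
  r <- one_pixel_metrics(c("SF", "NODATA", "SF"))
  expect_equal(r$m$asf[1, 1, 3], yrs(r$stack, 1, 3))
  expect_true(r$m$asf_censored[1, 1, 3])
  r2 <- one_pixel_metrics(c("MF", "NODATA", "NF", "SF"))
  expect_equal(r2$m$fc[1, 1, 4], 1L)
  expect_equal(r2$m$palu[1, 1, 4], yrs(r2$stack, 3, 4))
})

test_that("metric bins follow the three-class definitions", {
  asf <- bin_spec("asf")
  expect_equal(bin_metric(c(5, 6, 15, 16, 0), asf),
               c("initial", "intermediate", "intermediate", "advanced",
                 "initial"))
  palu <- bin_spec("palu")
  expect_equal(bin_metric(c(2, 3, 4, 5, 0), palu),
               c("short", "medium", "medium", "long", "short"))
  fc <- bin_spec("fc")
  expect_equal(bin_metric(c(0, 1, 2, 3, 7), fc),
               c("low", "low", "medium", "high", "high"))
  # decimal years floor to whole years before binning
  expect_equal(bin_metric(5.9, asf), "initial")
  expect_true(is.na(bin_metric(NA_real_, asf)))
})

test_that("PALU x FC cross-tab percentages sum to 100 with exact margins", {
  sim <- simulate_stack(simulation_config(shape = c(25, 25), seed = 33))
  m <- compute_trajectory_metrics(sim$stack)
  ct <- crosstab_palu_fc(sim$stack, m)
  expect_equal(sum(ct), 100, tolerance = 1e-9)
  k <- n_dates(sim$stack)
  sf_cells <- sim$stack$codes[, , k] == LCC_CODES[["SF"]]
  palu_cls <- bin_metric(m$palu[, , k], bin_spec("palu"))[sf_cells]
  margins <- 100 * table(factor(palu_cls, levels = bin_spec("palu")$labels)) /
    sum(sf_cells)
  expect_equal(unname(rowSums(ct)), as.numeric(margins))
  # degenerate: all SF short/low
  r <- one_pixel_metrics(c("MF", "NF", "SF"))
  ct1 <- crosstab_palu_fc(r$stack, r$m)
  expect_equal(ct1["short", "low"], 100)
  expect_error(crosstab_palu_fc(one_pixel_metrics(c("MF", "MF"))$stack,
                                one_pixel_metrics(c("MF", "MF"))$m),
               "no SF")
})

test_that("land-cover proportions exclude water and sum to 100", {
  g1 <- matrix(LCC_CODES[["MF"]], 10, 10)
  g1[1, ] <- LCC_CODES[["WATER"]]
  g1[2, 1:4] <- LCC_CODES[["NF"]]
  g1[3, 1:5] <- LCC_CODES[["SF"]]
  g2 <- g1
  s <- build_stack(list(land_cover_map(g1, 20000701, 1),
                        land_cover_map(g2, 20010701, 1)))
  pt <- landcover_proportion_table(s)
  expect_equal(pt$MF + pt$NF + pt$SF, c(100, 100))
  expect_equal(pt$MF[1], 100 * 81 / 90)
  expect_equal(pt$NF[1], 100 * 4 / 90)
  # synthetic stack matches the truth tally
  sim <- simulate_stack(simulation_config(shape = c(20, 20), seed = 8))
  pt2 <- landcover_proportion_table(sim$stack)
  k <- 5
  g <- sim$truth$class[, , k]
  them <- sum(g %in% THEMATIC_CODES)
  expect_equal(pt2$SF[k], 100 * sum(g == LCC_CODES[["SF"]]) / them)
})

test_that("OLS trend recovers exact lines and the closed form", {
  tr <- ols_trend(1:10, 2 * (1:10) + 1)
  expect_equal(tr$slope, 2)
  expect_equal(tr$r_squared, 1)
  set.seed(4)
  x <- 1990:2010; y <- rnorm(21)
  tr2 <- ols_trend(x, y)
  expect_equal(tr2$slope, sum((x - mean(x)) * (y - mean(y))) /
                 sum((x - mean(x))^2))
  expect_error(ols_trend(c(1, 2), c(1, 2)), "3 points")
  expect_error(ols_trend(rep(2000, 5), 1:5), "constant-year")
})

test_that("SF class-share curves start all-initial and sum to 100", {
  # 3 pixels abandoned at different times: shares shift initial -> older
  s <- seq_stack(list(c("MF", "NF", "SF", "SF", "SF", "SF", "SF", "SF"),
                      c("MF", "MF", "NF", "SF", "SF", "SF", "SF", "SF"),
                      c("MF", "MF", "MF", "MF", "NF", "SF", "SF", "SF")),
                 mid_year_dates(c(2000, 2002, 2004, 2006, 2008, 2010, 2012,
                                  2016)))
  m <- compute_trajectory_metrics(s)
  cv <- sf_class_proportion_curves(s, m, bin_spec("asf"))
  first <- cv[cv$years_since_onset == 0, ]
  expect_equal(first$share_pct[first$class == "initial"], 100)
  sums <- tapply(cv$share_pct, cv$date, sum)
  expect_true(all(abs(sums - 100) < 0.05))
  # with no reclearance the initial share never increases
  ini <- cv$share_pct[cv$class == "initial"]
  expect_true(all(diff(ini) <= 1e-9))
  # censored-only SF does not define the onset
  s2 <- seq_stack(list(c("SF", "SF", "SF"), c("MF", "NF", "SF")))
  m2 <- compute_trajectory_metrics(s2)
  cv2 <- sf_class_proportion_curves(s2, m2, bin_spec("asf"))
  expect_equal(min(cv2$years_since_onset), -decimal_years(s2$dates[1],
                                                          s2$dates[3]))
  # no SF anywhere: empty series
  s3 <- seq_stack(list(c("MF", "MF")))
  expect_equal(nrow(sf_class_proportion_curves(
    s3, compute_trajectory_metrics(s3), bin_spec("asf"))), 0)
})

test_that("vectorised metrics equal the per-pixel reference tracer", {
  for (seed in c(2, 9)) {
    s <- random_stack(nr = 15, nc = 15, nd = 9, p_nodata = 0.15, seed = seed)
    s <- correct_disallowed_transitions(s)$stack
    met <- compute_trajectory_metrics(s)
    tru <- trace_truth(s)
    for (f in c("asf", "asf_censored", "palu", "palu_zero", "fc",
                "fc_nf_start")) {
      expect_identical(met[[f]], tru[[f]], info = paste(seed, f))
    }
  }
})
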