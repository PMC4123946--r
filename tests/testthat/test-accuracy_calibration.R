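test_that("published error matrices reproduce their printed statistics", {
  em <- amazon_error_matrices()
  st_man <- accuracy_stats(em$manaus)
  expect_equal(st_man$overall, 0.930)
  expect_equal(unname(st_man$omission), c(0.070, 0.075, 0.065))
  expect_equal(unname(st_man$commission), c(8 / 205 + 11 / 205, 6 / 191,
                                            17 / 204), tolerance = 1e-12)
  expect_equal(round(unname(st_man$commission), 3), c(0.093, 0.031, 0.083))
  st_san <- accuracy_stats(em$santarem)
  expect_equal(unname(st_san$omission)[3], 0.170)
  expect_equal(round(unname(st_san$commission), 3)[1], 0.105)
  st_mac <- accuracy_stats(em$machadinho)
  expect_equal(unname(st_mac$omission)[3], 0.280)
  expect_equal(round(unname(st_mac$commission), 3)[2], 0.158)
})

test_that("identity matrix gives zero errors and perfect accuracy", {
  m <- error_matrix(diag(3) * 200)
  st <- accuracy_stats(m)
  expect_equal(st$overall, 1)
  expect_true(all(st$omission == 0))
  expect_true(all(st$commission == 0))
})

test_that("error matrices built from points match hand counts", {
  # map laid out so cell (r, c) has a known class; points reconstruct the
  # published Manaus matrix exactly
  counts <- amazon_error_matrices()$manaus$counts
  grid_labels <- rep(rep(THEMATIC_CLASSES, times = 3),
                     times = as.vector(t(counts)))
  ref_labels <- rep(rep(THEMATIC_CLASSES, each = 3),
                    times = as.vector(t(counts)))
  n <- length(grid_labels)
  g <- matrix(code_vec(grid_labels), n, 1)
  map <- land_cover_map(g, 20070801, 1)
  pts <- data.frame(row = seq_len(n), col = 1, reference = ref_labels)
  built <- build_error_matrix(pts, map)
  expect_equal(built$matrix$counts, counts)
  expect_equal(built$n_excluded, 0)
  # order invariance
  shuf <- pts[sample(n), ]
  expect_equal(build_error_matrix(shuf, map)$matrix$counts, counts)
  # perfect agreement: diagonal matrix
  pts_ok <- data.frame(row = seq_len(n), col = 1, reference = grid_labels)
  st <- accuracy_stats(build_error_matrix(pts_ok, map)$matrix)
  expect_equal(st$overall, 1)
  # points on masked cells are excluded and counted
  g2 <- g; g2[1, 1] <- LCC_CODES[["WATER"]]
  map2 <- land_cover_map(g2, 20070801, 1)
  expect_warning(b2 <- build_error_matrix(pts, map2), "excluded")
  expect_equal(b2$n_excluded, 1)
  expect_equal(sum(b2$matrix$counts), n - 1)
})

test_that("inverse calibration reproduces the two-class hand example", {
  m <- error_matrix(matrix(c(90, 10, 20, 80), 2, 2, byrow = TRUE),
                    classes = c("A", "B"))
  cal <- inverse_calibrate(m, f_j = c(800, 800))
  expect_equal(cal$N, 1800)
  expect_equal(unname(cal$p_naive), c(0.50556, 0.49444), tolerance = 1e-4)
  expect_equal(unname(cal$pi_calibrated),
               c((90 / 110) * (910 / 1800) + (10 / 90) * (890 / 1800),
                 (20 / 110) * (910 / 1800) + (80 / 90) * (890 / 1800)))
  expect_equal(unname(cal$pi_calibrated), c(0.4686, 0.5314), tolerance = 1e-4)
  expect_equal(sum(cal$pi_calibrated), 1, tolerance = 1e-9)
})

test_that("calibration with a diagonal matrix is the identity", {
  m <- error_matrix(diag(c(120, 80, 40)))
  for (f in list(c(0, 0, 0), c(1000, 500, 10), c(5, 5, 5))) {
    cal <- inverse_calibrate(m, f)
    expect_equal(cal$pi_calibrated, cal$p_naive, tolerance = 1e-12)
    expect_equal(sum(cal$pi_calibrated), 1, tolerance = 1e-9)
    expect_true(all(cal$pi_calibrated >= 0))
  }
  bad <- error_matrix(matrix(c(10, 0, 0, 0, 10, 0, 5, 5, 0), 3, 3,
                             byrow = TRUE))
  expect_error(inverse_calibrate(bad, c(1, 1, 1)), "SF")
})

test_that("calibrated proportions converge to truth as validation n grows", {
  set.seed(99)
  true_p <- c(MF = 0.5, NF = 0.2, SF = 0.3)
  n_cells <- 40000
  true_lab <- sample(THEMATIC_CODES, n_cells, replace = TRUE, prob = true_p)
  g <- matrix(true_lab, 200, 200)
  s <- build_stack(list(land_cover_map(g, 20000701, 1),
                        land_cover_map(g, 20010701, 1)))
  noisy <- corrupt_with_confusion(s, machadinho_confusion(), seed = 99)
  map_lab <- as.vector(noisy$codes[, , 1])
  true_frac <- vapply(THEMATIC_CODES, function(code) mean(true_lab == code), 0)
  mae <- function(n_val) {
    idx <- sample.int(n_cells, n_val)
    counts <- table(factor(label_of(true_lab[idx]), THEMATIC_CLASSES),
                    factor(label_of(map_lab[idx]), THEMATIC_CLASSES))
    m <- error_matrix(matrix(as.integer(counts), 3, 3))
    f_j <- vapply(THEMATIC_CODES,
                  function(code) sum(map_lab[-idx] == code), 0)
    cal <- inverse_calibrate(m, f_j)
    mean(abs(cal$pi_calibrated - true_frac))
  }
  errs <- vapply(c(300, 3000, 30000), mae, 0)
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.005)
})

test_that("error matrices from corrupted maps converge to the confusion rows", {
  set.seed(7)
  spec <- machadinho_confusion()
  n <- 100
  g <- matrix(sample(THEMATIC_CODES, n * n, replace = TRUE), n, n)
  s <- build_stack(list(land_cover_map(g, 20000701, 1),
                        land_cover_map(g, 20010701, 1)))
  noisy <- corrupt_with_confusion(s, spec, seed = 17)
  map <- stack_map(noisy, 1)
  pts <- data.frame(row = rep(seq_len(n), n), col = rep(seq_len(n), each = n),
                    reference = label_of(as.vector(g)))
  m <- build_error_matrix(pts, map)$matrix
  emp <- sweep(m$counts, 1, m$row_totals, "/")
  expect_lt(max(abs(emp - unclass(spec))), 0.02)
  st <- accuracy_stats(m)
  expect_lt(max(abs(unname(st$omission) - unname(1 - diag(unclass(spec))))),
            0.02)
})

test_that("overlay incidence matches brute-force tallies", {
  set.seed(12)
  g <- matrix(sample(unname(LCC_CODES[c("MF", "NF", "SF", "WATER")]), 400,
                     replace = TRUE), 20, 20)
  map <- land_cover_map(g, 20100101, 0.5)
  mask <- matrix(sample(c(TRUE, FALSE), 400, replace = TRUE), 20, 20)
  inc <- overlay_incidence(mask, map)
  for (i in 1:3) {
    cls <- THEMATIC_CODES[i]
    ov <- 0; ca <- 0
    for (r in 1:20) for (c in 1:20) {
      if (g[r, c] == cls) {
        ca <- ca + 0.5
        if (mask[r, c]) ov <- ov + 0.5
      }
    }
    expect_equal(inc$overlap_ha[i], ov)
    expect_equal(inc$class_area_ha[i], ca)
    expect_equal(inc$ri_pct[i], 100 * ov / ca)
  }
  # mask fully inside one class
  g2 <- matrix(LCC_CODES[["SF"]], 10, 10)
  g2[1:5, ] <- LCC_CODES[["MF"]]
  mask2 <- matrix(FALSE, 10, 10); mask2[6:7, 1:5] <- TRUE
  inc2 <- overlay_incidence(mask2, land_cover_map(g2, 20100101, 1))
  expect_equal(inc2$ri_pct[inc2$class == "SF"], 100 * 10 / 50)
  expect_equal(inc2$overlap_ha[inc2$class != "SF"], c(0, 0))
  expect_equal(inc2$share_of_mask_pct[inc2$class == "SF"], 100)
  # empty mask: zero table
  inc0 <- overlay_incidence(matrix(FALSE, 10, 10),
                            land_cover_map(g2, 20100101, 1))
  expect_true(all(inc0$overlap_ha == 0))
})

test_that("protection incidence ratio compares deforested fractions", {
  # identical fractions inside and outside -> 1
  g <- matrix(LCC_CODES[["MF"]], 10, 10)
  g[, 1:2] <- LCC_CODES[["NF"]]
  map <- land_cover_map(g, 20100101, 1)
  half <- matrix(FALSE, 10, 10); half[1:5, ] <- TRUE
  pr <- protection_incidence_ratio(half, map)
  expect_equal(pr$ratio, 1)
  # outside 0.4 vs inside 0.2 -> 2
  g2 <- matrix(LCC_CODES[["MF"]], 10, 10)
  g2[1:5, 1:2] <- LCC_CODES[["NF"]]   # inside rows 1:5: 10/50
  g2[6:10, 1:4] <- LCC_CODES[["SF"]]  # outside rows 6:10: 20/50
  inside <- matrix(FALSE, 10, 10); inside[1:5, ] <- TRUE
  pr2 <- protection_incidence_ratio(inside, land_cover_map(g2, 20100101, 1))
  expect_equal(pr2$ratio, 2)
  expect_equal(pr2$frac_outside, 0.4)
  expect_equal(pr2$frac_inside, 0.2)
  # zero inside deforestation flagged infinite
  g3 <- matrix(LCC_CODES[["MF"]], 10, 10)
  g3[6:10, 1] <- LCC_CODES[["NF"]]
  pr3 <- protection_incidence_ratio(inside, land_cover_map(g3, 20100101, 1))
  expect_true(pr3$infinite)
  expect_equal(pr3$ratio, Inf)
})
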