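# fixtures are built in code: label-sequence stacks and small maps

code_vec <- function(labels) unname(LCC_CODES[labels])

# one pixel per sequence, pixels stacked as rows of an n x 1 grid
seq_stack <- function(sequences, dates = NULL, pixel_area_ha = 1) {
  n <- length(sequences)
  nd <- length(sequences[[1]])
  if (is.null(dates)) dates <- paste0(2000 + seq_len(nd) - 1, "0701")
  maps <- lapply(seq_len(nd), function(k) {
    g <- matrix(vapply(sequences, function(s) code_vec(s[k]), 0L), n, 1)
    land_cover_map(g, dates[k], pixel_area_ha)
  })
  build_stack(maps)
}

mid_year_dates <- function(years) paste0(years, "0701")

# random thematic stack (no WATER so sequences are unconstrained)
random_stack <- function(nr = 10, nc = 10, nd = 6, p_nodata = 0,
                         seed = 1, pixel_area_ha = 1) {
  set.seed(seed)
  pool <- c(THEMATIC_CODES, if (p_nodata > 0) LCC_CODES[["NODATA"]])
  prob <- if (p_nodata > 0) c(rep((1 - p_nodata) / 3, 3), p_nodata)
          else rep(1 / 3, 3)
  maps <- lapply(seq_len(nd), function(k) {
    g <- matrix(sample(pool, nr * nc, replace = TRUE, prob = prob), nr, nc)
    land_cover_map(g, mid_year_dates(1999 + k), pixel_area_ha)
  })
  build_stack(maps)
}

# Machadinho-like classification noise (published 2010 error-matrix rows / 200)
machadinho_confusion <- function() {
  confusion_spec(matrix(c(1, 0, 0,
                          0, 0.985, 0.015,
                          0.095, 0.185, 0.72), 3, 3, byrow = TRUE))
}

metrics_at <- function(stack) compute_trajectory_metrics(stack)

# grid of square same-class patches, block x block cells each, classes
# arranged so no two adjacent blocks share a class
patchwork_map <- function(nblocks = 10, block = 6, pixel_area_ha = 1,
                          date = 20100701) {
  n <- nblocks * block
  g <- matrix(0L, n, n)
  for (bi in seq_len(nblocks)) {
    for (bj in seq_len(nblocks)) {
      cls <- THEMATIC_CODES[((bi + bj) %% 3) + 1]
      g[(bi - 1) * block + seq_len(block),
        (bj - 1) * block + seq_len(block)] <- cls
    }
  }
  land_cover_map(g, date, pixel_area_ha)
}
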