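#' Acquisition dates of the bundled Rondônia-like default scenario
#'
#' Twenty-one Landsat-style acquisition dates spanning 1984--2011 with
#' irregular 1--3 year gaps, matching the cadence of a typical Amazonian
#' deforestation-frontier time-series (Machadinho d'Oeste site).
#'
#' @return `Date` vector of length 21.
#' @export
default_scene_dates <- function() {
  parse_ymd(c(19840617, 19860810, 19870712, 19890717, 19900618, 19910925,
              19940816, 19950803, 19960704, 19970723, 19980624, 19990729,
              20010803, 20030724, 20050713, 20060716, 20070703, 20080806,
              20090809, 20100625, 20110612))
}

#' Configuration for the synthetic landscape simulator
#'
#' Defaults describe a Machadinho d'Oeste-like frontier: 21 irregular dates
#' 1984--2011, an initial mix of 91% mature forest / 1% non-forest / 9%
#' secondary forest, a mature-forest clearance hazard of 0.04 yr^-1
#' (reproducing the observed decline of MF from ~91% to ~32% over 27
#' years), an active-use (NF) duration that is geometric with mean 2 years,
#' and a secondary-forest reclearance hazard of 0.15 yr^-1. Pixels are
#' Landsat-sized (0.09 ha). A WATER border strip exercises the common-mask
#' path.
#'
#' @param shape integer c(rows, cols).
#' @param dates acquisition dates (`Date` or yyyymmdd), strictly increasing.
#' @param pixel_area_ha pixel area in hectares.
#' @param p_clear_mf per-year clearance probability for MF, in [0,1].
#' @param palu_sampler function(n) returning n integer active-use durations
#'   in years (support >= 1).
#' @param p_reclear_sf per-year reclearance probability for SF, in [0,1].
#' @param p_initial_sf fraction of pixels already SF at the first date.
#' @param p_initial_nf fraction of pixels NF at the first date.
#' @param water_border width (cells) of the permanent WATER strip along the
#'   first rows; 0 for none.
#' @param seed integer RNG seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(shape = c(100, 100),
                              dates = default_scene_dates(),
                              pixel_area_ha = 0.09,
                              p_clear_mf = 0.04,
                              palu_sampler = function(n) stats::rgeom(n, 0.5) + 1L,
                              p_reclear_sf = 0.15,
                              p_initial_sf = 0.09,
                              p_initial_nf = 0.01,
                              water_border = 2L,
                              seed = 1L) {
  if (!inherits(dates, "Date")) dates <- parse_ymd(dates)
  if (length(dates) < 2) stop("need at least two acquisition dates")
  if (any(diff(as.numeric(dates)) <= 0)) stop("dates must be strictly increasing")
  if (length(shape) != 2 || any(shape < 1)) stop("degenerate shape")
  for (p in c(p_clear_mf, p_reclear_sf, p_initial_sf, p_initial_nf)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0,1]")
  }
  if (p_initial_sf + p_initial_nf > 1) {
    stop("p_initial_sf + p_initial_nf must not exceed 1")
  }
  structure(list(shape = as.integer(shape), dates = dates,
                 pixel_area_ha = pixel_area_ha, p_clear_mf = p_clear_mf,
                 palu_sampler = palu_sampler, p_reclear_sf = p_reclear_sf,
                 p_initial_sf = p_initial_sf, p_initial_nf = p_initial_nf,
                 water_border = as.integer(water_border),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# per-year probability -> continuous-time hazard rate, so that over a gap of
# dt years the event probability is 1 - (1-p)^dt
hazard_rate <- function(p) {
  if (p >= 1) Inf else -log1p(-p)
}

# waiting time; a certain event (p = 1) happens just after the phase starts,
# never exactly at it, so the starting state is still observable
rexp_or_inf <- function(rate) {
  if (rate == 0) Inf else if (is.infinite(rate)) 1e-9 else stats::rexp(1L, rate)
}

#' Simulate a classified land-cover time-series with known truth
#'
#' Each pixel evolves independently as a continuous-time semi-Markov chain:
#' mature forest persists until a clearance event (exponential waiting time
#' with per-year hazard `p_clear_mf`), is then actively used (NF) for an
#' integer number of years drawn from `palu_sampler`, then abandoned to
#' secondary forest, which faces a reclearance hazard `p_reclear_sf`
#' restarting the NF phase. The chain is sampled at the configured
#' acquisition dates. Pixels may start the series as SF or NF (censored
#' starts). Ground truth (per-pixel, per-date ASF / PALU / FC and censoring
#' flags, under the observation-date conventions of
#' [compute_trajectory_metrics()]) is traced from the discretised state
#' sequence by an independent per-pixel reference tracer.
#'
#' @param config a [simulation_config()].
#' @return list with `stack` (a `classified_stack`) and `truth` (a
#'   `trajectory_truth`: arrays `class`, `asf`, `asf_censored`, `palu`,
#'   `palu_zero`, `fc`, `fc_nf_start`, each rows x cols x dates).
#' @export
simulate_stack <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nr <- config$shape[1]; nc <- config$shape[2]
  npix <- nr * nc
  nd <- length(config$dates)
  t_rel <- decimal_years(config$dates[1], config$dates)
  t_end <- t_rel[nd]
  lam_mf <- hazard_rate(config$p_clear_mf)
  lam_sf <- hazard_rate(config$p_reclear_sf)
  mf <- LCC_CODES[["MF"]]; nf <- LCC_CODES[["NF"]]; sf <- LCC_CODES[["SF"]]

  water <- matrix(FALSE, nr, nc)
  if (config$water_border > 0) {
    water[seq_len(min(config$water_border, nr)), ] <- TRUE
  }

  u <- stats::runif(npix)
  init <- ifelse(u < config$p_initial_sf, sf,
                 ifelse(u < config$p_initial_sf + config$p_initial_nf, nf, mf))

  labels <- matrix(LCC_CODES[["WATER"]], npix, nd)
  land <- which(!as.vector(water))
  for (i in land) {
    # build the phase sequence (start time, state) out to the last date
    times <- 0
    states <- init[i]
    cur_t <- 0; cur_s <- init[i]
    while (cur_t <= t_end) {
      if (cur_s == mf) {
        cur_t <- cur_t + rexp_or_inf(lam_mf)
        cur_s <- nf
      } else if (cur_s == nf) {
        cur_t <- cur_t + config$palu_sampler(1L)
        cur_s <- sf
      } else {
        cur_t <- cur_t + rexp_or_inf(lam_sf)
        cur_s <- nf
      }
      if (cur_t > t_end) break
      times <- c(times, cur_t)
      states <- c(states, cur_s)
    }
    labels[i, ] <- states[findInterval(t_rel, times)]
  }

  maps <- lapply(seq_len(nd), function(k) {
    g <- matrix(labels[, k], nr, nc)
    land_cover_map(g, config$dates[k], config$pixel_area_ha)
  })
  stack <- build_stack(maps)
  truth <- trace_truth(stack)
  list(stack = stack, truth = truth)
}

#' Trace per-pixel trajectory truth from a label sequence
#'
#' Reference (per-pixel, scalar) implementation of the observation-date
#' trajectory definitions; the production implementation in
#' [compute_trajectory_metrics()] is vectorised across pixels and is tested
#' against this tracer.
#'
#' @param stack a `classified_stack`.
#' @return object of class `trajectory_truth`.
#' @export
trace_truth <- function(stack) {
  nd <- n_dates(stack)
  dm <- dim(stack$codes)
  npix <- dm[1] * dm[2]
  t_rel <- decimal_years(stack$dates[1], stack$dates)
  labels <- matrix(stack$codes, npix, nd)
  mf <- LCC_CODES[["MF"]]; nf <- LCC_CODES[["NF"]]; sf <- LCC_CODES[["SF"]]

  asf <- matrix(NA_real_, npix, nd)
  asf_cens <- matrix(NA, npix, nd)
  palu <- matrix(NA_real_, npix, nd)
  palu_zero <- matrix(NA, npix, nd)
  fc <- matrix(NA_integer_, npix, nd)
  fc_nf_start <- matrix(NA, npix, nd)

  for (i in seq_len(npix)) {
    run_label <- NA_integer_; run_start <- NA_real_
    run_from_first <- FALSE
    first_label <- NA_integer_
    last_nf_dur <- NA_real_
    nclear <- 0L
    for (k in seq_len(nd)) {
      cur <- labels[i, k]
      if (cur != mf && cur != nf && cur != sf) next  # WATER / NODATA
      if (is.na(run_label)) {
        run_label <- cur; run_start <- t_rel[k]
        first_label <- cur; run_from_first <- TRUE
      } else if (cur != run_label) {
        if (run_label == nf) {
          last_nf_dur <- t_rel[k] - run_start
        } else if (run_label == mf && cur == sf) {
          last_nf_dur <- 0  # clearance + abandonment both unobserved
        }
        if (cur == nf) nclear <- nclear + 1L
        run_label <- cur; run_start <- t_rel[k]
        run_from_first <- FALSE
      }
      fc[i, k] <- nclear
      fc_nf_start[i, k] <- (first_label == nf) && nclear == 0L
      if (cur == sf) {
        asf[i, k] <- t_rel[k] - run_start
        cens <- run_from_first && first_label == sf
        asf_cens[i, k] <- cens
        if (cens) {
          palu[i, k] <- 0
          palu_zero[i, k] <- TRUE
        } else {
          palu[i, k] <- if (is.na(last_nf_dur)) 0 else last_nf_dur
          palu_zero[i, k] <- FALSE
        }
      }
    }
  }

  to_arr <- function(m) array(m, dim = dm)
  structure(list(class = stack$codes,
                 asf = to_arr(asf), asf_censored = to_arr(asf_cens),
                 palu = to_arr(palu), palu_zero = to_arr(palu_zero),
                 fc = to_arr(fc), fc_nf_start = to_arr(fc_nf_start),
                 dates = stack$dates),
            class = "trajectory_truth")
}

#' Confusion specification for classification noise
#'
#' A row-stochastic matrix over the thematic classes (MF, NF, SF): entry
#' (i, j) is the probability that a pixel whose true class is i is labelled
#' j by the classifier.
#'
#' @param prob 3x3 numeric matrix, rows summing to 1 within 1e-12.
#' @return object of class `confusion_spec`.
#' @export
confusion_spec <- function(prob) {
  prob <- as.matrix(prob)
  if (!all(dim(prob) == c(3, 3))) stop("confusion matrix must be 3x3 (MF, NF, SF)")
  if (any(prob < 0)) stop("confusion entries must be nonnegative")
  if (any(abs(rowSums(prob) - 1) > 1e-12)) {
    stop("confusion rows must sum to 1 (non-stochastic row)")
  }
  dimnames(prob) <- list(true = THEMATIC_CLASSES, labelled = THEMATIC_CLASSES)
  structure(prob, class = c("confusion_spec", "matrix"))
}

#' Apply confusion-matrix classification noise to a stack
#'
#' Each thematic cell (MF/NF/SF) at each date is relabelled independently
#' according to its true-class row of the confusion matrix. WATER and
#' NODATA cells are never corrupted.
#'
#' @param stack a `classified_stack`.
#' @param spec a [confusion_spec()].
#' @param seed integer RNG seed.
#' @return corrupted `classified_stack`.
#' @export
corrupt_with_confusion <- function(stack, spec, seed = 1L) {
  stopifnot(inherits(stack, "classified_stack"))
  if (!inherits(spec, "confusion_spec")) spec <- confusion_spec(spec)
  set.seed(seed)
  codes <- stack$codes
  for (i in seq_along(THEMATIC_CODES)) {
    idx <- which(codes == THEMATIC_CODES[i])
    if (length(idx) == 0) next
    new_lab <- sample.int(3L, length(idx), replace = TRUE, prob = spec[i, ])
    codes[idx] <- THEMATIC_CODES[new_lab]
  }
  stack$codes <- codes
  stack
}

#' Label connected patches of equal thematic class
#'
#' Two-pass union-find connected-component labelling with 4-connectivity;
#' components join only across cells of the same thematic class. WATER and
#' NODATA cells get label 0.
#'
#' @param grid integer matrix of class codes.
#' @return integer matrix of patch labels (1..n_patches; 0 = non-thematic).
#' @export
label_patches <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      g <- grid[i, j]
      if (g != 1L && g != 2L && g != 3L) next
      left <- if (j > 1 && grid[i, j - 1] == g) lab[i, j - 1] else 0L
      up <- if (i > 1 && grid[i - 1, j] == g) lab[i - 1, j] else 0L
      if (left == 0L && up == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else if (left > 0L && up > 0L) {
        rl <- find(left); ru <- find(up)
        if (rl != ru) parent[max(rl, ru)] <- min(rl, ru)
        lab[i, j] <- min(rl, ru)
      } else {
        lab[i, j] <- max(left, up)
      }
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, 1L)
  compact <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- compact[lab[pos]]
  lab
}

#' Draw reference validation points from large patches
#'
#' Implements the accuracy-assessment sampling design: for each thematic
#' class, `n_per_class` random points, each located at the interior centroid
#' cell of a distinct patch (4-connected component of that class) whose
#' area is at least `min_patch_ha`. If the geometric centroid of a concave
#' patch falls outside it, the nearest patch cell is used. Sampling is
#' without replacement across patches and seeded.
#'
#' @param map a `land_cover_map`.
#' @param n_per_class points per thematic class (default 200).
#' @param min_patch_ha minimum eligible patch area in hectares (default 6).
#' @param seed integer RNG seed.
#' @return data frame (row, col, label, patch_id), `n_per_class` rows per
#'   class.
#' @export
make_reference_sample <- function(map, n_per_class = 200L, min_patch_ha = 6,
                                  seed = 1L) {
  stopifnot(inherits(map, "land_cover_map"))
  set.seed(seed)
  lab <- label_patches(map$grid)
  out <- vector("list", 3)
  for (ci in seq_along(THEMATIC_CODES)) {
    code <- THEMATIC_CODES[ci]
    cls <- names(THEMATIC_CODES)[ci]
    cells <- which(map$grid == code, arr.ind = TRUE)
    ids <- lab[cells]
    sizes <- table(ids)
    eligible <- as.integer(names(sizes)[sizes * map$pixel_area_ha >= min_patch_ha])
    if (length(eligible) < n_per_class) {
      stop(sprintf(
        "class %s has only %d eligible patches (need %d of at least %g ha)",
        cls, length(eligible), n_per_class, min_patch_ha), call. = FALSE)
    }
    chosen <- eligible[sample.int(length(eligible), n_per_class)]
    pts <- matrix(NA_integer_, n_per_class, 2)
    for (p in seq_len(n_per_class)) {
      pc <- cells[ids == chosen[p], , drop = FALSE]
      ctr <- colMeans(pc)
      cand <- round(ctr)
      inside <- cand[1] >= 1 && cand[1] <= nrow(map$grid) &&
        cand[2] >= 1 && cand[2] <= ncol(map$grid) &&
        lab[cand[1], cand[2]] == chosen[p]
      if (inside) {
        pts[p, ] <- cand
      } else {
        d2 <- (pc[, 1] - ctr[1])^2 + (pc[, 2] - ctr[2])^2
        pts[p, ] <- pc[which.min(d2), ]
      }
    }
    out[[ci]] <- data.frame(row = pts[, 1], col = pts[, 2], label = cls,
                            patch_id = chosen, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
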