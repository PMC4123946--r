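#' Per-pixel trajectory metrics: ASF, PALU and FC
#'
#' Computes, for every pixel and every date of a (temporally corrected)
#' stack, the three land-use history metrics:
#'
#' * **ASF** (age of secondary forest): decimal years the pixel has been
#'   continuously SF since the onset of the current SF run. The onset is
#'   the first date at which SF is observed in the run, so ages are
#'   conservative "minimum" ages; if the run extends back to the first
#'   date of the series the true abandonment date is unknown and
#'   `asf_censored` is set.
#' * **PALU** (period of active land use): decimal years of the
#'   uninterrupted NF run immediately preceding the current SF run. Pixels
#'   SF since the first date have no observed active-use phase: PALU 0 with
#'   `palu_zero` set. A direct MF->SF change (clearance and abandonment
#'   both falling inside one observation gap) yields PALU 0 without the
#'   flag.
#' * **FC** (frequency of clearance): cumulative count of observed
#'   clearance transitions (MF->NF or SF->NF) up to the date. Pixels that
#'   enter the series as NF with no later observed clearance carry
#'   `fc_nf_start`; for class binning they belong to the low (1x) class.
#'
#' Runs continue across NODATA dates when the same label resumes; a label
#' change across a gap is dated at the first post-gap observation. WATER
#' cells are NA throughout.
#'
#' @param stack a `classified_stack` (apply
#'   [correct_disallowed_transitions()] first).
#' @return object of class `metric_maps`: arrays `asf`, `asf_censored`,
#'   `palu`, `palu_zero`, `fc`, `fc_nf_start` (rows x cols x dates) plus
#'   `dates`.
#' @export
compute_trajectory_metrics <- function(stack) {
  stopifnot(inherits(stack, "classified_stack"))
  nd <- n_dates(stack)
  dm <- dim(stack$codes)
  npix <- dm[1] * dm[2]
  t_rel <- decimal_years(stack$dates[1], stack$dates)
  labels <- matrix(stack$codes, npix, nd)
  mf <- LCC_CODES[["MF"]]; nf <- LCC_CODES[["NF"]]; sf <- LCC_CODES[["SF"]]

  run_label <- rep(NA_integer_, npix)
  run_start <- rep(NA_real_, npix)
  run_from_first <- rep(FALSE, npix)
  first_label <- rep(NA_integer_, npix)
  last_nf_dur <- rep(NA_real_, npix)
  nclear <- rep(0L, npix)

  asf <- matrix(NA_real_, npix, nd)
  asf_cens <- matrix(NA, npix, nd)
  palu <- matrix(NA_real_, npix, nd)
  palu_zero <- matrix(NA, npix, nd)
  fc <- matrix(NA_integer_, npix, nd)
  fc_nf_start <- matrix(NA, npix, nd)

  for (k in seq_len(nd)) {
    cur <- labels[, k]
    obs <- cur == mf | cur == nf | cur == sf

    fresh <- obs & is.na(run_label)
    if (any(fresh)) {
      run_label[fresh] <- cur[fresh]
      run_start[fresh] <- t_rel[k]
      run_from_first[fresh] <- TRUE
      first_label[fresh] <- cur[fresh]
    }

    changed <- obs & !is.na(run_label) & !fresh & cur != run_label
    if (any(changed)) {
      end_nf <- changed & run_label == nf
      last_nf_dur[end_nf] <- t_rel[k] - run_start[end_nf]
      skip_nf <- changed & run_label == mf & cur == sf
      last_nf_dur[skip_nf] <- 0
      clr <- changed & cur == nf & (run_label == mf | run_label == sf)
      nclear[clr] <- nclear[clr] + 1L
      run_label[changed] <- cur[changed]
      run_start[changed] <- t_rel[k]
      run_from_first[changed] <- FALSE
    }

    fc[obs, k] <- nclear[obs]
    fc_nf_start[obs, k] <- first_label[obs] == nf & nclear[obs] == 0L

    is_sf <- obs & cur == sf
    asf[is_sf, k] <- t_rel[k] - run_start[is_sf]
    cens <- is_sf & run_from_first & first_label == sf
    asf_cens[is_sf, k] <- cens[is_sf]
    palu_zero[is_sf, k] <- cens[is_sf]
    palu[cens, k] <- 0
    notc <- is_sf & !cens
    palu[notc, k] <- ifelse(is.na(last_nf_dur[notc]), 0, last_nf_dur[notc])
  }

  to_arr <- function(m) array(m, dim = dm)
  structure(list(asf = to_arr(asf), asf_censored = to_arr(asf_cens),
                 palu = to_arr(palu), palu_zero = to_arr(palu_zero),
                 fc = to_arr(fc), fc_nf_start = to_arr(fc_nf_start),
                 dates = stack$dates),
            class = "metric_maps")
}

#' Class bin specifications for ASF, PALU and FC
#'
#' The standard three-class bins, applied to metric values floored to whole
#' years:
#' ASF: initial (<=5), intermediate (6--15), advanced (>=16).
#' PALU: short (<=2), medium (3--4), long (>=5).
#' FC: low (<=1), medium (2), high (>=3); an FC of 0 (censored NF-start or
#' SF-persisting pixels) falls in the low class.
#'
#' @param metric one of "asf", "palu", "fc".
#' @return object of class `bin_spec` (list: metric, breaks, labels).
#' @export
bin_spec <- function(metric = c("asf", "palu", "fc")) {
  metric <- match.arg(metric)
  switch(metric,
    asf = structure(list(metric = "asf", breaks = c(-Inf, 5, 15, Inf),
                         labels = c("initial", "intermediate", "advanced")),
                    class = "bin_spec"),
    palu = structure(list(metric = "palu", breaks = c(-Inf, 2, 4, Inf),
                          labels = c("short", "medium", "long")),
                     class = "bin_spec"),
    fc = structure(list(metric = "fc", breaks = c(-Inf, 1, 2, Inf),
                        labels = c("low", "medium", "high")),
                   class = "bin_spec"))
}

#' Bin a metric grid into classes
#'
#' Values are floored to whole years before binning (bins are stated in
#' whole years; durations accumulate in decimal years). Undefined (NA)
#' cells stay NA.
#'
#' @param values numeric matrix/array of metric values.
#' @param spec a [bin_spec()].
#' @return factor array of the same shape, levels = `spec$labels`.
#' @export
bin_metric <- function(values, spec) {
  stopifnot(inherits(spec, "bin_spec"))
  v <- floor(as.vector(values))
  f <- as.character(cut(v, breaks = spec$breaks, labels = spec$labels,
                        right = TRUE))
  if (!is.null(dim(values))) dim(f) <- dim(values)
  f
}

#' PALU x FC cross-tabulation over current secondary forest
#'
#' Over pixels that are SF at the chosen date, the percentage of SF area in
#' each combination of PALU class (short/medium/long) and FC class
#' (low/medium/high). FC 0 pixels (censored starts) count as low.
#'
#' @param stack a corrected `classified_stack`.
#' @param metrics output of [compute_trajectory_metrics()] on `stack`.
#' @param k date index (default: last date).
#' @return 3x3 numeric matrix of percentages summing to 100.
#' @export
crosstab_palu_fc <- function(stack, metrics, k = n_dates(stack)) {
  sf_cells <- stack$codes[, , k] == LCC_CODES[["SF"]]
  if (!any(sf_cells)) stop("no SF pixels at the requested date")
  palu_cls <- bin_metric(metrics$palu[, , k], bin_spec("palu"))[sf_cells]
  fc_cls <- bin_metric(metrics$fc[, , k], bin_spec("fc"))[sf_cells]
  tab <- table(factor(palu_cls, levels = bin_spec("palu")$labels),
               factor(fc_cls, levels = bin_spec("fc")$labels))
  out <- 100 * tab / sum(tab)
  m <- matrix(as.numeric(out), 3, 3,
              dimnames = list(PALU = bin_spec("palu")$labels,
                              FC = bin_spec("fc")$labels))
  m
}

#' Land-cover proportion series
#'
#' Per date, the percentage of the thematic area (MF + NF + SF; WATER and
#' NODATA excluded from the denominator) in each class.
#'
#' @param stack a `classified_stack`.
#' @return data frame (date, year, MF, NF, SF) with percentages.
#' @export
landcover_proportion_table <- function(stack) {
  nd <- n_dates(stack)
  out <- data.frame(date = format_ymd(stack$dates),
                    year = as.integer(format(stack$dates, "%Y")),
                    MF = NA_real_, NF = NA_real_, SF = NA_real_)
  for (k in seq_len(nd)) {
    g <- stack$codes[, , k]
    n_mf <- sum(g == LCC_CODES[["MF"]])
    n_nf <- sum(g == LCC_CODES[["NF"]])
    n_sf <- sum(g == LCC_CODES[["SF"]])
    tot <- n_mf + n_nf + n_sf
    out$MF[k] <- 100 * n_mf / tot
    out$NF[k] <- 100 * n_nf / tot
    out$SF[k] <- 100 * n_sf / tot
  }
  out
}

#' Ordinary least-squares trend of a percentage series
#'
#' Linear fit of land-cover percentage on calendar year, as used to
#' summarise average annual change in class proportions.
#'
#' @param year numeric vector of years.
#' @param percent numeric vector of percentages (same length).
#' @return list with `slope` (percent per year), `intercept`, `r_squared`.
#' @export
ols_trend <- function(year, percent) {
  if (length(year) < 3) stop("need at least 3 points")
  if (length(unique(year)) < 2) stop("constant-year input")
  fit <- stats::lm(percent ~ year)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((percent - mean(percent))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_)
}

#' Metric-class shares of secondary forest through time
#'
#' For each date, the share (%) of the current SF area falling in each
#' class of a binned metric, indexed by years elapsed since the site-level
#' onset of secondary forest. The onset is the first date with any
#' non-censored SF (pixels SF since the first date are included in the
#' shares but do not define the onset).
#'
#' @param stack a corrected `classified_stack`.
#' @param metrics output of [compute_trajectory_metrics()].
#' @param spec a [bin_spec()] for the metric to bin ("asf", "palu", "fc").
#' @return data frame (date, years_since_onset, class, share_pct); empty if
#'   the series contains no SF.
#' @export
sf_class_proportion_curves <- function(stack, metrics, spec = bin_spec("asf")) {
  nd <- n_dates(stack)
  sf_code <- LCC_CODES[["SF"]]
  onset_k <- NA_integer_
  for (k in seq_len(nd)) {
    noncens <- stack$codes[, , k] == sf_code & !is.na(metrics$asf_censored[, , k]) &
      !metrics$asf_censored[, , k]
    if (any(noncens)) { onset_k <- k; break }
  }
  if (is.na(onset_k)) {
    return(data.frame(date = character(0), years_since_onset = numeric(0),
                      class = character(0), share_pct = numeric(0)))
  }
  t_onset <- stack$dates[onset_k]
  vals <- metrics[[spec$metric]]
  rows <- list()
  for (k in seq_len(nd)) {
    sf_cells <- stack$codes[, , k] == sf_code
    if (!any(sf_cells)) next
    cls <- factor(bin_metric(vals[, , k], spec)[sf_cells], levels = spec$labels)
    share <- 100 * as.numeric(table(cls)) / sum(sf_cells)
    rows[[length(rows) + 1]] <- data.frame(
      date = format_ymd(stack$dates[k]),
      years_since_onset = decimal_years(t_onset, stack$dates[k]),
      class = spec$labels, share_pct = share, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
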