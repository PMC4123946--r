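#' Cross-tabulated transition areas between two dated maps
#'
#' Exact 3x3 cross-tabulation of thematic labels (MF, NF, SF) between two
#' co-registered maps, scaled to hectares. Cells that are WATER, or NODATA
#' at either date, are excluded.
#'
#' @param map1,map2 `land_cover_map`s of identical shape and pixel area.
#' @param dt period length in decimal years (> 0); taken from the map dates
#'   when omitted.
#' @return object of class `transition_summary`: dates, `dt_years`,
#'   `areas_t1` / `areas_t2` (named ha), `trans` (3x3 ha matrix, rows =
#'   class at t1, cols = class at t2).
#' @export
transition_areas <- function(map1, map2, dt = NULL) {
  stopifnot(inherits(map1, "land_cover_map"), inherits(map2, "land_cover_map"))
  if (!identical(dim(map1$grid), dim(map2$grid))) stop("map shapes differ")
  if (is.null(dt)) dt <- decimal_years(map1$date, map2$date)
  if (dt <= 0) stop("dt must be positive")
  g1 <- as.vector(map1$grid); g2 <- as.vector(map2$grid)
  valid <- is_thematic(g1) & is_thematic(g2)
  tab <- table(factor(g1[valid], levels = THEMATIC_CODES),
               factor(g2[valid], levels = THEMATIC_CODES))
  trans <- matrix(as.numeric(tab), 3, 3,
                  dimnames = list(t1 = THEMATIC_CLASSES,
                                  t2 = THEMATIC_CLASSES)) * map1$pixel_area_ha
  a1 <- rowSums(trans)
  a2 <- colSums(trans)
  structure(list(t1 = map1$date, t2 = map2$date, dt_years = dt,
                 areas_t1 = a1, areas_t2 = a2, trans = trans,
                 pixel_area_ha = map1$pixel_area_ha),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("<transition_summary> %s -> %s (%.2f yr)\n",
              format_ymd(x$t1), format_ymd(x$t2), x$dt_years))
  print(round(x$trans, 2))
  invisible(x)
}

#' Annual relative rate of change (log-area convention)
#'
#' The standardised annual rate of change between two area measurements:
#' r = (100/dt) * ln(A2/A1), in percent per year. Negative for loss.
#'
#' @param A1,A2 areas in hectares at the start and end of the period (> 0).
#' @param dt period length in decimal years (> 0).
#' @return percent per year.
#' @export
relative_rate_ln <- function(A1, A2, dt) {
  if (any(dt <= 0)) stop("dt must be positive")
  if (any(A1 <= 0) || any(A2 <= 0)) {
    stop("undefined rate: areas must be positive")
  }
  (100 / dt) * log(A2 / A1)
}

#' Annual absolute rate of change
#'
#' R = (A2 - A1)/dt, in hectares per year.
#'
#' @param A1,A2 areas in hectares.
#' @param dt period length in decimal years (> 0).
#' @return hectares per year.
#' @export
absolute_rate <- function(A1, A2, dt) {
  if (any(dt <= 0)) stop("dt must be positive")
  (A2 - A1) / dt
}

#' Per-period deforestation and regrowth rates
#'
#' For every consecutive date pair of the stack, computes the transition
#' areas and annualised rates for four processes:
#' deforestation over MF (MF->NF), deforestation over SF (SF->NF), total
#' deforestation (their sum) and regrowth (NF->SF).
#'
#' Two relative-rate conventions are available. Under `ln_area`, r is the
#' log-area rate on (A_source(t1), A_source(t1) - T) — exact for
#' compounding loss, negative for loss. Under `transition_fraction`,
#' r = 100 * T / (A_source(t1) * dt) — the cleared (or regrown) fraction of
#' the source area per year, always nonnegative and able to exceed 100%/yr
#' over multi-year gaps with high turnover. The default `mixed` follows
#' common practice in frontier studies: `ln_area` for MF and total
#' deforestation, `transition_fraction` for SF reclearance and regrowth
#' (whose observed rates can exceed 100%/yr). The regrowth denominator is
#' A_NF(t1) by default, configurable to A_SF(t1).
#'
#' The absolute rate is always R = T/dt (so R * dt recovers the transition
#' area exactly).
#'
#' @param stack a corrected `classified_stack`.
#' @param convention "mixed" (default), "ln_area" or "transition_fraction".
#' @param regrowth_denominator "NF" (default) or "SF".
#' @return data frame with one row per period x process: t1, t2, dt_years,
#'   process, A_source_ha, transition_ha, r_pct_yr, R_ha_yr, convention,
#'   defined.
#' @export
period_rate_table <- function(stack,
                              convention = c("mixed", "ln_area",
                                             "transition_fraction"),
                              regrowth_denominator = c("NF", "SF")) {
  convention <- match.arg(convention)
  regrowth_denominator <- match.arg(regrowth_denominator)
  nd <- n_dates(stack)
  if (nd < 2) stop("need at least two dates")
  rows <- list()
  for (k in seq_len(nd - 1)) {
    ts <- transition_areas(stack_map(stack, k), stack_map(stack, k + 1))
    dt <- ts$dt_years
    t_mf_nf <- ts$trans["MF", "NF"]
    t_sf_nf <- ts$trans["SF", "NF"]
    t_nf_sf <- ts$trans["NF", "SF"]
    a_mf <- ts$areas_t1[["MF"]]; a_sf <- ts$areas_t1[["SF"]]
    a_nf <- ts$areas_t1[["NF"]]
    a_regrow <- if (regrowth_denominator == "NF") a_nf else a_sf
    proc <- list(
      mf_deforestation = list(T = t_mf_nf, A = a_mf, conv_mixed = "ln_area"),
      sf_deforestation = list(T = t_sf_nf, A = a_sf,
                              conv_mixed = "transition_fraction"),
      total_deforestation = list(T = t_mf_nf + t_sf_nf, A = a_mf + a_sf,
                                 conv_mixed = "ln_area"),
      regrowth = list(T = t_nf_sf, A = a_regrow,
                      conv_mixed = "transition_fraction"))
    for (pn in names(proc)) {
      p <- proc[[pn]]
      conv <- if (convention == "mixed") p$conv_mixed else convention
      defined <- p$A > 0 && (conv != "ln_area" || p$A - p$T > 0)
      r <- if (!defined) NA_real_
      else if (conv == "ln_area") relative_rate_ln(p$A, p$A - p$T, dt)
      else 100 * p$T / (p$A * dt)
      rows[[length(rows) + 1]] <- data.frame(
        t1 = format_ymd(ts$t1), t2 = format_ymd(ts$t2), dt_years = dt,
        process = pn, A_source_ha = p$A, transition_ha = p$T,
        r_pct_yr = r, R_ha_yr = p$T / dt, convention = conv,
        defined = defined, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summarise per-period rates
#'
#' Per process and unit, the distribution summary printed in frontier
#' change studies: minimum, maximum, mean, median, inter-quartile range
#' (Q3 - Q1, type-7 quantiles) and sample standard deviation. Rates are
#' summarised as magnitudes (loss rates positive); undefined rates are
#' excluded and counted in `n_undefined`.
#'
#' @param records output of [period_rate_table()].
#' @return data frame: process, unit, n, min, max, mean, median, iqr, sd,
#'   sd_flag (TRUE when n = 1 and sd is reported as 0), n_undefined.
#' @export
summarize_rates <- function(records) {
  if (nrow(records) == 0) stop("empty rate table")
  out <- list()
  for (pn in unique(records$process)) {
    sub <- records[records$process == pn, ]
    for (unit in c("pct_yr", "ha_yr")) {
      v <- if (unit == "pct_yr") abs(sub$r_pct_yr) else abs(sub$R_ha_yr)
      nun <- sum(is.na(v))
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
      sdv <- if (length(v) > 1) stats::sd(v) else 0
      out[[length(out) + 1]] <- data.frame(
        process = pn, unit = unit, n = length(v),
        min = min(v), max = max(v), mean = mean(v),
        median = stats::median(v), iqr = q[2] - q[1], sd = sdv,
        sd_flag = length(v) == 1, n_undefined = nun,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Classify a period into the land-use dynamics typology
#'
#' Labels each inter-date period along two orthogonal axes of the standard
#' frontier typology:
#'
#' Clearance composition (which forests are being cleared):
#' * `a` — clearance of MF only, with little or no deforestation over SF;
#' * `b` — both cleared, MF area cleared > SF area cleared;
#' * `c` — both cleared, MF area cleared < SF area cleared;
#' * `e` — reclearance of SF but no clearance of MF;
#' * `none` — no appreciable clearance of either.
#'
#' Clearance/regrowth balance:
#' * `d` — area of MF and SF cleared > area of SF regenerating;
#' * `f` — net abandonment of land to regenerating forest.
#'
#' "Little or no" uses a tolerance of `eps_frac` times the larger clearance
#' term. Equal clearances are labelled `b` with `tie = TRUE`; an exact
#' clearance/regrowth balance is labelled `d` with `tie = TRUE`.
#'
#' @param summary a `transition_summary`.
#' @param eps_frac tolerance fraction for "little or no" (default 0.01).
#' @return list: `clearance` (one of a/b/c/e/none), `balance` (d/f),
#'   `tie` (logical).
#' @export
classify_period_indicator <- function(summary, eps_frac = 0.01) {
  stopifnot(inherits(summary, "transition_summary"))
  t_mf <- summary$trans["MF", "NF"]
  t_sf <- summary$trans["SF", "NF"]
  t_re <- summary$trans["NF", "SF"]
  eps <- eps_frac * max(t_mf, t_sf)
  tie <- FALSE
  if (t_mf <= eps && t_sf <= eps) {
    clearance <- "none"
  } else if (t_sf <= eps) {
    clearance <- "a"
  } else if (t_mf <= eps) {
    clearance <- "e"
  } else if (t_mf > t_sf) {
    clearance <- "b"
  } else if (t_mf < t_sf) {
    clearance <- "c"
  } else {
    clearance <- "b"
    tie <- TRUE
  }
  cleared <- t_mf + t_sf
  if (cleared > t_re) {
    balance <- "d"
  } else if (t_re > cleared) {
    balance <- "f"
  } else {
    balance <- "d"
    tie <- TRUE
  }
  list(clearance = clearance, balance = balance, tie = tie)
}
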