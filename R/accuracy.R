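#' Construct an error matrix
#'
#' Orientation is fixed throughout the package: rows = reference (true)
#' class, columns = classified (map) class.
#'
#' @param counts k x k matrix of nonnegative integer counts.
#' @param classes class labels (default MF, NF, SF).
#' @return object of class `error_matrix`.
#' @export
error_matrix <- function(counts, classes = THEMATIC_CLASSES) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("error matrix must be square")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (nrow(counts) != length(classes)) stop("labels do not match dimension")
  dimnames(counts) <- list(reference = classes, classified = classes)
  structure(list(counts = counts, classes = classes, n = sum(counts),
                 row_totals = rowSums(counts), col_totals = colSums(counts)),
            class = "error_matrix")
}

#' @export
print.error_matrix <- function(x, ...) {
  cat(sprintf("<error_matrix> n = %d (rows = reference, cols = classified)\n",
              x$n))
  print(x$counts)
  invisible(x)
}

#' Build an error matrix from reference points and a classified map
#'
#' @param points data frame with columns `row`, `col` and `reference`
#'   (reference class label, one of MF/NF/SF).
#' @param map a `land_cover_map` (the classified product under assessment).
#' @return list with `matrix` (an `error_matrix`) and `n_excluded` (points
#'   falling on WATER/NODATA cells, excluded with a warning).
#' @export
build_error_matrix <- function(points, map) {
  stopifnot(all(c("row", "col", "reference") %in% names(points)))
  map_code <- map$grid[cbind(points$row, points$col)]
  ok <- is_thematic(map_code)
  if (any(!ok)) {
    warning(sum(!ok), " reference point(s) on masked (WATER/NODATA) cells",
            " were excluded")
  }
  tab <- table(factor(points$reference[ok], levels = THEMATIC_CLASSES),
               factor(label_of(map_code[ok]), levels = THEMATIC_CLASSES))
  list(matrix = error_matrix(matrix(as.integer(tab), 3, 3)),
       n_excluded = sum(!ok))
}

#' Accuracy statistics of an error matrix
#'
#' Overall accuracy (trace/n), per-class omission error (row-wise:
#' 1 - n_ii / row total, the fraction of reference samples of the class
#' missed by the map) and commission error (column-wise: 1 - n_jj / column
#' total, the fraction of map samples wrongly assigned to the class).
#'
#' @param m an `error_matrix`.
#' @return list: `overall`, `omission` (named per class), `commission`
#'   (named per class), `n`. Per-class values are NA (flagged in
#'   `undefined`) when the corresponding total is 0.
#' @export
accuracy_stats <- function(m) {
  stopifnot(inherits(m, "error_matrix"))
  if (m$n == 0) stop("empty error matrix")
  d <- diag(m$counts)
  omission <- ifelse(m$row_totals > 0, 1 - d / m$row_totals, NA_real_)
  commission <- ifelse(m$col_totals > 0, 1 - d / m$col_totals, NA_real_)
  names(omission) <- names(commission) <- m$classes
  list(overall = sum(d) / m$n, omission = omission, commission = commission,
       n = m$n,
       undefined = m$classes[m$row_totals == 0 | m$col_totals == 0])
}

#' Inverse (Tenenbein) calibration of class-area proportions
#'
#' Pixel counting of a classified map gives biased ("naive") class
#' proportions when classes are confused. The inverse calibration estimator
#' revises them using the conditional reference-given-classified
#' probabilities estimated from the validation error matrix:
#'
#' p_j = (n_.j + f_j) / N, the combined proportion labelled j, with n_.j
#' the validation column total, f_j the map pixels classified as j outside
#' the validation sample, and N = n + sum(f_j);
#' pi_i = sum_j (n_ij / n_.j) * p_j, the calibrated proportion of class i.
#'
#' With an error-free (diagonal) matrix the calibration is the identity.
#'
#' @param m an `error_matrix` (rows reference, columns classified).
#' @param f_j named or ordered numeric vector: pixels classified as each
#'   class in the map, excluding validation pixels.
#' @param total_area_ha optional total thematic area to convert proportions
#'   to hectares.
#' @return list: `p_naive` (combined predicted-class proportions p_j),
#'   `pi_calibrated` (calibrated reference-class proportions), `N`, and
#'   when `total_area_ha` is given, `areas_naive_ha` / `areas_calibrated_ha`.
#' @export
inverse_calibrate <- function(m, f_j, total_area_ha = NULL) {
  stopifnot(inherits(m, "error_matrix"))
  k <- length(m$classes)
  if (length(f_j) != k) stop("f_j must have one entry per class")
  f_j <- as.numeric(f_j)
  if (any(f_j < 0)) stop("f_j must be nonnegative")
  if (any(m$col_totals == 0)) {
    stop("empty predicted column for class ",
         paste(m$classes[m$col_totals == 0], collapse = ", "),
         ": calibration undefined")
  }
  N <- m$n + sum(f_j)
  p <- (m$col_totals + f_j) / N
  cond <- sweep(m$counts, 2, m$col_totals, "/")  # P(reference i | classified j)
  pi_hat <- as.numeric(cond %*% p)
  names(p) <- names(pi_hat) <- m$classes
  out <- list(p_naive = p, pi_calibrated = pi_hat, N = N)
  if (!is.null(total_area_ha)) {
    out$areas_naive_ha <- p * total_area_ha
    out$areas_calibrated_ha <- pi_hat * total_area_ha
  }
  out
}

#' Overlay incidence of a mask on a classified map
#'
#' For each thematic class: the overlap area with a boolean overlay (e.g. a
#' digitised crop polygon layer), its relative incidence RI = 100 *
#' overlap / class area, and its share of the total overlay area.
#'
#' @param mask logical matrix, same shape as the map grid.
#' @param map a `land_cover_map`.
#' @return data frame: class, class_area_ha, overlap_ha, ri_pct,
#'   share_of_mask_pct.
#' @export
overlay_incidence <- function(mask, map) {
  if (!identical(dim(mask), dim(map$grid))) stop("mask shape mismatch")
  pa <- map$pixel_area_ha
  out <- data.frame(class = THEMATIC_CLASSES, class_area_ha = NA_real_,
                    overlap_ha = NA_real_, ri_pct = NA_real_,
                    share_of_mask_pct = NA_real_, stringsAsFactors = FALSE)
  mask_total <- sum(mask & is_thematic(map$grid)) * pa
  for (i in seq_along(THEMATIC_CODES)) {
    cls <- map$grid == THEMATIC_CODES[i]
    out$class_area_ha[i] <- sum(cls) * pa
    out$overlap_ha[i] <- sum(cls & mask) * pa
    out$ri_pct[i] <- if (out$class_area_ha[i] > 0) {
      100 * out$overlap_ha[i] / out$class_area_ha[i]
    } else 0
    out$share_of_mask_pct[i] <- if (mask_total > 0) {
      100 * out$overlap_ha[i] / mask_total
    } else 0
  }
  out
}

#' Deforestation incidence ratio outside vs inside a protected mask
#'
#' Ratio of the deforested fraction (NF + SF share of the thematic area)
#' outside a protected-area mask to that inside it. Values above 1 indicate
#' deforestation concentrates outside protection.
#'
#' @param protected logical matrix, TRUE inside protected areas.
#' @param map a `land_cover_map`.
#' @return list: `ratio`, `frac_outside`, `frac_inside`, `infinite`
#'   (TRUE when the inside deforested fraction is 0).
#' @export
protection_incidence_ratio <- function(protected, map) {
  if (!identical(dim(protected), dim(map$grid))) stop("mask shape mismatch")
  them <- is_thematic(map$grid)
  defo <- map$grid == LCC_CODES[["NF"]] | map$grid == LCC_CODES[["SF"]]
  n_in <- sum(them & protected); n_out <- sum(them & !protected)
  if (n_in == 0 || n_out == 0) {
    stop("mask must leave thematic area both inside and outside")
  }
  f_in <- sum(defo & protected) / n_in
  f_out <- sum(defo & !protected) / n_out
  list(ratio = if (f_in > 0) f_out / f_in else Inf,
       frac_outside = f_out, frac_inside = f_in, infinite = f_in == 0)
}
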