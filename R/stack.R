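#' Construct a dated land-cover map
#'
#' A single classified scene: an integer grid over the 5-code alphabet
#' (see [LCC_CODES]), its acquisition date and the per-pixel area.
#'
#' @param grid integer matrix of class codes.
#' @param date acquisition date: a `Date` or a yyyymmdd integer/string.
#' @param pixel_area_ha area of one pixel in hectares (> 0).
#' @return object of class `land_cover_map`.
#' @examples
#' m <- land_cover_map(matrix(c(1, 1, 2, 3), 2, 2), 19840617, 1)
#' class_areas(m)
#' @export
land_cover_map <- function(grid, date, pixel_area_ha = 0.09) {
  if (!is.matrix(grid)) grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  bad <- setdiff(unique(as.vector(grid)), unname(LCC_CODES))
  if (length(bad) > 0) {
    stop("unknown class code(s): ", paste(sort(bad), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(grid) < 1 || ncol(grid) < 1) stop("grid dimensions must be positive")
  if (!is.numeric(pixel_area_ha) || length(pixel_area_ha) != 1 ||
      pixel_area_ha <= 0) {
    stop("pixel_area_ha must be a positive scalar")
  }
  if (!inherits(date, "Date")) date <- parse_ymd(date)
  structure(list(grid = grid, date = date, pixel_area_ha = pixel_area_ha),
            class = "land_cover_map")
}

#' @export
print.land_cover_map <- function(x, ...) {
  cat(sprintf("<land_cover_map> %s  %d x %d  pixel %.4g ha\n",
              format_ymd(x$date), nrow(x$grid), ncol(x$grid),
              x$pixel_area_ha))
  tab <- class_areas(x)
  print(round(tab, 2))
  invisible(x)
}

#' Per-class area of a map in hectares
#'
#' @param map a `land_cover_map`.
#' @return named numeric vector over WATER, MF, NF, SF, NODATA.
#' @export
class_areas <- function(map) {
  counts <- tabulate(match(as.vector(map$grid), LCC_CODES),
                     nbins = length(LCC_CODES))
  stats::setNames(counts * map$pixel_area_ha, names(LCC_CODES))
}

#' Build a validated time-series stack of classified maps
#'
#' Sorts maps by date, checks shapes, pixel areas and date uniqueness, and
#' imposes a common water mask: the union of WATER cells over all dates is
#' relabelled WATER on every date, so open water is permanent.
#'
#' @param maps list of `land_cover_map` with identical shape and pixel area.
#' @return object of class `classified_stack` with fields `codes` (3-D
#'   integer array rows x cols x dates), `dates` (`Date` vector, strictly
#'   increasing), `pixel_area_ha`, `water_mask` (logical matrix).
#' @export
build_stack <- function(maps) {
  if (length(maps) < 1) stop("need at least one map")
  if (!all(vapply(maps, inherits, TRUE, "land_cover_map"))) {
    stop("all elements must be land_cover_map objects")
  }
  dims <- vapply(maps, function(m) dim(m$grid), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("map shapes differ across dates")
  }
  pa <- vapply(maps, function(m) m$pixel_area_ha, 1)
  if (any(abs(pa - pa[1]) > 1e-12)) stop("pixel_area_ha differs across dates")
  dates <- do.call(c, lapply(maps, function(m) m$date))
  if (anyDuplicated(dates)) {
    stop("duplicate acquisition dates in manifest: ",
         paste(format_ymd(dates[duplicated(dates)]), collapse = ", "))
  }
  ord <- order(dates)
  maps <- maps[ord]
  dates <- dates[ord]
  nr <- dims[1, 1]; nc <- dims[2, 1]; nd <- length(maps)
  codes <- array(NA_integer_, dim = c(nr, nc, nd))
  for (k in seq_len(nd)) codes[, , k] <- maps[[k]]$grid
  water <- apply(codes == LCC_CODES[["WATER"]], c(1, 2), any)
  codes[rep(water, nd)] <- LCC_CODES[["WATER"]]
  structure(list(codes = codes, dates = dates, pixel_area_ha = pa[1],
                 water_mask = water),
            class = "classified_stack")
}

#' @export
print.classified_stack <- function(x, ...) {
  cat(sprintf("<classified_stack> %d dates %s..%s  %d x %d  pixel %.4g ha\n",
              n_dates(x), format_ymd(x$dates[1]),
              format_ymd(x$dates[n_dates(x)]),
              dim(x$codes)[1], dim(x$codes)[2], x$pixel_area_ha))
  invisible(x)
}

#' Number of dates in a stack
#' @param stack a `classified_stack`.
#' @export
n_dates <- function(stack) length(stack$dates)

#' Extract one date of a stack as a land_cover_map
#' @param stack a `classified_stack`.
#' @param k date index (1-based, chronological).
#' @export
stack_map <- function(stack, k) {
  stopifnot(k >= 1, k <= n_dates(stack))
  land_cover_map(stack$codes[, , k, drop = TRUE], stack$dates[k],
                 stack$pixel_area_ha)
}

#' Maps of a stack as a list
#' @param stack a `classified_stack`.
#' @export
stack_maps <- function(stack) {
  lapply(seq_len(n_dates(stack)), function(k) stack_map(stack, k))
}

#' Decimal-year gaps between consecutive dates
#' @param stack a `classified_stack`.
#' @return numeric vector of length `n_dates(stack) - 1`.
#' @export
date_gaps <- function(stack) {
  n <- n_dates(stack)
  if (n < 2) return(numeric(0))
  decimal_years(stack$dates[-n], stack$dates[-1])
}

#' Fill cloud gaps over persistent mature forest
#'
#' Classified time-series commonly carry a cloud-free mature-forest mask
#' derived from the most recent clear scenes: where that mask indicates MF
#' has persisted for the whole series, NODATA (cloud) cells on earlier dates
#' are filled as MF. Cells outside the mask, and all non-NODATA cells, are
#' left untouched.
#'
#' @param stack a `classified_stack`.
#' @param mf_mask logical matrix, same shape as the stack grids; TRUE where
#'   the pixel is assumed MF throughout the series.
#' @return a new `classified_stack` with NODATA-under-mask cells set to MF.
#' @export
fill_cloud_gaps <- function(stack, mf_mask) {
  stopifnot(inherits(stack, "classified_stack"))
  if (!is.logical(mf_mask)) stop("mf_mask must be logical")
  if (!identical(dim(mf_mask), dim(stack$codes)[1:2])) {
    stop("mf_mask shape does not match stack grids")
  }
  nd <- n_dates(stack)
  fill <- rep(mf_mask & !is.na(mf_mask), nd) &
    (stack$codes == LCC_CODES[["NODATA"]])
  stack$codes[fill] <- LCC_CODES[["MF"]]
  stack
}
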