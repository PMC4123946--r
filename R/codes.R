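#' Land-cover class codes
#'
#' Fixed integer codes used in all grids and file exchange:
#' 0 = WATER, 1 = MF (mature forest), 2 = NF (non-forest),
#' 3 = SF (secondary forest), 255 = NODATA (cloud / missing).
#'
#' @format Named integer vector of length 5.
#' @export
LCC_CODES <- c(WATER = 0L, MF = 1L, NF = 2L, SF = 3L, NODATA = 255L)

#' @rdname LCC_CODES
#' @export
THEMATIC_CODES <- c(MF = 1L, NF = 2L, SF = 3L)

#' @rdname LCC_CODES
#' @export
THEMATIC_CLASSES <- c("MF", "NF", "SF")

#' Convert between class labels and integer codes
#'
#' @param label character vector of class names (MF, NF, SF, WATER, NODATA).
#' @param code integer vector of class codes.
#' @return `code_of`: integer codes; `label_of`: class names.
#' @export
code_of <- function(label) {
  unname(LCC_CODES[match(label, names(LCC_CODES))])
}

#' @rdname code_of
#' @export
label_of <- function(code) {
  names(LCC_CODES)[match(code, LCC_CODES)]
}

is_thematic <- function(code) code %in% THEMATIC_CODES

#' Parse dates in yyyymmdd format
#'
#' Acquisition dates in manifests are 8-digit integers or strings
#' (e.g. 19840617). Returns a `Date`.
#'
#' @param x integer or character vector of yyyymmdd dates.
#' @return `Date` vector.
#' @export
parse_ymd <- function(x) {
  d <- as.Date(as.character(x), format = "%Y%m%d")
  if (anyNA(d)) {
    stop("invalid yyyymmdd date(s): ",
         paste(x[is.na(d)], collapse = ", "), call. = FALSE)
  }
  d
}

#' Format a Date back to yyyymmdd
#' @param d Date vector.
#' @return character vector.
#' @export
format_ymd <- function(d) format(d, "%Y%m%d")

#' Interval between two dates in decimal years
#'
#' Day count divided by 365.25; acquisition dates are day-resolved and all
#' rates are per calendar year.
#'
#' @param d1,d2 `Date` scalars or vectors.
#' @return numeric decimal years (d2 - d1)/365.25.
#' @export
decimal_years <- function(d1, d2) {
  as.numeric(difftime(d2, d1, units = "days")) / 365.25
}
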