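#' Write a land-cover map to a headered text grid
#'
#' A small self-describing ASCII format for categorical grids (GeoTIFF
#' support would require a raster I/O library): four header lines
#' (`nrows`, `ncols`, `date` in yyyymmdd, `pixel_area_ha`) followed by one
#' space-separated row of integer codes per grid row. Round-trips are
#' bit-exact.
#'
#' @param map a `land_cover_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "land_cover_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("nrows", nrow(map$grid)),
               paste("ncols", ncol(map$grid)),
               paste("date", format_ymd(map$date)),
               paste("pixel_area_ha",
                     format(map$pixel_area_ha, digits = 17))), con)
  utils::write.table(map$grid, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a land-cover map from a headered text grid
#'
#' @param path file written by [write_map()].
#' @return a `land_cover_map`. Unknown class codes raise a format error
#'   naming the offending values.
#' @export
read_map <- function(path) {
  hdr <- readLines(path, n = 4)
  kv <- strsplit(hdr, " ")
  keys <- vapply(kv, `[`, "", 1)
  if (!identical(keys, c("nrows", "ncols", "date", "pixel_area_ha"))) {
    stop("not a land-cover grid file: ", path)
  }
  vals <- vapply(kv, `[`, "", 2)
  nr <- as.integer(vals[1]); nc <- as.integer(vals[2])
  grid <- as.matrix(utils::read.table(path, skip = 4, colClasses = "integer"))
  dimnames(grid) <- NULL
  if (!identical(dim(grid), c(nr, nc))) stop("grid shape does not match header")
  land_cover_map(grid, vals[3], as.numeric(vals[4]))
}

#' Read a stack from a manifest CSV
#'
#' The manifest has columns `date` (yyyymmdd) and `path` (grid file,
#' relative paths resolved against the manifest's directory).
#'
#' @param manifest_path path to the manifest CSV.
#' @return a `classified_stack`.
#' @export
read_stack <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, colClasses = "character")
  if (!all(c("date", "path") %in% names(man))) {
    stop("manifest must have columns date, path")
  }
  if (anyDuplicated(man$date)) stop("duplicate dates in manifest")
  base <- dirname(manifest_path)
  maps <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    m <- read_map(p)
    if (format_ymd(m$date) != man$date[i]) {
      stop("manifest date ", man$date[i], " does not match file date for ", p)
    }
    m
  })
  build_stack(maps)
}

#' Write a stack as grid files plus a manifest CSV
#'
#' @param stack a `classified_stack`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix for the per-date grids.
#' @return path of the manifest CSV, invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "map") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dates <- format_ymd(stack$dates)
  paths <- file.path(dir, paste0(prefix, "_", dates, ".grd"))
  for (k in seq_len(n_dates(stack))) write_map(stack_map(stack, k), paths[k])
  manifest <- file.path(dir, paste0(prefix, "_manifest.csv"))
  utils::write.csv(data.frame(date = dates, path = basename(paths)),
                   manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Export trajectory truth or metrics as a long CSV-ready table
#'
#' @param x a `trajectory_truth` or `metric_maps` object.
#' @return data frame (pixel_id, row, col, date, asf, asf_censored, palu,
#'   palu_zero, fc, fc_nf_start; plus `class` for truth objects), one row
#'   per pixel-date with any defined value.
#' @export
as_trajectory_df <- function(x) {
  dm <- dim(x$asf)
  npix <- dm[1] * dm[2]
  nd <- dm[3]
  idx <- expand.grid(pixel = seq_len(npix), k = seq_len(nd))
  out <- data.frame(
    pixel_id = idx$pixel,
    row = ((idx$pixel - 1) %% dm[1]) + 1,
    col = ((idx$pixel - 1) %/% dm[1]) + 1,
    date = format_ymd(x$dates)[idx$k],
    asf = as.vector(x$asf), asf_censored = as.vector(x$asf_censored),
    palu = as.vector(x$palu), palu_zero = as.vector(x$palu_zero),
    fc = as.vector(x$fc), fc_nf_start = as.vector(x$fc_nf_start),
    stringsAsFactors = FALSE)
  if (!is.null(x$class)) out$class <- label_of(as.vector(x$class))
  keep <- !is.na(out$fc) | !is.na(out$asf)
  out[keep, , drop = FALSE]
}
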