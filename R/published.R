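#' Published accuracy-assessment error matrices for three Amazon sites
#'
#' Validation error matrices (200 reference points per class; rows =
#' reference, columns = classified) for the most recent classified map at
#' three Brazilian Amazon Landsat time-series sites: Manaus (2007 map),
#' Santarém (2010) and Machadinho d'Oeste (2010).
#'
#' @return named list of `error_matrix` objects.
#' @export
amazon_error_matrices <- function() {
  list(
    manaus = error_matrix(matrix(c(186, 4, 10,
                                   8, 185, 7,
                                   11, 2, 187), 3, 3, byrow = TRUE)),
    santarem = error_matrix(matrix(c(196, 0, 4,
                                     0, 198, 2,
                                     23, 11, 166), 3, 3, byrow = TRUE)),
    machadinho = error_matrix(matrix(c(200, 0, 0,
                                       0, 197, 3,
                                       19, 37, 144), 3, 3, byrow = TRUE))
  )
}

#' Published land-cover proportion series for three Amazon sites
#'
#' Per-year percentages of mature forest (MF), non-forest (NF) and
#' secondary forest (SF) over the classified time-series at Manaus
#' (1973--2011), Santarém (1984--2010) and Machadinho d'Oeste (1984--2011),
#' printed to integer percent.
#'
#' @return data frame: site, year, MF, NF, SF.
#' @export
amazon_landcover_proportions <- function() {
  manaus <- data.frame(
    site = "manaus",
    year = c(1973, 1977, 1978, 1979, 1983, 1985, 1988, 1989, 1991, 1992,
             1994, 1995, 1996, 1999, 2001, 2002, 2003, 2006, 2007, 2008,
             2009, 2010, 2011),
    MF = c(91, 90, 90, 89, 88, 83, 81, 79, 79, 78, 78, 78, 78, 77, 77, 76,
           74, 73, 72, 72, 72, 72, 72),
    NF = c(4, 4, 5, 6, 7, 8, 8, 9, 8, 8, 8, 7, 5, 7, 7, 8, 7, 8, 8, 8, 9,
           9, 9),
    SF = c(5, 5, 5, 5, 5, 8, 11, 12, 13, 13, 14, 15, 17, 16, 16, 16, 20,
           19, 19, 20, 19, 19, 19))
  santarem <- data.frame(
    site = "santarem",
    year = c(1984, 1985, 1986, 1987, 1988, 1989, 1990, 1991, 1993, 1995,
             1996, 1997, 1998, 1999, 2000, 2001, 2003, 2005, 2006, 2007,
             2008, 2009, 2010),
    MF = c(79, 78, 76, 75, 72, 72, 71, 71, 65, 64, 63, 62, 53, 52, 51, 51,
           50, 48, 47, 47, 47, 46, 46),
    NF = c(2, 4, 6, 2, 12, 4, 4, 5, 10, 6, 10, 6, 15, 16, 9, 7, 13, 16,
           15, 10, 14, 11, 10),
    SF = c(19, 18, 19, 23, 16, 24, 25, 24, 26, 30, 27, 32, 32, 33, 40, 42,
           37, 36, 38, 43, 40, 43, 44))
  machadinho <- data.frame(
    site = "machadinho",
    year = c(1984, 1986, 1987, 1989, 1990, 1991, 1994, 1995, 1996, 1997,
             1998, 1999, 2001, 2003, 2005, 2006, 2007, 2008, 2009, 2010,
             2011),
    MF = c(91, 84, 82, 79, 77, 74, 68, 63, 60, 57, 55, 51, 48, 43, 38, 35,
           34, 33, 32, 32, 32),
    NF = c(1, 7, 5, 6, 5, 11, 12, 16, 12, 17, 16, 18, 23, 21, 27, 28, 31,
           38, 36, 33, 33),
    SF = c(9, 9, 13, 14, 18, 14, 20, 20, 28, 26, 29, 30, 29, 36, 34, 37,
           35, 29, 32, 35, 36))
  rbind(manaus, santarem, machadinho)
}

#' Published crop-overlay incidence for the Manaus and Machadinho sites
#'
#' Area (ha) of manually delineated tree-crop (TC) and perennial-crop (PC)
#' polygons falling in each classified class, with the published relative
#' incidence (RI, % of the class area), for the Manaus 2007 and Machadinho
#' d'Oeste 2010 maps.
#'
#' @return data frame: site, crop, class, overlap_ha, ri_pct.
#' @export
amazon_crop_overlay <- function() {
  data.frame(
    site = c(rep("manaus", 3), rep("machadinho", 6)),
    crop = c(rep("TC", 3), rep("PC", 3), rep("TC", 3)),
    class = rep(c("MF", "NF", "SF"), 3),
    overlap_ha = c(139, 398, 4237, 31, 540, 1323, 0, 14, 3),
    ri_pct = c(0.0, 1.0, 4.4, 0.1, 0.9, 2.1, 0.0, 0.0, 0.0),
    stringsAsFactors = FALSE)
}
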