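#' Water-year utilities
#'
#' A water year runs 1 October through 30 September and is labelled by the
#' calendar year in which it ends, the standard US hydrologic convention.
#' All temporally explicit windows in this package align to whole water
#' years.
#'
#' @param dates a `Date` vector.
#' @return `water_year()` returns an integer vector of water-year labels.
#' @examples
#' water_year(as.Date(c("1992-09-30", "1992-10-01")))  # 1992, 1993
#' @export
water_year <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  lt <- as.POSIXlt(dates)
  yr <- lt$year + 1900L
  ifelse(lt$mon + 1L >= 10L, yr + 1L, yr)
}

#' @rdname water_year
#' @param wy integer water-year label(s).
#' @return `water_year_start()` / `water_year_end()` return the first (1 Oct)
#'   and last (30 Sep) calendar dates of the water year.
#' @export
water_year_start <- function(wy) as.Date(sprintf("%d-10-01", wy - 1L))

#' @rdname water_year
#' @export
water_year_end <- function(wy) as.Date(sprintf("%d-09-30", wy))

# All dates of a run of water years, as a gap-free daily sequence.
water_year_dates <- function(wy_first, wy_last) {
  seq(water_year_start(wy_first), water_year_end(wy_last), by = "day")
}

# TRUE for dates in the wet season (November-April) of a Mediterranean
# climate; the complement (May-October) is the dry season.
is_wet_season <- function(dates) {
  m <- as.POSIXlt(dates)$mon + 1L
  m >= 11L | m <= 4L
}
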