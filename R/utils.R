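#' Decade endpoints of a study period
#'
#' The study period is divided into consecutive 10-year timesteps; cumulative
#' quantities are evaluated at the last calendar year of each step. For the
#' default 1870--2019 period this gives the 15 endpoints 1879, 1889, ..., 2019.
#'
#' @param start_year,end_year Integer calendar years delimiting the period
#'   (inclusive). The period length must be a multiple of 10.
#' @return Integer vector of decade endpoints.
#' @examples
#' decade_endpoints(1870, 2019)
#' @export
decade_endpoints <- function(start_year, end_year) {
  check_year_range(c(start_year, end_year))
  if ((end_year - start_year + 1L) %% 10L != 0L) {
    abort(sprintf(
      "Year range %d-%d is not divisible into 10-year timesteps.",
      start_year, end_year
    ))
  }
  seq(start_year + 9L, end_year, by = 10L)
}

check_year_range <- function(year_range) {
  if (length(year_range) != 2L || any(!is.finite(year_range)) ||
      year_range[2] < year_range[1]) {
    abort("`year_range` must be two finite years with start <= end.")
  }
  invisible(year_range)
}

# decade endpoint covering a calendar year
decade_end_of <- function(year, start_year) {
  start_year + 10L * ((year - start_year) %/% 10L) + 9L
}

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371 km, used as a fallback when a
#' country-pair distance is missing from the supplied distance table.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectorised).
#' @return Distance in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf(
      "%s is missing required column(s): %s", what,
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("%s must be finite and non-negative.", what))
  }
  invisible(x)
}
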