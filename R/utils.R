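#' Map Unix timestamps to local calendar days
#'
#' Converts Unix timestamps (seconds since 1970-01-01 UTC) to the calendar
#' date in a given time zone. Day counting for inclusion filters, daily
#' Wi-Fi minutes and daily distance all go through this single mapping.
#'
#' @param t Numeric vector of Unix timestamps in seconds.
#' @param tz Olson time-zone name; defaults to the cohort's local zone.
#' @return A `Date` vector of the same length.
#' @export
local_day <- function(t, tz = "America/Chicago") {
  as.Date(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"), tz = tz)
}

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Vectorised over its arguments with the usual recycling.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 1)   # one degree of longitude at the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  # clamp guards acos/asin domain error from rounding at antipodes
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Convert kilometres to miles
#'
#' @param km Distance in kilometres.
#' @return Distance in statute miles.
#' @export
km_to_miles <- function(km) km * 0.621371

# Internal: stop unless coordinates are within valid ranges.
check_coords <- function(lat, lon) {
  if (any(abs(lat) > 90, na.rm = TRUE) || any(abs(lon) > 180, na.rm = TRUE)) {
    abort("latitude must lie in [-90, 90] and longitude in [-180, 180]")
  }
  invisible(TRUE)
}
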