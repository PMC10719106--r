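# Great-circle distances: vaccine access is proxied by distance to the
# nearest district health clinic.

#' Haversine great-circle distance in kilometers
#'
#' Spherical-earth haversine distance with radius 6,371 km. Inputs are
#' decimal-degree latitude/longitude pairs; both arguments are recycled
#' row-wise, so one point against many works.
#'
#' @param a,b Numeric vectors `c(lat, lon)`, or two-column matrices /
#'   data frames with columns `lat`, `lon`.
#' @return Numeric vector of distances (km).
#' @export
#' @examples
#' great_circle_km(c(5.6037, -0.1870), c(5.5560, -0.1969))
great_circle_km <- function(a, b) {
  a <- as_latlon(a)
  b <- as_latlon(b)
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  rad <- pi / 180
  dlat <- (b[, 1] - a[, 1]) * rad
  dlon <- (b[, 2] - a[, 2]) * rad
  h <- sin(dlat / 2)^2 +
    cos(a[, 1] * rad) * cos(b[, 1] * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(h)))
}

as_latlon <- function(x) {
  if (is.data.frame(x)) {
    assert_cols(x, c("lat", "lon"), "coordinate table")
    x <- cbind(x$lat, x$lon)
  } else if (is.null(dim(x))) {
    if (length(x) != 2L) stop("a point must be c(lat, lon)")
    x <- matrix(x, ncol = 2L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("coordinates must have two columns (lat, lon)")
  if (any(!is.finite(x))) stop("coordinates must be finite")
  if (any(abs(x[, 1]) > 90)) stop("latitude must lie in [-90, 90]")
  x
}

#' Distance to the nearest clinic
#'
#' Minimum haversine distance from each point to any clinic.
#'
#' @param points Point(s): `c(lat, lon)` or a matrix/data frame.
#' @param clinics Clinic coordinates, one row per clinic (must be non-empty).
#' @return Numeric vector: nearest-clinic distance (km) per point.
#' @export
nearest_clinic_km <- function(points, clinics) {
  points <- as_latlon(points)
  clinics <- as_latlon(clinics)
  if (nrow(clinics) == 0L) stop("at least one clinic is required")
  d <- sapply(seq_len(nrow(clinics)), function(j) {
    great_circle_km(points, clinics[j, , drop = FALSE])
  })
  d <- matrix(d, nrow = nrow(points))
  apply(d, 1, min)
}
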