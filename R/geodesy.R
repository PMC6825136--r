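#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the mean Earth
#' radius). Used for all site-to-site distances, in particular the h-block
#' exclusion radius. At the 100-km granularity of the h grid, the
#' difference from an ellipsoidal geodesic is immaterial.
#'
#' @param a,b points as `c(lon, lat)` in decimal degrees (WGS84), or
#'   two-column matrices of such points. If both are matrices they must
#'   have the same number of rows; if one is a single point it is recycled.
#' @return Numeric vector of distances in km.
#' @examples
#' great_circle_km(c(0, 0), c(180, 0))  # half the Earth's circumference
#' @export
great_circle_km <- function(a, b) {
  a <- to_lonlat_matrix(a)
  b <- to_lonlat_matrix(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("a and b must have compatible numbers of points")
  haversine_km(a[, 1], a[, 2], b[, 1], b[, 2])
}

to_lonlat_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("lon", "lat")])
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (ncol(p) != 2) stop("points must be c(lon, lat) or a two-column matrix")
  storage.mode(p) <- "double"
  if (anyNA(p)) stop("coordinates must not be NA")
  if (any(p[, 1] < -180 | p[, 1] > 180))
    stop("longitude out of range [-180, 180]")
  if (any(p[, 2] < -90 | p[, 2] > 90))
    stop("latitude out of range [-90, 90]")
  p
}

haversine_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  h <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  h <- pmin(1, pmax(0, h))
  2 * .EARTH_RADIUS_KM * asin(sqrt(h))
}

#' Pairwise great-circle distance matrix
#'
#' @param coords two-column matrix or data frame with columns `lon`, `lat`.
#' @return Symmetric n x n matrix of distances in km.
#' @export
great_circle_matrix <- function(coords) {
  p <- to_lonlat_matrix(coords)
  n <- nrow(p)
  rad <- pi / 180
  lat <- p[, 2] * rad
  lon <- p[, 1] * rad
  coslat <- cos(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- sin((lat - lat[i]) / 2)^2 + coslat[i] * coslat * sin((lon - lon[i]) / 2)^2
    d[i, ] <- 2 * .EARTH_RADIUS_KM * asin(sqrt(pmin(1, pmax(0, h))))
  }
  (d + t(d)) / 2
}
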