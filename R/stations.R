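#' Scattered station observations
#'
#' A `station_set` holds scattered point observations of a pollutant
#' concentration field: one row per station (or city), with a longitude and
#' latitude in decimal degrees and an observed value in micrograms per cubic
#' metre. All interpolators in the package consume this container.
#'
#' @param ids Character or integer vector of opaque station labels.
#' @param lons,lats Numeric vectors of coordinates, degrees east / north.
#' @param values Numeric vector of observed concentrations.
#'
#' @return An object of class `station_set`: a list with fields `ids`,
#'   `lons`, `lats`, `values` and the station count `n`.
#'
#' @details Coordinates are treated as planar degrees (plate carree): all
#'   distances, influence radii and variogram ranges downstream are in the
#'   same degree units. Duplicated coordinate pairs are rejected because the
#'   kriging system becomes singular and a duplicate city is an input error.
#'
#' @examples
#' st <- station_set(c("a", "b", "c"), c(100, 110, 120), c(20, 30, 25),
#'                   c(35, 80, 55))
#' st$n
#' @export
station_set <- function(ids, lons, lats, values) {
  n <- length(values)
  if (n < 1L) stop("a station_set needs at least one station", call. = FALSE)
  if (length(lons) != n || length(lats) != n || length(ids) != n) {
    stop("ids, lons, lats and values must all have the same length",
         call. = FALSE)
  }
  lons <- as.numeric(lons)
  lats <- as.numeric(lats)
  values <- as.numeric(values)
  if (!all(is.finite(lons)) || !all(is.finite(lats))) {
    stop("station coordinates must all be finite", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("station values must all be finite", call. = FALSE)
  }
  if (anyDuplicated(cbind(lons, lats))) {
    stop("duplicate (lon, lat) station coordinates are not allowed",
         call. = FALSE)
  }
  structure(
    list(ids = as.character(ids), lons = lons, lats = lats,
         values = values, n = n),
    class = "station_set"
  )
}

#' @export
print.station_set <- function(x, ...) {
  cat(sprintf("<station_set> %d stations, lon [%.3f, %.3f], lat [%.3f, %.3f]\n",
              x$n, min(x$lons), max(x$lons), min(x$lats), max(x$lats)))
  cat(sprintf("  values: min %.2f, median %.2f, max %.2f ug/m3\n",
              min(x$values), stats::median(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.station_set <- function(x, ...) {
  data.frame(id = x$ids, lon = x$lons, lat = x$lats, value = x$values,
             stringsAsFactors = FALSE)
}

# Subset a station_set by integer index, keeping the class invariants.
subset_stations <- function(stations, idx) {
  station_set(stations$ids[idx], stations$lons[idx], stations$lats[idx],
              stations$values[idx])
}

#' Rectangular spatial domain
#'
#' The reference rectangle used to map geographic coordinates onto the
#' Chebyshev square \eqn{[-1, 1]^2}, and the bounding box of simulation and
#' gridding operations.
#'
#' @param lon_min,lon_max,lat_min,lat_max Box edges, decimal degrees.
#' @return An object of class `domain_box`.
#' @examples
#' domain_box(97, 123, 18, 38)
#' @export
domain_box <- function(lon_min, lon_max, lat_min, lat_max) {
  for (nm in c("lon_min", "lon_max", "lat_min", "lat_max")) {
    stopifnot_scalar_number(get(nm), nm)
  }
  if (lon_min >= lon_max || lat_min >= lat_max) {
    stop("invalid domain: need lon_min < lon_max and lat_min < lat_max",
         call. = FALSE)
  }
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max),
            class = "domain_box")
}

#' @export
print.domain_box <- function(x, ...) {
  cat(sprintf("<domain_box> lon [%g, %g], lat [%g, %g]\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

#' Bounding box of a station network
#'
#' @param stations A [station_set()].
#' @param pad Fraction of each axis span added symmetrically to both ends
#'   (default 0: the tight bounding box of the stations).
#' @return A [domain_box()].
#' @export
station_bbox <- function(stations, pad = 0) {
  stopifnot(inherits(stations, "station_set"))
  stopifnot_scalar_number(pad, "pad")
  w <- diff(range(stations$lons))
  h <- diff(range(stations$lats))
  if (w <= 0 || h <= 0) {
    stop("stations are collinear along an axis; cannot form a domain box",
         call. = FALSE)
  }
  domain_box(min(stations$lons) - pad * w, max(stations$lons) + pad * w,
             min(stations$lats) - pad * h, max(stations$lats) + pad * h)
}

domain_diagonal <- function(domain) {
  sqrt((domain$lon_max - domain$lon_min)^2 +
       (domain$lat_max - domain$lat_min)^2)
}
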