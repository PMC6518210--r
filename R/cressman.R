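#' Planar distance in degrees
#'
#' Euclidean distance on longitude/latitude treated as planar coordinates
#' (plate carree). All influence radii and variogram ranges in this package
#' are expressed in the same degree units.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees; vectors recycle.
#' @return Numeric vector of distances in degrees.
#' @export
euclidean_degree_distance <- function(lon1, lat1, lon2, lat2) {
  sqrt((lon1 - lon2)^2 + (lat1 - lat2)^2)
}

# Cross-distance matrix: rows = query points, cols = stations.
cross_distances <- function(qlon, qlat, slon, slat) {
  sqrt(outer(qlon, slon, "-")^2 + outer(qlat, slat, "-")^2)
}

#' Parameters of the adaptive-radius Cressman scheme
#'
#' @param r0 Initial influence radius, degrees (default 4).
#' @param r_step Radius increment when too few stations fall inside the
#'   current radius, degrees (default 0.1).
#' @param min_neighbors Minimum number of stations that must lie strictly
#'   inside the radius before a grid value is computed (default 5).
#' @param r_max Hard cap on the radius, degrees. `NULL` (default) means the
#'   diagonal of the station bounding box at interpolation time.
#' @return An object of class `cressman_params`.
#' @export
cressman_params <- function(r0 = 4, r_step = 0.1, min_neighbors = 5,
                            r_max = NULL) {
  stopifnot_scalar_number(r0, "r0")
  stopifnot_scalar_number(r_step, "r_step")
  stopifnot_scalar_number(min_neighbors, "min_neighbors")
  if (r0 <= 0) stop("invalid radius: r0 must be > 0", call. = FALSE)
  if (r_step <= 0) stop("r_step must be > 0", call. = FALSE)
  if (min_neighbors < 1) stop("min_neighbors must be >= 1", call. = FALSE)
  if (!is.null(r_max)) {
    stopifnot_scalar_number(r_max, "r_max")
    if (r_max < r0) stop("r_max must be >= r0", call. = FALSE)
  }
  structure(list(r0 = r0, r_step = r_step,
                 min_neighbors = as.integer(min_neighbors), r_max = r_max),
            class = "cressman_params")
}

#' Cressman distance-weighting kernel
#'
#' The classical objective-analysis weight
#' \eqn{w = (R^2 - d^2) / (R^2 + d^2)} for `d < R`, and 0 at or beyond the
#' radius. Decreasing in `d`, equal to 1 at the station itself.
#'
#' @param d Distances, degrees (`>= 0`); vectorized.
#' @param R Influence radius, degrees (`> 0`).
#' @return Weights in `[0, 1]`.
#' @examples
#' cressman_weight(2, 4) # 0.6
#' @export
cressman_weight <- function(d, R) {
  stopifnot_scalar_number(R, "R")
  if (R <= 0) stop("invalid radius: R must be > 0", call. = FALSE)
  if (any(d < 0)) stop("distances must be nonnegative", call. = FALSE)
  ifelse(d < R, (R^2 - d^2) / (R^2 + d^2), 0)
}

#' Cressman objective analysis with adaptive influence radius
#'
#' Single-pass distance-weighted interpolation. For each query point the
#' influence radius starts at `r0`; if fewer than `min_neighbors` stations
#' lie strictly inside it, the radius is increased in steps of `r_step`
#' until enough do (equivalently: the final radius is the smallest value in
#' `r0 + j * r_step`, integer `j >= 0`, strictly exceeding the
#' `min_neighbors`-th nearest station distance). The estimate is the
#' kernel-weighted mean of the in-range station values, so it always lies
#' within the range of those values. There are no successive-correction
#' iterations.
#'
#' @param stations A [station_set()] with at least `min_neighbors` stations.
#' @param lons,lats Query coordinates (degrees), equal length.
#' @param params A [cressman_params()].
#' @return A list with `values` (estimates, ug/m3) and `radii` (final
#'   influence radius used at each query point, degrees).
#' @examples
#' dom <- domain_box(97, 123, 18, 38)
#' st <- sample_stations(ie1_preset(dom), n = 50, seed = 1)
#' cressman_interpolate(st, 110, 28, cressman_params())$values
#' @export
cressman_interpolate <- function(stations, lons, lats,
                                 params = cressman_params()) {
  stopifnot(inherits(stations, "station_set"),
            inherits(params, "cressman_params"))
  if (length(lons) != length(lats)) {
    stop("lons and lats must have equal length", call. = FALSE)
  }
  if (stations$n < params$min_neighbors) {
    stop(sprintf("need at least min_neighbors = %d stations, have %d",
                 params$min_neighbors, stations$n), call. = FALSE)
  }
  r_max <- params$r_max
  if (is.null(r_max)) {
    r_max <- max(params$r0, domain_diagonal(station_bbox(stations)))
  }
  D <- cross_distances(lons, lats, stations$lons, stations$lats)
  m <- length(lons)
  values <- numeric(m)
  radii <- numeric(m)
  kth <- params$min_neighbors
  for (p in seq_len(m)) {
    d <- D[p, ]
    dk <- sort(d, partial = kth)[kth]
    # smallest radius on the r0 + j * r_step ladder with d_(k) strictly inside
    if (dk < params$r0) {
      R <- params$r0
    } else {
      j <- floor((dk - params$r0) / params$r_step) + 1
      while (params$r0 + j * params$r_step <= dk) j <- j + 1
      R <- params$r0 + j * params$r_step
    }
    if (R > r_max) {
      stop(sprintf(
        "no-neighbors: point (%.4f, %.4f) needs radius %.2f > r_max %.2f to reach %d stations",
        lons[p], lats[p], R, r_max, kth), call. = FALSE)
    }
    w <- cressman_weight(d, R)
    values[p] <- sum(w * stations$values) / sum(w)
    radii[p] <- R
  }
  list(values = values, radii = radii)
}
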