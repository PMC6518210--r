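#' Smooth bimodal truth field for twin experiments
#'
#' A `blob_field` is a deterministic concentration surface built from a
#' constant background plus Gaussian bumps:
#' \deqn{f(p) = background + \sum_c A_c \exp(-d_c(p)^2 / (2 w_c^2))}
#' with \eqn{d_c} the planar-degree distance from `p` to center `c`.
#' Negative amplitudes carve out low-concentration ("slight contamination")
#' regions. These fields stand in for the prescribed truth maps of a twin
#' experiment: a known surface is sampled at stations and the interpolators
#' are scored against it.
#'
#' @param background Background concentration, ug/m3.
#' @param centers Data frame with columns `lon`, `lat`, `amplitude`
#'   (ug/m3, may be negative) and `width` (degrees, `> 0`).
#' @param domain A [domain_box()].
#' @return An object of class `blob_field`.
#' @export
blob_field <- function(background, centers, domain) {
  stopifnot(inherits(domain, "domain_box"))
  stopifnot_scalar_number(background, "background")
  centers <- as.data.frame(centers)
  if (nrow(centers) > 0) {
    req <- c("lon", "lat", "amplitude", "width")
    if (!all(req %in% names(centers))) {
      stop("centers needs columns lon, lat, amplitude, width", call. = FALSE)
    }
    if (any(centers$width <= 0)) stop("widths must be > 0", call. = FALSE)
  }
  structure(list(background = background, centers = centers, domain = domain),
            class = "blob_field")
}

#' Evaluate a truth field at points
#'
#' @param field A [blob_field()].
#' @param lons,lats Coordinate vectors (degrees), equal length.
#' @return Numeric vector of field values, ug/m3.
#' @export
evaluate_field <- function(field, lons, lats) {
  stopifnot(inherits(field, "blob_field"))
  if (length(lons) != length(lats)) {
    stop("lons and lats must have equal length", call. = FALSE)
  }
  v <- rep(field$background, length(lons))
  for (c_i in seq_len(nrow(field$centers))) {
    ctr <- field$centers[c_i, ]
    d2 <- (lons - ctr$lon)^2 + (lats - ctr$lat)^2
    v <- v + ctr$amplitude * exp(-d2 / (2 * ctr$width^2))
  }
  v
}

#' Default study-zone domain
#'
#' A rectangle approximating central and southern China (lon 97-123, lat
#' 18-38 degrees), sized so that degree-scaled interpolation parameters
#' (a 4-degree influence radius, a 10-degree variogram range) have
#' sensible reach. Override freely.
#'
#' @return A [domain_box()].
#' @export
default_domain <- function() domain_box(97, 123, 18, 38)

#' Twin-experiment preset fields
#'
#' Two canonical pollution geometries. `ie1_preset()` places a
#' heavy-contamination center in the northwest quadrant and a
#' slight-contamination (negative-amplitude) center in the southeast — the
#' most common continental PM2.5 pattern. `ie2_preset()` puts the heavy
#' center in the southeast and the slight center in the southwest, a
#' pattern typical of spring and autumn. Default magnitudes (background 60,
#' amplitudes +70 / -50 ug/m3, widths 4 degrees) keep field values in
#' roughly the 10-130 ug/m3 range of daily PM2.5 maps, nonnegative
#' everywhere in the domain, and give the centers the distinct regional
#' footprint (roughly 8-degree diameter at half maximum) of observed
#' contamination episodes.
#'
#' @param domain A [domain_box()] (default [default_domain()]).
#' @param background Background level, ug/m3.
#' @param amp_heavy Amplitude of the heavy-contamination center (`> 0`).
#' @param amp_slight Amplitude of the slight-contamination center
#'   (negative: a clean-air pocket).
#' @param width Gaussian width of both centers, degrees.
#' @return A [blob_field()].
#' @examples
#' fld <- ie1_preset()
#' evaluate_field(fld, 104.8, 32) # at the heavy NW center: 130
#' @export
ie1_preset <- function(domain = default_domain(), background = 60,
                       amp_heavy = 70, amp_slight = -50, width = 4) {
  at <- function(fx, fy) c(domain$lon_min + fx * (domain$lon_max - domain$lon_min),
                           domain$lat_min + fy * (domain$lat_max - domain$lat_min))
  nw <- at(0.30, 0.70)
  se <- at(0.70, 0.30)
  blob_field(background, data.frame(
    lon = c(nw[1], se[1]), lat = c(nw[2], se[2]),
    amplitude = c(amp_heavy, amp_slight), width = c(width, width)
  ), domain)
}

#' @rdname ie1_preset
#' @export
ie2_preset <- function(domain = default_domain(), background = 60,
                       amp_heavy = 70, amp_slight = -50, width = 4) {
  at <- function(fx, fy) c(domain$lon_min + fx * (domain$lon_max - domain$lon_min),
                           domain$lat_min + fy * (domain$lat_max - domain$lat_min))
  se <- at(0.70, 0.30)
  sw <- at(0.30, 0.30)
  blob_field(background, data.frame(
    lon = c(se[1], sw[1]), lat = c(se[2], sw[2]),
    amplitude = c(amp_heavy, amp_slight), width = c(width, width)
  ), domain)
}

#' Sample a synthetic station network from a truth field
#'
#' Draws `n` station locations by seeded jittered-grid placement: the
#' domain is tiled by a near-square grid of `n` cells and one location is
#' drawn uniformly inside each cell. This yields an irregular but
#' space-covering network resembling a national city monitoring network,
#' without duplicate coordinates. Station values are the field evaluated at
#' the drawn locations plus optional i.i.d. Gaussian observation noise.
#'
#' @param field A [blob_field()] (its `domain` is the sampling region).
#' @param n Number of stations (default 225).
#' @param seed Integer seed; the result is a deterministic function of it.
#' @param noise_sd Standard deviation of additive observation noise, ug/m3
#'   (default 0: stations observe the field exactly).
#' @return A [station_set()] with ids `"S001"`, `"S002"`, ...
#' @examples
#' st <- sample_stations(ie1_preset(), n = 225, seed = 42, noise_sd = 5)
#' st
#' @export
sample_stations <- function(field, n = 225, seed, noise_sd = 0) {
  stopifnot(inherits(field, "blob_field"))
  stopifnot_scalar_number(n, "n")
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  dom <- field$domain
  with_seed(seed, {
    nx <- ceiling(sqrt(n))
    ny <- ceiling(n / nx)
    # first n cells of the nx-by-ny tiling, lon index varying fastest
    cell <- seq_len(n) - 1L
    ix <- cell %% nx
    iy <- cell %/% nx
    wx <- (dom$lon_max - dom$lon_min) / nx
    wy <- (dom$lat_max - dom$lat_min) / ny
    lons <- dom$lon_min + (ix + stats::runif(n)) * wx
    lats <- dom$lat_min + (iy + stats::runif(n)) * wy
    vals <- evaluate_field(field, lons, lats)
    if (noise_sd > 0) vals <- vals + stats::rnorm(n, sd = noise_sd)
    station_set(sprintf("S%03d", seq_len(n)), lons, lats, vals)
  })
}
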