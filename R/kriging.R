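#' Spherical semivariogram model
#'
#' Fixed-parameter spherical model used by the ordinary-kriging comparator.
#' Defaults follow the study configuration: range 10 degrees, sill 1,
#' nugget 0. The sill only scales the kriging variance, not the estimates
#' (with zero nugget the weights are invariant to a positive rescaling of
#' the sill), so its nominal units are immaterial to interpolated values.
#'
#' @param range_a Range, degrees (`> 0`; default 10).
#' @param sill Sill, squared concentration units (`> 0`; default 1).
#' @param nugget Nugget variance (`>= 0`; default 0, giving exact
#'   interpolation at station locations).
#' @return An object of class `variogram_model` with `model = "spherical"`.
#' @export
variogram_model <- function(range_a = 10, sill = 1, nugget = 0) {
  stopifnot_scalar_number(range_a, "range_a")
  stopifnot_scalar_number(sill, "sill")
  stopifnot_scalar_number(nugget, "nugget")
  if (range_a <= 0) stop("range_a must be > 0", call. = FALSE)
  if (sill <= 0) stop("sill must be > 0", call. = FALSE)
  if (nugget < 0) stop("nugget must be >= 0", call. = FALSE)
  structure(list(model = "spherical", range_a = range_a, sill = sill,
                 nugget = nugget),
            class = "variogram_model")
}

#' Spherical semivariance at lag h
#'
#' \eqn{\gamma(0) = 0}; for \eqn{0 < h \le a},
#' \eqn{\gamma(h) = nugget + sill (1.5 h/a - 0.5 (h/a)^3)}; beyond the
#' range, \eqn{\gamma(h) = nugget + sill}. Nondecreasing in `h`.
#'
#' @param h Lag distances, degrees (`>= 0`); vectorized.
#' @param model A [variogram_model()].
#' @return Semivariance values.
#' @examples
#' spherical_semivariogram(5, variogram_model(range_a = 10)) # 0.6875
#' @export
spherical_semivariogram <- function(h, model = variogram_model()) {
  stopifnot(inherits(model, "variogram_model"))
  if (any(h < 0)) stop("invalid lag: h must be >= 0", call. = FALSE)
  r <- pmin(h / model$range_a, 1)
  g <- model$nugget + model$sill * (1.5 * r - 0.5 * r^3)
  g[h == 0] <- 0
  g
}

#' Ordinary kriging with a fixed spherical semivariogram
#'
#' Global ordinary kriging: every query point uses all stations (no search
#' neighborhood; networks here are small). Per point, the weights solve the
#' standard `(n + 1)`-equation system — semivariogram matrix rows plus the
#' unbiasedness constraint that weights sum to one, with a Lagrange
#' multiplier — and the estimate is the weighted sum of observations. With
#' zero nugget the predictor interpolates exactly at station locations.
#' The coefficient matrix is factorized once and shared across all query
#' points.
#'
#' @param stations A [station_set()] with `n >= 2` (duplicate coordinates
#'   are already rejected by the constructor).
#' @param lons,lats Query coordinates (degrees), equal length.
#' @param model A [variogram_model()].
#' @param return_variance Also return the kriging variance per point.
#' @return A list with `values` (estimates, ug/m3), `weight_sums`
#'   (diagnostic; equal to 1 up to solver round-off), and, if requested,
#'   `variance`.
#' @examples
#' dom <- domain_box(97, 123, 18, 38)
#' st <- sample_stations(ie1_preset(dom), n = 50, seed = 1)
#' ordinary_kriging(st, 110, 28)$values
#' @export
ordinary_kriging <- function(stations, lons, lats,
                             model = variogram_model(),
                             return_variance = FALSE) {
  stopifnot(inherits(stations, "station_set"),
            inherits(model, "variogram_model"))
  if (length(lons) != length(lats)) {
    stop("lons and lats must have equal length", call. = FALSE)
  }
  n <- stations$n
  if (n < 2L) stop("ordinary kriging needs at least 2 stations", call. = FALSE)

  Ds <- cross_distances(stations$lons, stations$lats,
                        stations$lons, stations$lats)
  A <- matrix(1, n + 1L, n + 1L)
  A[1:n, 1:n] <- spherical_semivariogram(Ds, model)
  A[n + 1L, n + 1L] <- 0

  D0 <- cross_distances(stations$lons, stations$lats, lons, lats)
  G0 <- spherical_semivariogram(D0, model)
  dim(G0) <- c(n, length(lons))
  B <- rbind(G0, rep(1, length(lons)))

  W <- tryCatch(solve(A, B), error = function(e) {
    stop("singular kriging system: ", conditionMessage(e), call. = FALSE)
  })
  w <- W[1:n, , drop = FALSE]
  out <- list(values = drop(crossprod(w, stations$values)),
              weight_sums = colSums(w))
  if (return_variance) {
    # sigma^2 = sum_i w_i * gamma(s_i, s0) + mu
    out$variance <- colSums(w * B[1:n, , drop = FALSE]) + W[n + 1L, ]
  }
  out
}
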