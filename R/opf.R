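#' Map a coordinate onto the Chebyshev reference interval
#'
#' Affine map of a geographic coordinate from `[lo, hi]` onto `[-1, 1]`:
#' `t = 2 * (coord - lo) / (hi - lo) - 1`. Chebyshev polynomials of the
#' first kind are defined on this reference interval, so every fit and
#' evaluation passes coordinates through this map first.
#'
#' @param coord Numeric vector of coordinates (degrees).
#' @param lo,hi Interval endpoints, `lo < hi`.
#' @return Numeric vector of reference coordinates; `lo` maps to -1 and
#'   `hi` to +1. Points outside `[lo, hi]` map outside `[-1, 1]`.
#' @examples
#' map_to_reference(110, 100, 120) # 0
#' @export
map_to_reference <- function(coord, lo, hi) {
  stopifnot_scalar_number(lo, "lo")
  stopifnot_scalar_number(hi, "hi")
  if (lo >= hi) stop("invalid domain: need lo < hi", call. = FALSE)
  2 * (coord - lo) / (hi - lo) - 1
}

#' Chebyshev polynomials of the first kind
#'
#' Evaluates \eqn{T_0, \ldots, T_{n_{max}}} at each reference coordinate via
#' the three-term recurrence \eqn{T_m = 2 t T_{m-1} - T_{m-2}}. On
#' \eqn{[-1, 1]} this agrees with the closed form
#' \eqn{T_m(t) = \cos(m \arccos t)}; the recurrence also extends smoothly to
#' points slightly outside the interval, which occur when evaluating a
#' fitted surface on a padded grid.
#'
#' @param t Numeric vector of reference coordinates.
#' @param n_max Highest polynomial order, `>= 0`.
#' @return A `length(t)` by `n_max + 1` matrix; column `m + 1` holds
#'   \eqn{T_m(t)}.
#' @examples
#' chebyshev_basis(0.5, 3) # 1, 0.5, -0.5, -1
#' @export
chebyshev_basis <- function(t, n_max) {
  stopifnot_scalar_number(n_max, "n_max")
  if (n_max < 0 || n_max != round(n_max)) {
    stop("invalid order: n_max must be a nonnegative integer", call. = FALSE)
  }
  t <- as.numeric(t)
  if (!all(is.finite(t))) stop("t must be finite", call. = FALSE)
  n_max <- as.integer(n_max)
  out <- matrix(0, nrow = length(t), ncol = n_max + 1L)
  out[, 1L] <- 1
  if (n_max >= 1L) out[, 2L] <- t
  if (n_max >= 2L) {
    for (m in 2L:n_max) {
      out[, m + 1L] <- 2 * t * out[, m] - out[, m - 1L]
    }
  }
  out
}

# Tensor-product design matrix for scattered points already inside a domain.
# Column j * (s + 1) + i + 1 holds T_i(x') * T_j(y'), i = 0..s, j = 0..k,
# so the first column is the constant basis function.
design_matrix_points <- function(lons, lats, s, k, domain) {
  x <- map_to_reference(lons, domain$lon_min, domain$lon_max)
  y <- map_to_reference(lats, domain$lat_min, domain$lat_max)
  bx <- chebyshev_basis(x, s)
  by <- chebyshev_basis(y, k)
  # Khatri-Rao style row-wise tensor product with lon-order varying fastest.
  out <- matrix(0, nrow = length(lons), ncol = (s + 1L) * (k + 1L))
  for (j in 0:k) {
    cols <- j * (s + 1L) + seq_len(s + 1L)
    out[, cols] <- bx * by[, j + 1L]
  }
  out
}

#' Design matrix of the tensor-product Chebyshev basis
#'
#' Builds the least-squares design matrix whose row for station `r` holds
#' \eqn{T_i(x'_r) T_j(y'_r)} for all order pairs `(i, j)` with `i <= s`,
#' `j <= k`, where `x', y'` are station coordinates mapped to the reference
#' square by [map_to_reference()]. Columns are ordered with the longitude
#' order `i` varying fastest: column `j * (s + 1) + i + 1` corresponds to
#' the coefficient \eqn{a_{ij}}.
#'
#' @param stations A [station_set()].
#' @param s,k Polynomial orders in the longitude and latitude directions.
#' @param domain A [domain_box()] defining the reference rectangle.
#' @return An `n` by `(s + 1) * (k + 1)` numeric matrix.
#' @export
build_design_matrix <- function(stations, s, k, domain) {
  stopifnot(inherits(stations, "station_set"), inherits(domain, "domain_box"))
  check_order(s, "s")
  check_order(k, "k")
  design_matrix_points(stations$lons, stations$lats, s, k, domain)
}

check_order <- function(o, name) {
  stopifnot_scalar_number(o, name)
  if (o < 0 || o != round(o)) {
    stop(sprintf("invalid order: `%s` must be a nonnegative integer", name),
         call. = FALSE)
  }
  invisible(as.integer(o))
}

#' Fit a Chebyshev polynomial surface to scattered observations
#'
#' Least-squares fit of the tensor-product Chebyshev expansion
#' \deqn{f(x, y) = \sum_{i=0}^{s} \sum_{j=0}^{k} a_{ij} T_i(x') T_j(y')}
#' to the station values, where `x', y'` are coordinates mapped onto
#' \eqn{[-1,1]^2} over `domain`. The system is solved by rank-revealing SVD
#' least squares: singular values below `svd_tol` times the largest are
#' truncated, and if that happens the minimum-norm solution is returned
#' with a warning. High orders on a couple of hundred scattered stations
#' are genuinely ill-conditioned, which is why a plain normal-equations
#' solve is avoided.
#'
#' @param stations A [station_set()]; needs at least `(s+1) * (k+1)`
#'   stations.
#' @param s,k Polynomial orders in longitude and latitude (default cap 10;
#'   see `max_order`).
#' @param domain Reference rectangle; defaults to the tight bounding box of
#'   the training stations ([station_bbox()]).
#' @param svd_tol Relative singular-value cutoff (default `1e-10`).
#' @param max_order Soft policy cap on `s` and `k` (default 10); pass a
#'   larger value explicitly to override.
#' @return An object of class `chebyshev_surface`: fields `s`, `k`,
#'   `domain` and the `(s+1)` by `(k+1)` coefficient matrix `coeffs`
#'   (`coeffs[i+1, j+1]` is \eqn{a_{ij}}), plus diagnostic fields
#'   `fitted`, `residuals`, `rank` and `condition`.
#' @examples
#' dom <- domain_box(97, 123, 18, 38)
#' fld <- ie1_preset(dom)
#' st <- sample_stations(fld, n = 225, seed = 1)
#' surf <- fit_surface(st, s = 5, k = 5, domain = dom)
#' surf
#' @export
fit_surface <- function(stations, s, k, domain = station_bbox(stations),
                        svd_tol = 1e-10, max_order = 10) {
  stopifnot(inherits(stations, "station_set"), inherits(domain, "domain_box"))
  s <- check_order(s, "s")
  k <- check_order(k, "k")
  if (s > max_order || k > max_order) {
    stop(sprintf("orders (s=%d, k=%d) exceed the policy cap max_order=%d",
                 s, k, as.integer(max_order)), call. = FALSE)
  }
  p <- (s + 1L) * (k + 1L)
  if (stations$n < p) {
    stop(sprintf(
      "underdetermined fit: %d stations but orders (s=%d, k=%d) require at least %d",
      stations$n, s, k, p), call. = FALSE)
  }
  X <- design_matrix_points(stations$lons, stations$lats, s, k, domain)
  z <- stations$values

  sv <- svd(X)
  keep <- sv$d > svd_tol * sv$d[1L]
  rank <- sum(keep)
  if (rank < p) {
    warning(sprintf(
      "rank-deficient design (rank %d of %d); returning the minimum-norm solution",
      rank, p), call. = FALSE)
  }
  dinv <- ifelse(keep, 1 / sv$d, 0)
  beta <- sv$v %*% (dinv * crossprod(sv$u, z))
  fitted <- drop(X %*% beta)

  structure(
    list(s = s, k = k, domain = domain,
         coeffs = matrix(beta, nrow = s + 1L, ncol = k + 1L),
         fitted = fitted, residuals = z - fitted,
         rank = rank,
         condition = sv$d[1L] / sv$d[max(which(keep))]),
    class = "chebyshev_surface"
  )
}

#' @export
print.chebyshev_surface <- function(x, ...) {
  cat(sprintf("<chebyshev_surface> orders (s=%d, k=%d), %d coefficients\n",
              x$s, x$k, length(x$coeffs)))
  cat(sprintf("  domain: lon [%g, %g], lat [%g, %g]\n",
              x$domain$lon_min, x$domain$lon_max,
              x$domain$lat_min, x$domain$lat_max))
  cat(sprintf("  fit: rank %d, condition %.3g, residual RMS %.4g\n",
              x$rank, x$condition, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Evaluate a fitted Chebyshev surface
#'
#' Computes \eqn{\sum_{ij} a_{ij} T_i(x') T_j(y')} at arbitrary points.
#' Evaluation at the original fitting stations reproduces the least-squares
#' fitted values. Raw polynomial values can be negative; `clip_zero` floors
#' them at 0 for presentation output only and must stay off when computing
#' error metrics.
#'
#' @param surface A `chebyshev_surface` from [fit_surface()].
#' @param lons,lats Equal-length coordinate vectors (degrees).
#' @param clip_zero Floor negative values at zero (default `FALSE`).
#' @return Numeric vector of surface values.
#' @export
evaluate_surface <- function(surface, lons, lats, clip_zero = FALSE) {
  stopifnot(inherits(surface, "chebyshev_surface"))
  if (length(lons) != length(lats)) {
    stop("lons and lats must have equal length", call. = FALSE)
  }
  x <- map_to_reference(lons, surface$domain$lon_min, surface$domain$lon_max)
  y <- map_to_reference(lats, surface$domain$lat_min, surface$domain$lat_max)
  bx <- chebyshev_basis(x, surface$s)
  by <- chebyshev_basis(y, surface$k)
  v <- rowSums((bx %*% surface$coeffs) * by)
  if (clip_zero) v <- pmax(v, 0)
  v
}

#' @export
predict.chebyshev_surface <- function(object, lons, lats, ...) {
  evaluate_surface(object, lons, lats, ...)
}

#' Serialize a fitted surface to JSON
#'
#' Writes `{s, k, domain, coeffs}` as plain JSON so fitted surfaces are
#' portable across languages; [read_surface_json()] round-trips losslessly.
#' The coefficient matrix is stored row-by-row: `coeffs[[i+1]][[j+1]]` is
#' \eqn{a_{ij}} (longitude order `i`, latitude order `j`).
#'
#' @param surface A `chebyshev_surface`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface_json <- function(surface, path) {
  stopifnot(inherits(surface, "chebyshev_surface"))
  doc <- list(
    s = surface$s, k = surface$k,
    domain = surface$domain[c("lon_min", "lon_max", "lat_min", "lat_max")],
    coeffs = apply(surface$coeffs, 1L, identity, simplify = FALSE)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_surface_json
#' @return `read_surface_json()` returns the reconstructed
#'   `chebyshev_surface` (without fit diagnostics).
#' @export
read_surface_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dom <- domain_box(doc$domain$lon_min, doc$domain$lon_max,
                    doc$domain$lat_min, doc$domain$lat_max)
  coeffs <- doc$coeffs
  if (is.list(coeffs)) coeffs <- do.call(rbind, coeffs)
  coeffs <- matrix(as.numeric(coeffs), nrow = doc$s + 1L, ncol = doc$k + 1L,
                   byrow = FALSE)
  structure(
    list(s = as.integer(doc$s), k = as.integer(doc$k), domain = dom,
         coeffs = coeffs, fitted = NULL, residuals = NULL,
         rank = NA_integer_, condition = NA_real_),
    class = "chebyshev_surface"
  )
}
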