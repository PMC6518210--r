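test_that("reference mapping is the documented affine map and rejects bad domains", {
  expect_equal(map_to_reference(110, 100, 120), 0)
  expect_equal(map_to_reference(100, 100, 120), -1)
  expect_equal(map_to_reference(120, 100, 120), 1)
  expect_equal(map_to_reference(3, 0, 4), 0.5)
  # strictly monotone, vectorized
  t <- map_to_reference(seq(100, 120, by = 0.5), 100, 120)
  expect_true(all(diff(t) > 0))
  expect_error(map_to_reference(1, 5, 5), "lo < hi")
  expect_error(map_to_reference(1, 7, 5), "lo < hi")
})

test_that("Chebyshev recurrence matches closed form and known values", {
  expect_equal(drop(chebyshev_basis(0.5, 3)), c(1, 0.5, -0.5, -1))
  expect_equal(drop(chebyshev_basis(1, 4)), rep(1, 5))
  expect_equal(drop(chebyshev_basis(-1, 3)), c(1, -1, 1, -1))
  set.seed(401)
  t <- stats::runif(1000, -1, 1)
  B <- chebyshev_basis(t, 10)
  for (m in 0:10) {
    expect_lt(max(abs(B[, m + 1] - cos(m * acos(t)))), 1e-10)
  }
  expect_error(chebyshev_basis(0.3, -1), "invalid order")
})

test_that("design matrix holds tensor products in the documented column order", {
  dom <- test_domain()
  center <- station_set("c", 110, 28, 1)
  row <- build_design_matrix(center, 2, 2, dom)
  # T(0) = (1, 0, -1) tensored with itself
  expect_equal(drop(row), c(1, 0, -1, 0, 0, 0, -1, 0, 1))

  st <- scatter_stations(7, seed = 21)
  expect_equal(build_design_matrix(st, 0, 0, dom),
               matrix(1, nrow = 7, ncol = 1))

  # order (1,1) columns match direct monomial-style evaluation {1, x, y, xy}
  st3 <- scatter_stations(3, seed = 22)
  X <- build_design_matrix(st3, 1, 1, dom)
  r <- ref_xy(st3$lons, st3$lats, dom)
  expect_equal(X, cbind(1, r$x, r$y, r$x * r$y), ignore_attr = TRUE)
})

test_that("fitting a constant field recovers a single constant coefficient", {
  dom <- test_domain()
  st <- scatter_stations(40, seed = 31, fun = function(lon, lat) 0 * lon + 42)
  for (ord in list(c(0, 0), c(2, 3), c(5, 5))) {
    surf <- fit_surface(st, ord[1], ord[2], domain = dom)
    expect_equal(surf$coeffs[1, 1], 42, tolerance = 1e-8)
    off_diag <- surf$coeffs
    off_diag[1, 1] <- 0
    expect_lt(max(abs(off_diag)), 1e-8)
    expect_equal(surf$fitted, rep(42, st$n), tolerance = 1e-8)
  }
})

test_that("noiseless Chebyshev data is refit with the generating coefficients", {
  dom <- test_domain()
  gen <- function(lon, lat) {
    r <- ref_xy(lon, lat, dom)
    3 * r$x - 2 * (2 * r$y^2 - 1) # 3 T1(x) - 2 T2(y)
  }
  st <- scatter_stations(30, seed = 32, fun = gen)
  surf <- fit_surface(st, 3, 3, domain = dom)
  expected <- matrix(0, 4, 4)
  expected[2, 1] <- 3   # a_10
  expected[1, 3] <- -2  # a_02
  expect_equal(surf$coeffs, expected, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("Chebyshev fit equals brute-force monomial OLS on the same space", {
  dom <- test_domain()
  set.seed(33)
  for (rep in 1:10) {
    st <- scatter_stations(20, seed = 330 + rep,
                           fun = function(lon, lat) 60 + lon - lat,
                           noise_sd = 5)
    surf <- fit_surface(st, 2, 2, domain = dom)
    # independent oracle: plain OLS on the monomial tensor basis x^i y^j
    r <- ref_xy(st$lons, st$lats, dom)
    M <- do.call(cbind, lapply(0:2, function(j) {
      sapply(0:2, function(i) r$x^i * r$y^j)
    }))
    oracle_fit <- stats::lm.fit(M, st$values)$fitted.values
    expect_equal(unname(surf$fitted), unname(oracle_fit), tolerance = 1e-8)
  }
})

test_that("fit requires at least (s+1)(k+1) stations and reports the minimum", {
  st <- scatter_stations(30, seed = 34)
  expect_error(fit_surface(st, 9, 9), "underdetermined.*100")
  expect_error(fit_surface(st, 11, 2, max_order = 10), "policy cap")
})

test_that("station order does not affect the fitted surface", {
  dom <- test_domain()
  st <- scatter_stations(60, seed = 35,
                         fun = function(lon, lat) 50 + lon * 0.5, noise_sd = 3)
  perm <- with(list(), {set.seed(36); sample(st$n)})
  stp <- station_set(st$ids[perm], st$lons[perm], st$lats[perm],
                     st$values[perm])
  pts <- grid_points(grid_spec(dom, 2, 2))
  a <- evaluate_surface(fit_surface(st, 4, 4, domain = dom), pts$lon, pts$lat)
  b <- evaluate_surface(fit_surface(stp, 4, 4, domain = dom), pts$lon, pts$lat)
  expect_lt(max(abs(a - b)), 1e-10)
})

test_that("surface evaluation honors closed-form identities", {
  dom <- test_domain()
  surf <- structure(
    list(s = 2L, k = 2L, domain = dom,
         coeffs = matrix(c(7, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3)),
    class = "chebyshev_surface")
  expect_equal(evaluate_surface(surf, c(101, 110, 119), c(21, 28, 35)),
               rep(7, 3))
  # at the (lon_max, lat_max) corner every T_i T_j equals 1
  set.seed(37)
  surf$coeffs <- matrix(stats::rnorm(9), 3, 3)
  expect_equal(evaluate_surface(surf, dom$lon_max, dom$lat_max),
               sum(surf$coeffs), tolerance = 1e-12)
  # clip-at-zero is presentation-only flooring
  surf$coeffs <- matrix(c(-5, rep(0, 8)), 3, 3)
  expect_equal(evaluate_surface(surf, 110, 28), -5)
  expect_equal(evaluate_surface(surf, 110, 28, clip_zero = TRUE), 0)
})

test_that("tensor polynomials within the fitted orders are reproduced on a grid", {
  dom <- test_domain()
  gen <- function(lon, lat) {
    r <- ref_xy(lon, lat, dom)
    10 + 4 * r$x - 3 * r$y + 2 * r$x^2 * r$y^2 - r$x * r$y
  }
  st <- scatter_stations(60, seed = 38, fun = gen)
  surf <- fit_surface(st, 2, 2, domain = dom)
  pts <- grid_points(grid_spec(dom, 0.4, 0.4))
  est <- evaluate_surface(surf, pts$lon, pts$lat)
  expect_lt(max(abs(est - gen(pts$lon, pts$lat))), 1e-6)
  # evaluation at the fitting stations reproduces the fitted values
  expect_equal(evaluate_surface(surf, st$lons, st$lats), surf$fitted,
               tolerance = 1e-10)
})

test_that("surface JSON serialization round-trips losslessly", {
  dom <- test_domain()
  st <- scatter_stations(50, seed = 39,
                         fun = function(lon, lat) 60 + lon - 2 * lat,
                         noise_sd = 4)
  surf <- fit_surface(st, 3, 2, domain = dom)
  path <- withr::local_tempfile(fileext = ".json")
  write_surface_json(surf, path)
  back <- read_surface_json(path)
  expect_identical(back$s, surf$s)
  expect_identical(back$k, surf$k)
  expect_equal(back$coeffs, surf$coeffs, tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(unclass(back$domain), unclass(surf$domain))
  # degenerate shapes survive the round trip too
  for (ord in list(c(0, 0), c(0, 2), c(2, 0))) {
    s2 <- fit_surface(st, ord[1], ord[2], domain = dom)
    write_surface_json(s2, path)
    expect_equal(read_surface_json(path)$coeffs, s2$coeffs,
                 tolerance = 1e-15, ignore_attr = TRUE)
  }
})

test_that("rank-deficient designs fall back to the minimum-norm solution", {
  # all stations on a vertical line: latitude basis is degenerate
  st <- station_set(1:12, rep(110, 12) + seq(0, 1.1, by = 0.1), rep(28, 12),
                    seq(40, 51))
  dom <- test_domain()
  expect_warning(surf <- fit_surface(st, 1, 1, domain = dom),
                 "rank-deficient")
  expect_true(all(is.finite(surf$coeffs)))
})
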