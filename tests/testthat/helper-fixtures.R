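# Fixtures built in code; no data files.

test_domain <- function() domain_box(100, 120, 20, 36)

# n stations scattered over the test domain, values from `fun(lon, lat)`.
scatter_stations <- function(n, seed, fun = function(lon, lat) 0 * lon,
                             domain = test_domain(), noise_sd = 0) {
  with_seed <- getFromNamespace("with_seed", "opfit")
  with_seed(seed, {
    lons <- stats::runif(n, domain$lon_min, domain$lon_max)
    lats <- stats::runif(n, domain$lat_min, domain$lat_max)
    v <- fun(lons, lats)
    if (noise_sd > 0) v <- v + stats::rnorm(n, sd = noise_sd)
    station_set(seq_len(n), lons, lats, v)
  })
}

# Reference coordinates of points within a domain (for building oracles).
ref_xy <- function(lons, lats, domain) {
  list(x = map_to_reference(lons, domain$lon_min, domain$lon_max),
       y = map_to_reference(lats, domain$lat_min, domain$lat_max))
}
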