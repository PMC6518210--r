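#' Read scattered station observations from CSV
#'
#' Expects a header with columns `id`, `lon`, `lat`, `value` in any order
#' and any letter case. Rows whose value is missing or non-numeric are
#' dropped with a message counting them; duplicate coordinate pairs are an
#' error (they would make the kriging system singular and indicate a data
#' problem upstream).
#'
#' @param path Path to a CSV file.
#' @return A [station_set()].
#' @export
read_stations_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  req <- c("id", "lon", "lat", "value")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(df$value))
  lons <- suppressWarnings(as.numeric(df$lon))
  lats <- suppressWarnings(as.numeric(df$lat))
  ok <- is.finite(vals) & is.finite(lons) & is.finite(lats)
  if (sum(!ok) > 0) {
    message(sum(!ok), " row(s) with missing/non-numeric fields dropped")
  }
  if (!any(ok)) stop("empty input: no usable rows in ", path, call. = FALSE)
  station_set(df$id[ok], lons[ok], lats[ok], vals[ok])
}

#' Write a station set to CSV
#'
#' Columns `id,lon,lat,value`; round-trips through
#' [read_stations_csv()].
#'
#' @param stations A [station_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stations_csv <- function(stations, path) {
  stopifnot(inherits(stations, "station_set"))
  utils::write.csv(as.data.frame(stations), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Regular evaluation grid over a domain
#'
#' @param domain A [domain_box()].
#' @param d_lon,d_lat Grid spacing in degrees (default 0.25); each axis
#'   must yield at least 2 nodes.
#' @return An object of class `grid_spec` with node vectors `lons`,
#'   `lats` and counts `n_lon`, `n_lat`.
#' @export
grid_spec <- function(domain, d_lon = 0.25, d_lat = 0.25) {
  stopifnot(inherits(domain, "domain_box"))
  stopifnot_scalar_number(d_lon, "d_lon")
  stopifnot_scalar_number(d_lat, "d_lat")
  if (d_lon <= 0 || d_lat <= 0) {
    stop("grid spacings must be > 0", call. = FALSE)
  }
  lons <- seq(domain$lon_min, domain$lon_max, by = d_lon)
  lats <- seq(domain$lat_min, domain$lat_max, by = d_lat)
  if (length(lons) < 2L || length(lats) < 2L) {
    stop("grid must have at least 2 nodes per axis", call. = FALSE)
  }
  structure(list(domain = domain, d_lon = d_lon, d_lat = d_lat,
                 lons = lons, lats = lats,
                 n_lon = length(lons), n_lat = length(lats)),
            class = "grid_spec")
}

#' Long-format node coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @return Data frame with columns `lon`, `lat`; longitude varies fastest.
#' @export
grid_points <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  expand.grid(lon = spec$lons, lat = spec$lats, KEEP.OUT.ATTRS = FALSE)
}

#' Write gridded values as long-format CSV
#'
#' One row per node, columns `lon,lat,value`, longitude varying fastest.
#' `NA` values are written as empty fields and read back as missing.
#'
#' @param values Numeric vector, one value per node of `spec` (in
#'   [grid_points()] order).
#' @param spec A [grid_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(values, spec, path) {
  stopifnot(inherits(spec, "grid_spec"))
  pts <- grid_points(spec)
  if (length(values) != nrow(pts)) {
    stop(sprintf("shape mismatch: %d values for %d grid nodes",
                 length(values), nrow(pts)), call. = FALSE)
  }
  utils::write.csv(cbind(pts, value = values), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_grid_csv
#' @return `read_grid_csv()` returns a data frame `lon, lat, value`.
#' @export
read_grid_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("lon", "lat", "value")
  if (!all(req %in% names(df))) {
    stop("schema error: grid CSV needs columns lon, lat, value",
         call. = FALSE)
  }
  df[req]
}
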