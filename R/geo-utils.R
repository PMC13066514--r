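#' @keywords internal
"_PACKAGE"

# Mean-Earth-radius degree length (2*pi*6371.0088/360 km). All km <-> degree
# conversions use a local equirectangular scaling: 1 deg lon = KM_PER_DEG *
# cos(lat) km, 1 deg lat = KM_PER_DEG km.
KM_PER_DEG <- 111.19508

deg2rad <- function(x) x * pi / 180

#' Local equirectangular projection of lon/lat to km offsets
#'
#' Projects coordinates onto a plane tangent at a reference point, with the
#' east-west scale fixed by the reference latitude. Adequate for the
#' site-box (3 km) and inter-site (tens to hundreds of km) scales used here.
#'
#' @param lon,lat coordinates in decimal degrees (WGS84).
#' @param lon0,lat0 reference point of the projection.
#' @return list with `x` and `y` offsets in km (east and north positive).
#' @export
lonlat_to_km <- function(lon, lat, lon0, lat0) {
  list(
    x = (lon - lon0) * KM_PER_DEG * cos(deg2rad(lat0)),
    y = (lat - lat0) * KM_PER_DEG
  )
}

#' Inverse of [lonlat_to_km()]
#' @param x,y offsets in km east/north of the reference point.
#' @param lon0,lat0 reference point of the projection.
#' @return list with `lon` and `lat` in decimal degrees.
#' @export
km_to_lonlat <- function(x, y, lon0, lat0) {
  list(
    lon = lon0 + x / (KM_PER_DEG * cos(deg2rad(lat0))),
    lat = lat0 + y / KM_PER_DEG
  )
}

# polyline arc length (km) through lon/lat waypoints, and cumulative lengths
polyline_lengths <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(list(seg = numeric(0), cum = 0, total = 0))
  seg <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    latm <- (lat[i] + lat[i + 1]) / 2
    dx <- (lon[i + 1] - lon[i]) * KM_PER_DEG * cos(deg2rad(latm))
    dy <- (lat[i + 1] - lat[i]) * KM_PER_DEG
    seg[i] <- sqrt(dx^2 + dy^2)
  }
  list(seg = seg, cum = c(0, cumsum(seg)), total = sum(seg))
}

# point at arc-length s along a lon/lat polyline (s in km, clamped to ends)
polyline_point <- function(lon, lat, s) {
  pl <- polyline_lengths(lon, lat)
  s <- pmin(pmax(s, 0), pl$total)
  out_lon <- numeric(length(s)); out_lat <- numeric(length(s))
  for (k in seq_along(s)) {
    i <- findInterval(s[k], pl$cum, rightmost.closed = TRUE)
    i <- min(max(i, 1), length(pl$seg))
    f <- if (pl$seg[i] > 0) (s[k] - pl$cum[i]) / pl$seg[i] else 0
    out_lon[k] <- lon[i] + f * (lon[i + 1] - lon[i])
    out_lat[k] <- lat[i] + f * (lat[i + 1] - lat[i])
  }
  list(lon = out_lon, lat = out_lat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
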