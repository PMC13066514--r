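# Analytic velocity fields and hand-built ensembles used across tests.

t_origin <- as.POSIXct("2020-06-01 00:00:00", tz = "Asia/Tokyo")

# field from u(lon,lat), v(lon,lat) functions, constant in time
make_field <- function(fu, fv, lon = seq(120, 130, 0.5),
                       lat = seq(-3, 3, 0.5),
                       times = t_origin + c(0, 40 * 86400)) {
  g <- expand.grid(lon = lon, lat = lat)
  nt <- length(times)
  u1 <- matrix(fu(g$lon, g$lat), length(lon), length(lat))
  v1 <- matrix(fv(g$lon, g$lat), length(lon), length(lat))
  velocity_field(lon, lat, times,
                 array(rep(u1, nt), c(dim(u1), nt)),
                 array(rep(v1, nt), c(dim(v1), nt)))
}

uniform_field <- function(u0 = 0.1, v0 = 0, ...)
  make_field(function(x, y) u0 + 0 * x, function(x, y) v0 + 0 * x, ...)

# solid-body rotation (m/s) about (lon0, lat0) with angular velocity omega
# (rad/s), defined on km offsets; near the equator the lon/lat metric is
# uniform so the analytic orbit is circular
rotation_field <- function(omega, lon0 = 125, lat0 = 0,
                           lon = seq(123, 127, 0.1), lat = seq(-2, 2, 0.1)) {
  make_field(
    function(x, y) -omega * (y - lat0) * 111195.08,
    function(x, y) omega * (x - lon0) * 111195.08 * cos(lat0 * pi / 180),
    lon = lon, lat = lat
  )
}

one_site_layout <- function(lon = 125, lat = 0, hw = 1e-9)
  habitat_layout(data.frame(site = "A", lon = lon, lat = lat, group = "g"),
                 box_halfwidth_km = hw)

single_release <- function(site = "A", time = t_origin, count = 1L) {
  structure(data.frame(site = site, time = time, count = as.integer(count),
                       stringsAsFactors = FALSE),
            class = c("release_schedule", "data.frame"))
}

# hand-built ensemble from explicit trajectories
make_ensemble <- function(lon, lat, age_days, source,
                          release_time = rep(t_origin, nrow(lon)),
                          exited = rep(FALSE, nrow(lon))) {
  structure(list(lon = lon, lat = lat, age_days = age_days,
                 source = source, release_time = release_time,
                 exited = exited,
                 exit_time = rep(as.POSIXct(NA), nrow(lon)),
                 params = integration_params(max_age_days = max(age_days) + 1),
                 domain = list(lon = range(lon, na.rm = TRUE) + c(-1, 1),
                               lat = range(lat, na.rm = TRUE) + c(-1, 1))),
            class = "particle_ensemble")
}
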