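# Gridded surface velocity fields and the idealized boundary-jet generator.

#' Construct a gridded velocity field
#'
#' Container for time-varying 2D surface currents on a regular lon/lat grid.
#' Velocities are in m/s; land cells carry NA and are treated as zero
#' velocity during interpolation (larvae stall rather than beach).
#'
#' @param lon,lat strictly increasing grid coordinate vectors (degrees).
#' @param time POSIXct vector of time slices, strictly increasing.
#' @param u,v numeric arrays of dim `c(length(lon), length(lat), length(time))`.
#' @param land optional logical matrix `length(lon) x length(lat)`; TRUE = land.
#' @return object of class `velocity_field`.
#' @export
velocity_field <- function(lon, lat, time, u, v, land = NULL) {
  stopifnot(is.numeric(lon), is.numeric(lat), inherits(time, "POSIXct"))
  dm <- c(length(lon), length(lat), length(time))
  if (!identical(dim(u), as.integer(dm)) || !identical(dim(v), as.integer(dm)))
    stop("u and v must have dim (nlon, nlat, ntime)")
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0))
    stop("lon and lat must be strictly increasing")
  if (length(time) > 1 && any(diff(as.numeric(time)) <= 0))
    stop("time must be strictly increasing")
  if (!is.null(land)) {
    stopifnot(identical(dim(land), as.integer(dm[1:2])))
    u[array(land, dm)] <- NA_real_
    v[array(land, dm)] <- NA_real_
  }
  structure(
    list(lon = lon, lat = lat, time = time, u = u, v = v,
         land = land %||% matrix(FALSE, dm[1], dm[2])),
    class = "velocity_field"
  )
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf(
    "velocity_field: %d x %d grid, %d time slice(s)\n  lon [%g, %g], lat [%g, %g]\n  %s .. %s\n",
    length(x$lon), length(x$lat), length(x$time),
    min(x$lon), max(x$lon), min(x$lat), max(x$lat),
    format(min(x$time)), format(max(x$time))))
  invisible(x)
}

#' Configuration for the synthetic boundary-jet field
#'
#' Describes an idealized western-boundary current: a jet with Gaussian
#' cross-section following a waypoint centerline, an opposing counter-current
#' band offset to the jet's left, a time-periodic eddy perturbation, and
#' seeded Gaussian noise. This is the synthetic stand-in for an operational
#' ocean-model product and only aims at the qualitative circulation features
#' (a fast along-arc core, localized recirculation, weak variability).
#'
#' @param lon_range,lat_range domain bounds (degrees).
#' @param spacing grid spacing (degrees), > 0.
#' @param origin POSIXct start of the field's time axis.
#' @param span_days,step_hours temporal extent and resolution.
#' @param jet_lon,jet_lat centerline waypoints (degrees).
#' @param jet_peak peak jet speed (m/s), >= 0.
#' @param jet_width Gaussian cross-section e-folding width parameter (km), > 0.
#' @param counter_speed counter-current peak speed (m/s); 0 disables it.
#' @param counter_offset_km,counter_width_km location (signed, positive =
#'   left of the jet) and width of the counter-current band (km).
#' @param eddy_amp,eddy_period_days amplitude (m/s) and period of the
#'   propagating eddy perturbation; 0 amplitude disables it.
#' @param noise_sd standard deviation of per-cell, per-slice velocity noise (m/s).
#' @param land optional logical land matrix (see [velocity_field()]).
#' @param seed integer seed; identical seed + config gives a bit-identical field.
#' @return list of class `field_config`.
#' @export
field_config <- function(lon_range = c(122, 132), lat_range = c(23, 31),
                         spacing = 0.1,
                         origin = as.POSIXct("2019-05-01 00:00:00", tz = "Asia/Tokyo"),
                         span_days = 40, step_hours = 3,
                         jet_lon = c(122.5, 125, 128, 130.5, 131.5),
                         jet_lat = c(23.8, 25.2, 27.3, 29.3, 30.5),
                         jet_peak = 1.2, jet_width = 80,
                         counter_speed = 0.15,
                         counter_offset_km = 1.5 * jet_width,
                         counter_width_km = jet_width / 2,
                         eddy_amp = 0.05, eddy_period_days = 20,
                         noise_sd = 0.01, land = NULL, seed = 1L) {
  stopifnot(spacing > 0, jet_width > 0, jet_peak >= 0, noise_sd >= 0,
            length(jet_lon) == length(jet_lat), length(jet_lon) >= 2)
  structure(as.list(environment()), class = "field_config")
}

# perpendicular distance (km), unit tangent, and signed side of the nearest
# centerline segment, for vectors of query points
.centerline_geometry <- function(qlon, qlat, cl_lon, cl_lat) {
  lat0 <- mean(cl_lat); lon0 <- mean(cl_lon)
  q <- lonlat_to_km(qlon, qlat, lon0, lat0)
  w <- lonlat_to_km(cl_lon, cl_lat, lon0, lat0)
  n <- length(qlon)
  best_d2 <- rep(Inf, n); tx <- numeric(n); ty <- numeric(n)
  side <- numeric(n); along <- numeric(n)
  cum <- c(0, cumsum(sqrt(diff(w$x)^2 + diff(w$y)^2)))
  for (i in seq_len(length(cl_lon) - 1)) {
    ax <- w$x[i]; ay <- w$y[i]
    bx <- w$x[i + 1]; by <- w$y[i + 1]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    tpar <- if (L2 > 0) pmin(pmax(((q$x - ax) * vx + (q$y - ay) * vy) / L2, 0), 1) else 0
    px <- ax + tpar * vx; py <- ay + tpar * vy
    d2 <- (q$x - px)^2 + (q$y - py)^2
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      L <- sqrt(L2)
      tx[upd] <- vx / L; ty[upd] <- vy / L
      # positive side = left of the tangent direction
      side[upd] <- sign(vx * (q$y[upd] - ay) - vy * (q$x[upd] - ax))
      along[upd] <- cum[i] + tpar[upd] * sqrt(L2)
    }
  }
  list(dist = sqrt(best_d2), tx = tx, ty = ty, side = side, along = along)
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate an idealized boundary-jet velocity field
#'
#' Builds the synthetic current field described by a [field_config()]:
#' at every grid point the velocity is the sum of (i) a jet directed along
#' the centerline with Gaussian decay `exp(-d^2 / (2 w^2))` in perpendicular
#' distance d, (ii) an opposing counter-current band offset to the jet's
#' left, (iii) a time-periodic propagating eddy perturbation, and (iv)
#' seeded white noise. Deterministic per seed.
#'
#' @param config a [field_config()].
#' @return a [velocity_field()].
#' @export
generate_jet_field <- function(config) {
  stopifnot(inherits(config, "field_config"))
  cf <- config
  if (any(cf$jet_lon < cf$lon_range[1]) || any(cf$jet_lon > cf$lon_range[2]) ||
      any(cf$jet_lat < cf$lat_range[1]) || any(cf$jet_lat > cf$lat_range[2]))
    stop("invalid config: jet centerline extends outside the domain")
  lon <- seq(cf$lon_range[1], cf$lon_range[2], by = cf$spacing)
  lat <- seq(cf$lat_range[1], cf$lat_range[2], by = cf$spacing)
  time <- cf$origin + 3600 * seq(0, cf$span_days * 24, by = cf$step_hours)
  nlon <- length(lon); nlat <- length(lat); nt <- length(time)

  grid <- expand.grid(lon = lon, lat = lat)
  geom <- .centerline_geometry(grid$lon, grid$lat, cf$jet_lon, cf$jet_lat)

  jet_speed <- cf$jet_peak * exp(-geom$dist^2 / (2 * cf$jet_width^2))
  u0 <- jet_speed * geom$tx
  v0 <- jet_speed * geom$ty
  if (cf$counter_speed > 0) {
    sdist <- geom$side * geom$dist
    cc <- cf$counter_speed *
      exp(-(sdist - cf$counter_offset_km)^2 / (2 * cf$counter_width_km^2))
    u0 <- u0 - cc * geom$tx
    v0 <- v0 - cc * geom$ty
  }
  u0 <- matrix(u0, nlon, nlat)
  v0 <- matrix(v0, nlon, nlat)

  u <- array(0, c(nlon, nlat, nt))
  v <- array(0, c(nlon, nlat, nt))
  tsec <- as.numeric(time) - as.numeric(time[1])
  phase_lon <- matrix(2 * pi * grid$lon / 2, nlon, nlat)  # 2-degree wavelength
  phase_lat <- matrix(2 * pi * grid$lat / 2, nlon, nlat)
  for (k in seq_len(nt)) {
    uk <- u0; vk <- v0
    if (cf$eddy_amp > 0) {
      ph <- 2 * pi * tsec[k] / (cf$eddy_period_days * 86400)
      uk <- uk + cf$eddy_amp * sin(ph + phase_lat)
      vk <- vk + cf$eddy_amp * cos(ph + phase_lon)
    }
    u[, , k] <- uk
    v[, , k] <- vk
  }
  if (cf$noise_sd > 0) {
    with_seed(cf$seed, {
      u <- u + array(stats::rnorm(length(u), 0, cf$noise_sd), dim(u))
      v <- v + array(stats::rnorm(length(v), 0, cf$noise_sd), dim(v))
    })
  }
  velocity_field(lon, lat, time, u, v, land = cf$land)
}

#' Temporal-mean current speed over selected calendar months
#'
#' Averages the instantaneous speed `sqrt(u^2 + v^2)` (not the speed of the
#' mean velocity) over all time slices whose calendar month is in `months`.
#'
#' @param field a [velocity_field()].
#' @param months integer months (1-12) to include; default May-August.
#' @param of either `"speed"` (default; mean of instantaneous speed) or
#'   `"velocity"` (speed of the time-mean velocity vector).
#' @return list with `lon`, `lat` and matrix `speed` (m/s), class `mean_speed_grid`.
#' @export
mean_field <- function(field, months = 5:8, of = c("speed", "velocity")) {
  of <- match.arg(of)
  stopifnot(inherits(field, "velocity_field"))
  mo <- as.integer(format(field$time, "%m"))
  keep <- which(mo %in% months)
  if (length(keep) == 0) stop("no time slices fall in the requested months")
  if (of == "speed") {
    sp <- sqrt(field$u[, , keep, drop = FALSE]^2 + field$v[, , keep, drop = FALSE]^2)
    m <- apply(sp, c(1, 2), mean)
  } else {
    mu <- apply(field$u[, , keep, drop = FALSE], c(1, 2), mean)
    mv <- apply(field$v[, , keep, drop = FALSE], c(1, 2), mean)
    m <- sqrt(mu^2 + mv^2)
  }
  structure(list(lon = field$lon, lat = field$lat, speed = m, months = months),
            class = "mean_speed_grid")
}

#' Fast-current region mask
#'
#' Boolean grid marking cells whose temporal-mean speed over the stated
#' months exceeds a threshold; used to ask what fraction of a site's
#' particles ever enter the strong-current region.
#'
#' @param mean_speed a `mean_speed_grid` from [mean_field()], or a
#'   [velocity_field()] (then [mean_field()] is applied first).
#' @param threshold speed threshold in m/s (default 0.4).
#' @param months months passed through when a raw field is given.
#' @return list with `lon`, `lat`, logical matrix `mask`, `threshold`, `months`;
#'   class `current_region_mask`.
#' @export
current_region_mask <- function(mean_speed, threshold = 0.4, months = 5:8) {
  if (inherits(mean_speed, "velocity_field"))
    mean_speed <- mean_field(mean_speed, months = months)
  stopifnot(inherits(mean_speed, "mean_speed_grid"))
  structure(
    list(lon = mean_speed$lon, lat = mean_speed$lat,
         mask = mean_speed$speed > threshold,
         threshold = threshold, months = mean_speed$months),
    class = "current_region_mask"
  )
}

#' Write / read a velocity field as long-format CSV
#'
#' Plain-text serialization (columns time, lon, lat, u, v); times ISO-8601
#' in the field's timezone. Intended for the small synthetic fields this
#' package generates, not operational model output.
#'
#' @param field a [velocity_field()].
#' @param path file path.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "velocity_field"))
  tz <- attr(field$time, "tzone") %||% "UTC"
  df <- expand.grid(lon = field$lon, lat = field$lat,
                    time = format(field$time, "%Y-%m-%dT%H:%M:%S", tz = tz),
                    stringsAsFactors = FALSE)
  df$u <- as.vector(field$u)
  df$v <- as.vector(field$v)
  df$tz <- tz
  utils::write.csv(df[, c("time", "tz", "lon", "lat", "u", "v")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tz <- df$tz[1]
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  tstr <- unique(df$time)
  time <- as.POSIXct(tstr, format = "%Y-%m-%dT%H:%M:%S", tz = tz)
  ord <- order(match(df$time, tstr), match(df$lat, lat), match(df$lon, lon))
  dm <- c(length(lon), length(lat), length(time))
  velocity_field(lon, lat, time[order(time)],
                 array(df$u[ord], dm)[, , order(time), drop = FALSE],
                 array(df$v[ord], dm)[, , order(time), drop = FALSE])
}
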