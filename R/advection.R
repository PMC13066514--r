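# Passive Lagrangian advection: bilinear/linear interpolation + fixed-step RK4.

#' Integration parameters for particle tracking
#'
#' @param dt_minutes RK4 timestep in minutes (default 30).
#' @param output_interval_hours trajectory sampling interval (default 1);
#'   must be a multiple of the timestep.
#' @param max_age_days maximum tracked age = longest pelagic larval
#'   duration of interest (default 30).
#' @param domain list with `lon` and `lat` 2-vectors; particles leaving it
#'   are terminated. Defaults to the field extent at advection time.
#' @return list of class `integration_params`.
#' @export
integration_params <- function(dt_minutes = 30, output_interval_hours = 1,
                               max_age_days = 30, domain = NULL) {
  stopifnot(dt_minutes > 0, max_age_days > 0,
            output_interval_hours * 60 >= dt_minutes)
  if (abs(output_interval_hours * 60 / dt_minutes -
          round(output_interval_hours * 60 / dt_minutes)) > 1e-9)
    stop("output interval must be a multiple of the timestep")
  structure(list(dt_minutes = dt_minutes,
                 output_interval_hours = output_interval_hours,
                 max_age_days = max_age_days, domain = domain),
            class = "integration_params")
}

#' Interpolate the velocity field at arbitrary points and time
#'
#' Bilinear interpolation in space, linear in time. Land (NA) neighbours
#' contribute zero velocity, so particles stall near coasts instead of
#' acquiring spurious velocities.
#'
#' @param field a [velocity_field()].
#' @param lon,lat query positions (vectors, degrees).
#' @param time single POSIXct (or numeric seconds since epoch) query time.
#' @return list with numeric vectors `u` and `v` (m/s); NA for queries
#'   outside the field's spatial coverage.
#' @export
interpolate_velocity <- function(field, lon, lat, time) {
  tq <- as.numeric(time)
  tf <- as.numeric(field$time)
  if (tq < tf[1] - 1e-6 || tq > tf[length(tf)] + 1e-6)
    stop("query time outside field coverage")
  if (length(tf) == 1) {
    k <- 1; wt <- 0
  } else {
    k <- findInterval(tq, tf, rightmost.closed = TRUE)
    k <- min(max(k, 1), length(tf) - 1)
    wt <- (tq - tf[k]) / (tf[k + 1] - tf[k])
  }
  u1 <- .bilinear(field, field$u[, , k], lon, lat)
  v1 <- .bilinear(field, field$v[, , k], lon, lat)
  if (wt > 0) {
    u2 <- .bilinear(field, field$u[, , k + 1], lon, lat)
    v2 <- .bilinear(field, field$v[, , k + 1], lon, lat)
    u1 <- (1 - wt) * u1 + wt * u2
    v1 <- (1 - wt) * v1 + wt * v2
  }
  list(u = u1, v = v1)
}

# vectorized bilinear interpolation of one slice; NA (land) neighbours -> 0;
# out-of-grid queries -> NA
.bilinear <- function(field, slice, lon, lat) {
  gx <- field$lon; gy <- field$lat
  nx <- length(gx); ny <- length(gy)
  i <- findInterval(lon, gx, rightmost.closed = TRUE)
  j <- findInterval(lat, gy, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(lon))
  ok <- i >= 1 & i <= nx - 1 & j >= 1 & j <= ny - 1 &
    lon >= gx[1] & lon <= gx[nx] & lat >= gy[1] & lat <= gy[ny]
  # degenerate single-row/col grids: clamp
  if (nx == 1 || ny == 1) {
    ok <- lon >= gx[1] & lon <= gx[nx] & lat >= gy[1] & lat <= gy[ny]
    i <- pmin(pmax(i, 1), max(nx - 1, 1))
    j <- pmin(pmax(j, 1), max(ny - 1, 1))
  }
  if (!any(ok)) return(out)
  io <- i[ok]; jo <- j[ok]
  i2 <- pmin(io + 1, nx); j2 <- pmin(jo + 1, ny)
  fx <- if (nx > 1) (lon[ok] - gx[io]) / (gx[io + 1] - gx[io]) else 0
  fy <- if (ny > 1) (lat[ok] - gy[jo]) / (gy[jo + 1] - gy[jo]) else 0
  z00 <- slice[cbind(io, jo)]; z10 <- slice[cbind(i2, jo)]
  z01 <- slice[cbind(io, j2)]; z11 <- slice[cbind(i2, j2)]
  z00[is.na(z00)] <- 0; z10[is.na(z10)] <- 0
  z01[is.na(z01)] <- 0; z11[is.na(z11)] <- 0
  out[ok] <- z00 * (1 - fx) * (1 - fy) + z10 * fx * (1 - fy) +
    z01 * (1 - fx) * fy + z11 * fx * fy
  out
}

# velocity (m/s) -> position tendency (deg/s) at the particles' latitudes
.tendency <- function(field, lon, lat, tsec) {
  vel <- interpolate_velocity(field, lon, lat, tsec)
  u <- vel$u; v <- vel$v
  u[is.na(u)] <- 0; v[is.na(v)] <- 0
  m_per_deg <- KM_PER_DEG * 1000
  list(dlon = u / (m_per_deg * cos(deg2rad(lat))), dlat = v / m_per_deg)
}

#' Advect scheduled particles through a velocity field
#'
#' Each release event places its particles uniformly at random (seeded)
#' inside the source site's square box, then integrates them as passive
#' tracers with fixed-step 4th-order Runge-Kutta until the maximum age is
#' reached or the particle exits the domain. Positions are recorded on a
#' fixed age grid (multiples of the output interval). The seed affects only
#' initial placement; the integration itself is deterministic.
#'
#' @param field a [velocity_field()].
#' @param schedule a `release_schedule` (see [build_release_schedule()]).
#' @param layout the [habitat_layout()] providing source-box centres.
#' @param params an [integration_params()].
#' @param seed integer seed for initial placement.
#' @return object of class `particle_ensemble`: list with matrices `lon`,
#'   `lat` (particles x samples; NA after exit), vector `age_days` (one per
#'   sample column), `source` (site id per particle), `release_time`,
#'   `exited` (logical), `exit_time` (POSIXct, NA if never exited), and the
#'   params used.
#' @export
advect <- function(field, schedule, layout, params = integration_params(),
                   seed = 1L) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(layout, "habitat_layout"),
            inherits(params, "integration_params"))
  if (nrow(schedule) == 0) stop("empty release schedule")
  dom <- params$domain %||% list(lon = range(field$lon), lat = range(field$lat))
  dt <- params$dt_minutes * 60
  out_int <- params$output_interval_hours * 3600
  steps_per_out <- round(out_int / dt)
  n_out <- floor(params$max_age_days * 86400 / out_int)
  age_days <- (0:n_out) * out_int / 86400

  tf <- range(as.numeric(field$time))
  tmax_needed <- max(as.numeric(schedule$time)) + params$max_age_days * 86400
  if (min(as.numeric(schedule$time)) < tf[1] || tmax_needed > tf[2] + 1e-6)
    stop(sprintf(
      "field temporal coverage ends %.2f days before release + max age",
      (tmax_needed - tf[2]) / 86400))

  n_total <- sum(schedule$count)
  LON <- matrix(NA_real_, n_total, n_out + 1)
  LAT <- matrix(NA_real_, n_total, n_out + 1)
  src <- character(n_total)
  rel <- rep(schedule$time[1], n_total)
  exited <- logical(n_total)
  exit_t <- rep(as.POSIXct(NA), n_total)

  site_idx <- match(schedule$site, layout$sites$site)
  if (anyNA(site_idx)) stop("schedule references unknown site ids")
  hw <- layout$box_halfwidth_km

  # initial placement for all particles, one seeded draw
  offs <- with_seed(seed, matrix(stats::runif(2 * n_total, -hw, hw), ncol = 2))
  row0 <- cumsum(c(0, schedule$count))
  for (e in seq_len(nrow(schedule))) {
    idx <- (row0[e] + 1):row0[e + 1]
    s <- layout$sites[site_idx[e], ]
    p0 <- km_to_lonlat(offs[idx, 1], offs[idx, 2], s$lon, s$lat)
    LON[idx, 1] <- p0$lon
    LAT[idx, 1] <- p0$lat
    src[idx] <- s$site
    rel[idx] <- schedule$time[e]
  }

  inside <- function(lon, lat)
    lon >= dom$lon[1] & lon <= dom$lon[2] & lat >= dom$lat[1] & lat <= dom$lat[2]

  for (t0 in unique(as.numeric(schedule$time))) {
    cohort <- which(as.numeric(rel) == t0)
    active <- cohort[inside(LON[cohort, 1], LAT[cohort, 1])]
    gone <- setdiff(cohort, active)
    if (length(gone)) {
      exited[gone] <- TRUE
      exit_t[gone] <- as.POSIXct(t0, origin = "1970-01-01",
                                 tz = attr(field$time, "tzone") %||% "UTC")
    }
    lon <- LON[active, 1]; lat <- LAT[active, 1]
    tcur <- t0
    for (ob in seq_len(n_out)) {
      if (length(active) == 0) break
      for (s in seq_len(steps_per_out)) {
        k1 <- .tendency(field, lon, lat, tcur)
        k2 <- .tendency(field, lon + dt / 2 * k1$dlon, lat + dt / 2 * k1$dlat, tcur + dt / 2)
        k3 <- .tendency(field, lon + dt / 2 * k2$dlon, lat + dt / 2 * k2$dlat, tcur + dt / 2)
        k4 <- .tendency(field, lon + dt * k3$dlon, lat + dt * k3$dlat, tcur + dt)
        lon <- lon + dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
        lat <- lat + dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
        tcur <- tcur + dt
        out_now <- !inside(lon, lat)
        if (any(out_now)) {
          gone <- active[out_now]
          exited[gone] <- TRUE
          exit_t[gone] <- as.POSIXct(tcur, origin = "1970-01-01",
                                     tz = attr(field$time, "tzone") %||% "UTC")
          active <- active[!out_now]
          lon <- lon[!out_now]; lat <- lat[!out_now]
        }
      }
      if (length(active)) {
        LON[active, ob + 1] <- lon
        LAT[active, ob + 1] <- lat
      }
      tcur <- t0 + ob * out_int  # re-anchor to avoid drift in t accumulation
    }
  }

  structure(list(lon = LON, lat = LAT, age_days = age_days,
                 source = src, release_time = rel,
                 exited = exited, exit_time = exit_t,
                 params = params, domain = dom),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf(
    "particle_ensemble: %d particles from %d site(s), %d samples (0..%g d), %d exited\n",
    nrow(x$lon), length(unique(x$source)), length(x$age_days),
    max(x$age_days), sum(x$exited)))
  invisible(x)
}

#' Number of particles per source site in an ensemble
#' @param ensemble a `particle_ensemble`.
#' @export
particles_per_source <- function(ensemble) {
  tab <- table(ensemble$source)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write / read a particle ensemble as long-format CSV
#'
#' One row per recorded sample (exited samples dropped); release metadata
#' repeated per row. Times ISO-8601.
#' @param ensemble a `particle_ensemble`.
#' @param path file path.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  n <- nrow(ensemble$lon); m <- ncol(ensemble$lon)
  tz <- attr(ensemble$release_time, "tzone") %||% "UTC"
  keep <- !is.na(ensemble$lon)
  pid <- row(ensemble$lon)[keep]
  ob <- col(ensemble$lon)[keep]
  df <- data.frame(
    particle = pid,
    source = ensemble$source[pid],
    release = format(ensemble$release_time[pid], "%Y-%m-%dT%H:%M:%S", tz = tz),
    tz = tz,
    age_days = ensemble$age_days[ob],
    lon = ensemble$lon[keep], lat = ensemble$lat[keep],
    exited = ensemble$exited[pid]
  )
  utils::write.csv(df[order(df$particle, df$age_days), ], path, row.names = FALSE)
  invisible(path)
}
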