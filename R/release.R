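# Spawning release schedules: lunar-gated, seasonal, fixed evening hours.

#' Build the spawning release schedule
#'
#' Spawning is gated three ways: (i) it happens only in the spawning season
#' (May-August by default) — only full moons whose local calendar date falls
#' inside the season open a window; (ii) releases occur on every day within
#' +/- `window_days` of such a full moon, with the window clipped to the
#' season boundaries; (iii) on each release day, particles are released at
#' 3-hour intervals in the 18:00-24:00 evening window (18:00, 21:00, 24:00
#' local — 24:00 is kept on the same calendar day). With an astronomical
#' calendar for 2019-2023 and 200 particles per event this yields 798
#' events = 159,600 particles per site.
#'
#' @param layout a [habitat_layout()]; one event list is produced per site.
#' @param calendar a `lunar_calendar` covering `years`.
#' @param years integer vector of calendar years to simulate.
#' @param per_event_count particles per release event (> 0; default 200).
#' @param season_months months in which spawning can occur (default 5:8).
#' @param window_days half-width of the lunar window in days (default 6).
#' @param release_hours local hours of the daily release events
#'   (default `c(18, 21, 24)`).
#' @return data.frame of class `release_schedule` with columns `site`,
#'   `time` (POSIXct) and `count`, ordered by site then time.
#' @export
build_release_schedule <- function(layout, calendar, years,
                                   per_event_count = 200,
                                   season_months = 5:8,
                                   window_days = 6,
                                   release_hours = c(18, 21, 24)) {
  stopifnot(inherits(layout, "habitat_layout"),
            inherits(calendar, "POSIXct"),
            per_event_count > 0)
  tz <- attr(calendar, "tzone") %||% "UTC"
  cyr <- as.integer(format(calendar, "%Y"))
  cmo <- as.integer(format(calendar, "%m"))
  moons <- calendar[cyr %in% years & cmo %in% season_months]
  days <- character(0)
  for (m in moons) {
    m <- as.POSIXct(m, origin = "1970-01-01", tz = tz)
    d0 <- as.Date(format(m, "%Y-%m-%d"))
    win <- seq(d0 - window_days, d0 + window_days, by = "day")
    yr <- as.integer(format(d0, "%Y"))
    season_lo <- as.Date(sprintf("%d-%02d-01", yr, min(season_months)))
    season_hi <- seq(as.Date(sprintf("%d-%02d-01", yr, max(season_months))),
                     by = "month", length.out = 2)[2] - 1
    days <- c(days, as.character(win[win >= season_lo & win <= season_hi]))
  }
  days <- sort(unique(days))
  if (length(days) == 0) {
    warning("no release days: lunar windows do not intersect the spawning season")
    return(structure(
      data.frame(site = character(0), time = as.POSIXct(character(0), tz = tz),
                 count = integer(0)),
      class = c("release_schedule", "data.frame")))
  }
  day_start <- as.POSIXct(paste0(days, " 00:00:00"), tz = tz)
  times <- sort(rep(day_start, times = length(release_hours)) +
                  rep(release_hours, each = length(days)) * 3600)
  sites <- layout$sites$site
  out <- data.frame(
    site = rep(sites, each = length(times)),
    time = rep(times, times = length(sites)),
    count = as.integer(per_event_count),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("release_schedule", "data.frame"),
            release_days = days, window_days = window_days,
            season_months = season_months)
}

#' Total scheduled particles, overall or per site
#' @param schedule a `release_schedule`.
#' @param per_site if TRUE, return a named vector of per-site totals.
#' @export
total_particles <- function(schedule, per_site = FALSE) {
  if (per_site) tapply(schedule$count, schedule$site, sum)
  else sum(schedule$count)
}

#' Write / read a release schedule as CSV
#' @param schedule a `release_schedule`.
#' @param path file path.
#' @export
write_schedule_csv <- function(schedule, path) {
  tz <- attr(schedule$time, "tzone") %||% "UTC"
  df <- data.frame(site = schedule$site,
                   time = format(schedule$time, "%Y-%m-%dT%H:%M:%S", tz = tz),
                   tz = tz, count = schedule$count)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tz <- df$tz[1]
  out <- data.frame(site = as.character(df$site),
                    time = as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%S", tz = tz),
                    count = as.integer(df$count), stringsAsFactors = FALSE)
  structure(out, class = c("release_schedule", "data.frame"))
}
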