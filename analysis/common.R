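# Shared study configuration for the analysis drivers.
#
# A scaled-down emulation of an along-archipelago dispersal study: a
# boundary jet linking the ends of a 20-site island chain whose central
# sites sit away from the jet core, a lunar-gated spawning calendar for one
# season, and passive surface advection. Problem sizes (one spawning year,
# 20 particles per release event, 3 PLDs) keep a full run on a laptop scale
# while preserving every structural feature of the full design.

library(larvanet)

RESULTS_DIR <- file.path("results")
SEED <- 20260925L

ARC_LON <- c(124, 125.5, 127)
ARC_LAT <- c(24, 24.6, 24)

study_layout <- function() {
  generate_island_chain(
    20, groups = c(sakishima = 5, okinawa = 4, amami = 4, tokara = 3, osumi = 4),
    arc_lon = ARC_LON, arc_lat = ARC_LAT
  )
}

# Two current systems, generated separately and summed on the shared grid:
#  - an offshore boundary jet running straight past the chain ends (with a
#    weak counter-current band between the jet and the islands), which
#    links the ends while bypassing the bulge of the arc;
#  - a slow coastal current following the island arc itself, which gives
#    neighbour-scale stepping-stone connectivity along the chain.
study_field <- function(seed = SEED) {
  shared <- list(
    lon_range = c(123, 128), lat_range = c(23, 26.5), spacing = 0.1,
    origin = as.POSIXct("2021-04-25 00:00:00", tz = "Asia/Tokyo"),
    span_days = 160, step_hours = 3)
  offshore <- generate_jet_field(do.call(field_config, c(shared, list(
    jet_lon = c(123.2, 127.8), jet_lat = c(23.55, 23.55),
    jet_peak = 0.6, jet_width = 40,
    counter_speed = 0.08, counter_offset_km = 60, counter_width_km = 25,
    eddy_amp = 0.02, eddy_period_days = 20,
    noise_sd = 0.01, seed = seed))))
  coastal <- generate_jet_field(do.call(field_config, c(shared, list(
    jet_lon = ARC_LON, jet_lat = ARC_LAT,
    jet_peak = 0.04, jet_width = 15,
    counter_speed = 0, eddy_amp = 0, noise_sd = 0, seed = seed))))
  velocity_field(offshore$lon, offshore$lat, offshore$time,
                 offshore$u + coastal$u, offshore$v + coastal$v)
}

STUDY_YEARS <- 2021
STUDY_WINDOW_DAYS <- 2     # scaled down from the +/- 6 d lunar window
STUDY_COUNT <- 20          # particles per release event (full design: 200)
STUDY_PLDS <- c(10, 20, 30)
HEADLINE_PLD <- 30
PRE_COMPETENCY <- 4

study_params <- function() {
  integration_params(dt_minutes = 60, output_interval_hours = 1,
                     max_age_days = max(STUDY_PLDS))
}
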