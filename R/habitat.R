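# Release-site (habitat) layouts along an island chain.

#' Construct a habitat layout
#'
#' @param sites data.frame with columns `site` (unique ids), `lon`, `lat`
#'   (decimal degrees) and `group` (island-group label).
#' @param box_halfwidth_km half-width of the square release/settlement box
#'   centred on each site (default 1.5, i.e. a 3 x 3 km box).
#' @return object of class `habitat_layout`.
#' @export
habitat_layout <- function(sites, box_halfwidth_km = 1.5) {
  stopifnot(is.data.frame(sites),
            all(c("site", "lon", "lat", "group") %in% names(sites)),
            box_halfwidth_km > 0)
  sites$site <- as.character(sites$site)
  sites$group <- as.character(sites$group)
  if (anyDuplicated(sites$site)) stop("site ids must be unique")
  structure(list(sites = sites, box_halfwidth_km = box_halfwidth_km),
            class = "habitat_layout")
}

#' @export
print.habitat_layout <- function(x, ...) {
  cat(sprintf("habitat_layout: %d sites in %d group(s), box half-width %.1f km\n",
              nrow(x$sites), length(unique(x$sites$group)), x$box_halfwidth_km))
  invisible(x)
}

#' Place release sites along an island arc
#'
#' Sites are placed at equal arc-length spacing along a waypoint polyline
#' (the island chain), from its start to its end, and island-group labels
#' are assigned in contiguous blocks.
#'
#' @param n_sites number of sites (>= 2).
#' @param groups either a single integer (number of equally sized contiguous
#'   groups), a named integer vector of group sizes summing to `n_sites`, or
#'   a character vector of length `n_sites` with contiguous labels.
#' @param arc_lon,arc_lat arc waypoints (degrees), at least two.
#' @param box_halfwidth_km passed to [habitat_layout()].
#' @param prefix prefix for generated site ids.
#' @return a [habitat_layout()]. Consecutive inter-site distance equals the
#'   chain length divided by `n_sites - 1` (15 km for a 60 km chain of 5).
#' @export
generate_island_chain <- function(n_sites, groups = 1L,
                                  arc_lon = c(123, 126.5, 130),
                                  arc_lat = c(24, 26, 29.5),
                                  box_halfwidth_km = 1.5,
                                  prefix = "S") {
  stopifnot(n_sites >= 2, length(arc_lon) == length(arc_lat), length(arc_lon) >= 2)
  total <- polyline_lengths(arc_lon, arc_lat)$total
  s <- seq(0, total, length.out = n_sites)
  pts <- polyline_point(arc_lon, arc_lat, s)
  if (is.character(groups) && length(groups) == n_sites) {
    lab <- groups
    if (length(rle(lab)$values) != length(unique(lab)))
      stop("group labels must be contiguous along the chain")
  } else if (length(groups) == 1 && is.numeric(groups)) {
    k <- as.integer(groups)
    sizes <- rep(n_sites %/% k, k) + c(rep(1, n_sites %% k), rep(0, k - n_sites %% k))
    lab <- rep(paste0("g", seq_len(k)), times = sizes)
  } else if (is.numeric(groups)) {
    if (sum(groups) != n_sites) stop("group sizes must sum to n_sites")
    lab <- rep(names(groups) %||% paste0("g", seq_along(groups)), times = groups)
  } else stop("unrecognized 'groups' specification")
  habitat_layout(
    data.frame(site = sprintf("%s%02d", prefix, seq_len(n_sites)),
               lon = pts$lon, lat = pts$lat, group = lab,
               stringsAsFactors = FALSE),
    box_halfwidth_km = box_halfwidth_km
  )
}

#' Pairwise along-ground chain distances between consecutive sites (km)
#' @param layout a [habitat_layout()].
#' @return numeric vector of length `n_sites - 1`.
#' @export
consecutive_site_distances <- function(layout) {
  s <- layout$sites
  polyline_lengths(s$lon, s$lat)$seg
}

#' Write / read a habitat layout as CSV
#' @param layout a [habitat_layout()].
#' @param path file path.
#' @export
write_sites_csv <- function(layout, path) {
  stopifnot(inherits(layout, "habitat_layout"))
  df <- layout$sites
  df$box_halfwidth_km <- layout$box_halfwidth_km
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_csv
#' @export
read_sites_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  hw <- if ("box_halfwidth_km" %in% names(df)) df$box_halfwidth_km[1] else 1.5
  habitat_layout(df[, c("site", "lon", "lat", "group")], box_halfwidth_km = hw)
}
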