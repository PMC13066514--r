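# Trajectories -> dispersal-percentage matrices, island-group aggregates,
# strong-current entry fractions, and pathway kernel densities.

#' Count site-box passages per (source, sink) pair
#'
#' A particle counts toward sink B if any recorded position with age in
#' `(pre_competency_days, pld_days]` lies inside B's square box (boundary
#' inclusive, in local-km axes centred on B). Each particle counts at most
#' once per sink but may count toward several sinks (pass-through
#' semantics: passing a site does not remove the particle). The same rule
#' applies to the source's own box, giving the self-recruitment diagonal.
#'
#' @param ensemble a `particle_ensemble`.
#' @param layout a [habitat_layout()]; sinks are its sites.
#' @param pre_competency_days age before which passages do not count
#'   (strict lower bound; default 4).
#' @param pld_days pelagic larval duration: inclusive upper age bound.
#' @return integer matrix, rows = source sites, cols = sink sites.
#' @export
detect_passages <- function(ensemble, layout, pre_competency_days = 4,
                            pld_days = 30) {
  stopifnot(inherits(ensemble, "particle_ensemble"),
            inherits(layout, "habitat_layout"),
            pld_days > pre_competency_days)
  sites <- layout$sites
  if (!all(unique(ensemble$source) %in% sites$site))
    stop("ensemble contains unknown source site ids")
  hw <- layout$box_halfwidth_km
  cols <- which(ensemble$age_days > pre_competency_days &
                  ensemble$age_days <= pld_days)
  n_sites <- nrow(sites)
  counts <- matrix(0L, n_sites, n_sites,
                   dimnames = list(source = sites$site, sink = sites$site))
  if (length(cols) == 0 || nrow(ensemble$lon) == 0) return(counts)
  lon <- ensemble$lon[, cols, drop = FALSE]
  lat <- ensemble$lat[, cols, drop = FALSE]
  src_f <- factor(ensemble$source, levels = sites$site)
  for (b in seq_len(n_sites)) {
    km <- lonlat_to_km(lon, lat, sites$lon[b], sites$lat[b])
    hit <- abs(km$x) <= hw & abs(km$y) <= hw
    hit[is.na(hit)] <- FALSE
    particle_hit <- rowSums(hit) > 0
    counts[, b] <- as.integer(tapply(particle_hit, src_f, sum, default = 0L))
  }
  counts
}

#' Dispersal-percentage matrix from passage counts
#'
#' P(A,B) = 100 * N(A->B) / N_all(A): the percentage of particles released
#' from A that passed through B's box after the pre-competency period and
#' within the PLD. The diagonal is self-recruitment.
#'
#' @param counts integer matrix from [detect_passages()] (sources x sinks,
#'   with dimnames).
#' @param n_all named vector of particles released per source, or a single
#'   number applying to all sources.
#' @param pld_days,pre_competency_days recorded as metadata.
#' @return numeric matrix of class `dispersal_matrix` (percent, in
#'   `[0, 100]`) with attributes `pld_days`, `pre_competency_days`, `n_all`.
#' @export
dispersal_percentage <- function(counts, n_all, pld_days = NA_real_,
                                 pre_competency_days = NA_real_) {
  sites <- rownames(counts)
  if (length(n_all) == 1) n_all <- stats::setNames(rep(n_all, nrow(counts)), sites)
  n_all <- n_all[sites]
  if (any(n_all <= 0)) stop("n_all must be positive for every source")
  if (any(counts > n_all[row(counts)]))
    stop("integrity error: passage counts exceed particles released")
  P <- 100 * sweep(counts, 1, n_all, "/")
  structure(P, class = c("dispersal_matrix", "matrix"),
            pld_days = pld_days, pre_competency_days = pre_competency_days,
            n_all = n_all)
}

#' One-call dispersal matrix from an ensemble
#' @inheritParams detect_passages
#' @return a `dispersal_matrix` (see [dispersal_percentage()]).
#' @export
dispersal_matrix <- function(ensemble, layout, pld_days = 30,
                             pre_competency_days = 4) {
  counts <- detect_passages(ensemble, layout, pre_competency_days, pld_days)
  n_all <- particles_per_source(ensemble)
  # sources with no particles cannot appear; restrict to released sites
  released <- rownames(counts) %in% names(n_all)
  dispersal_percentage(counts[released, , drop = FALSE], n_all,
                       pld_days = pld_days,
                       pre_competency_days = pre_competency_days)
}

#' Aggregate a site-level dispersal matrix to island groups
#'
#' Each group-to-group cell is the mean of P(a, b) over all source sites a
#' in the row group and sink sites b in the column group; diagonal cells
#' include a = b terms, so self-recruitment enters group self-cells. The
#' per-cell standard deviation across the site pairs is reported alongside.
#'
#' @param P a `dispersal_matrix` (or plain named matrix, percent).
#' @param layout the [habitat_layout()] carrying group labels.
#' @return list of class `group_dispersal_table` with matrices `mean` and
#'   `sd` (groups x groups, in chain order).
#' @export
aggregate_island_groups <- function(P, layout) {
  sites <- layout$sites
  rs <- rownames(P); cs <- colnames(P)
  if (!all(rs %in% sites$site) || !all(cs %in% sites$site))
    stop("matrix site ids missing from layout")
  g_row <- sites$group[match(rs, sites$site)]
  g_col <- sites$group[match(cs, sites$site)]
  groups <- unique(sites$group)
  if (!all(groups %in% g_row) || !all(groups %in% g_col))
    stop("empty island group: every group needs at least one site in the matrix")
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(source = groups, sink = groups))
  s <- m
  for (ga in groups) for (gb in groups) {
    vals <- P[g_row == ga, g_col == gb]
    m[ga, gb] <- mean(vals)
    s[ga, gb] <- stats::sd(vals)
  }
  structure(list(mean = m, sd = s), class = "group_dispersal_table")
}

#' @export
print.group_dispersal_table <- function(x, digits = 3, ...) {
  cat("group dispersal percentages (mean):\n")
  print(round(x$mean, digits))
  invisible(x)
}

#' Fraction of a site's particles entering a strong-current region
#'
#' Percentage of the source's particles having at least one recorded
#' position (at any age) inside a TRUE cell of the mask; a position belongs
#' to the cell whose centre is nearest.
#'
#' @param ensemble a `particle_ensemble`.
#' @param mask a [current_region_mask()].
#' @param source_site site id, or vector of ids pooled as one source
#'   population; default all sources.
#' @return percent (0-100).
#' @export
current_region_entry_fraction <- function(ensemble, mask, source_site = NULL) {
  stopifnot(inherits(mask, "current_region_mask"))
  rows <- if (is.null(source_site)) seq_len(nrow(ensemble$lon))
          else which(ensemble$source %in% source_site)
  if (length(rows) == 0) stop("no particles from the requested source")
  lon <- ensemble$lon[rows, , drop = FALSE]
  lat <- ensemble$lat[rows, , drop = FALSE]
  gi <- round(stats::approx(mask$lon, seq_along(mask$lon), xout = lon,
                            rule = 2)$y)
  gj <- round(stats::approx(mask$lat, seq_along(mask$lat), xout = lat,
                            rule = 2)$y)
  inmask <- matrix(FALSE, nrow(lon), ncol(lon))
  ok <- !is.na(gi) & !is.na(gj)
  inmask[ok] <- mask$mask[cbind(gi[ok], gj[ok])]
  100 * mean(rowSums(inmask) > 0)
}

#' Kernel density of all recorded particle positions
#'
#' Gaussian-kernel density over every recorded (lon, lat) sample of the
#' ensemble, evaluated on a regular grid and renormalized so the discrete
#' integral over the grid equals 1. Bandwidth defaults to Scott's rule per
#' axis (sample standard deviation times n^(-1/6)).
#'
#' @param ensemble a `particle_ensemble`.
#' @param lon_range,lat_range grid extent; default the ensemble's bounding
#'   box padded by 0.5 degrees.
#' @param n grid points per axis (default 101).
#' @param bandwidth optional 2-vector of kernel standard deviations
#'   (degrees lon, lat).
#' @return list of class `pathway_density` with `lon`, `lat`, matrix
#'   `density` (per square degree) and `bandwidth`.
#' @export
pathway_density <- function(ensemble, lon_range = NULL, lat_range = NULL,
                            n = 101, bandwidth = NULL) {
  lon <- as.vector(ensemble$lon); lat <- as.vector(ensemble$lat)
  keep <- !is.na(lon) & !is.na(lat)
  lon <- lon[keep]; lat <- lat[keep]
  if (length(lon) == 0) stop("ensemble has no recorded positions")
  lon_range <- lon_range %||% (range(lon) + c(-0.5, 0.5))
  lat_range <- lat_range %||% (range(lat) + c(-0.5, 0.5))
  if (is.null(bandwidth)) {
    m <- length(lon)
    scott <- function(x) {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) s <- diff(range(x)) / 10 + 1e-3
      s * m^(-1 / 6)
    }
    bandwidth <- c(scott(lon), scott(lat))
  }
  if (any(bandwidth <= 0)) stop("bandwidth must be positive")
  # MASS::kde2d's h is 1/4 of the kernel sd scale it uses internally
  kd <- MASS::kde2d(lon, lat, h = 4 * bandwidth, n = n,
                    lims = c(lon_range, lat_range))
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  dens <- kd$z / (sum(kd$z) * cell)
  structure(list(lon = kd$x, lat = kd$y, density = dens,
                 bandwidth = bandwidth),
            class = "pathway_density")
}

#' Write a dispersal matrix (or any named square matrix) as CSV
#' @param m matrix with site-id dimnames.
#' @param path file path.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(site = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
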