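# Comparison of genetic differentiation with geography and modelled
# dispersal: distance matrices and Mantel permutation tests.

.check_square <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(name, " must be a square matrix")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop(name, " must carry matching site-id dimnames")
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-12)
    stop(name, " must be symmetric")
  invisible(m)
}

#' Pairwise geographic distance between sites (km)
#'
#' Straight-line ("Euclidean") distance computed on a local equirectangular
#' projection centred on the centroid of the chosen sites; a great-circle
#' option is available for wider domains.
#'
#' @param layout a [habitat_layout()].
#' @param subset optional site ids to restrict to (default all).
#' @param method `"equirectangular"` (default) or `"greatcircle"`
#'   (haversine, via the geosphere package).
#' @return symmetric km matrix with zero diagonal and site-id dimnames.
#' @export
geographic_distance <- function(layout, subset = NULL,
                                method = c("equirectangular", "greatcircle")) {
  method <- match.arg(method)
  s <- layout$sites
  if (!is.null(subset)) {
    if (!all(subset %in% s$site)) stop("unknown site ids in subset")
    s <- s[match(subset, s$site), ]
  }
  n <- nrow(s)
  if (method == "equirectangular") {
    km <- lonlat_to_km(s$lon, s$lat, mean(s$lon), mean(s$lat))
    D <- as.matrix(stats::dist(cbind(km$x, km$y)))
  } else {
    if (!requireNamespace("geosphere", quietly = TRUE))
      stop("the greatcircle method needs the geosphere package")
    D <- geosphere::distm(cbind(s$lon, s$lat),
                          fun = geosphere::distHaversine) / 1000
  }
  dimnames(D) <- list(s$site, s$site)
  D
}

#' Convert symmetric dispersal proportions to a distance matrix
#'
#' The dispersal distance between two sites is log(1/p), where p is the
#' (symmetrized) stepping-stone proportion. Larger flow = smaller distance.
#'
#' @param p symmetric matrix of proportions in (0, 1], e.g. from
#'   [symmetrize_max()].
#' @return symmetric distance matrix (zero diagonal where p = 1).
#' @export
dispersal_to_distance <- function(p) {
  .check_square(p, "p")
  off <- p[upper.tri(p)]
  bad <- which(upper.tri(p) & (is.na(p) | p <= 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    prs <- paste(rownames(p)[bad[, 1]], colnames(p)[bad[, 2]], sep = "-")
    stop("zero/undefined dispersal proportion for pair(s): ",
         paste(prs, collapse = ", "),
         "; restrict the comparison to connected pairs")
  }
  D <- log(1 / p)
  diag(D) <- 0
  D
}

# Pearson r between the upper off-diagonal vectors of two matrices,
# optionally dropping masked pair positions
.mantel_r <- function(v1, v2) {
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("degenerate (constant) distance vector: correlation undefined")
  stats::cor(v1, v2, method = "pearson")
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation R of the vectorized upper off-diagonals, with a
#' permutation null built by simultaneously shuffling the rows and columns
#' of the second matrix. The identity permutation is counted in both the
#' numerator and denominator, so p is never exactly zero. The default test
#' is two-tailed on |R|.
#'
#' @param m1,m2 symmetric matrices with identical site-id dimnames.
#' @param n_perm number of random permutations (default 10000).
#' @param seed integer seed for the permutation draw.
#' @param tail `"two"` (default), `"greater"` or `"less"`.
#' @param exclude optional 2-column matrix / data.frame of site-id pairs
#'   whose entries are dropped from the correlation (e.g. an outlier pair).
#' @param exclusion_follows for the permutation null with exclusions:
#'   `"positions"` (default) keeps the mask fixed to the original pair
#'   positions; `"labels"` lets the mask follow the permuted site labels.
#' @return object of class `mantel_result` with elements `r`, `p`,
#'   `n_perm`, `tail`, `method`, `seed`, `excluded`, `n_sites`.
#' @export
mantel_test <- function(m1, m2, n_perm = 10000, seed = NULL,
                        tail = c("two", "greater", "less"),
                        exclude = NULL,
                        exclusion_follows = c("positions", "labels")) {
  tail <- match.arg(tail)
  exclusion_follows <- match.arg(exclusion_follows)
  .check_square(m1, "m1"); .check_square(m2, "m2")
  if (!identical(rownames(m1), rownames(m2)))
    stop("m1 and m2 must share the same site ids in the same order")
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- nrow(m1)
  ut <- upper.tri(m1)

  keep <- ut
  excluded <- character(0)
  if (!is.null(exclude)) {
    exclude <- as.matrix(exclude)
    for (r in seq_len(nrow(exclude))) {
      i <- match(exclude[r, 1], rownames(m1))
      j <- match(exclude[r, 2], rownames(m1))
      if (is.na(i) || is.na(j)) stop("excluded pair has unknown site id")
      keep[min(i, j), max(i, j)] <- FALSE
      excluded <- c(excluded, paste(exclude[r, 1], exclude[r, 2], sep = "-"))
    }
    if (!any(keep)) stop("all pairs excluded")
  }

  v1 <- m1[keep]
  r_obs <- .mantel_r(v1, m2[keep])

  count <- 1L  # identity permutation
  if (is.null(seed)) seed <- 1L
  with_seed(seed, {
    for (b in seq_len(n_perm - 1)) {
      perm <- sample.int(n)
      if (exclusion_follows == "labels" && !is.null(exclude)) {
        # mask defined on labels: exclude the permuted images of the pairs
        inv <- order(perm)
        keep_b <- ut
        if (length(excluded)) {
          prs <- do.call(rbind, strsplit(excluded, "-"))
          for (r in seq_len(nrow(prs))) {
            i <- inv[match(prs[r, 1], rownames(m1))]
            j <- inv[match(prs[r, 2], rownames(m1))]
            keep_b[min(i, j), max(i, j)] <- FALSE
          }
        }
        v1b <- m1[keep_b]
        r_b <- .mantel_r(v1b, m2[perm, perm][keep_b])
      } else {
        r_b <- .mantel_r(v1, m2[perm, perm][keep])
      }
      hit <- switch(tail,
                    two = abs(r_b) >= abs(r_obs) - 1e-12,
                    greater = r_b >= r_obs - 1e-12,
                    less = r_b <= r_obs + 1e-12)
      if (hit) count <- count + 1L
    }
  })
  structure(list(r = r_obs, p = count / n_perm, n_perm = n_perm,
                 tail = tail, method = "pearson", seed = seed,
                 excluded = excluded, n_sites = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (pearson, %s-tailed): R = %.4f, p = %.4g (%d permutations%s)\n",
              x$tail, x$r, x$p, x$n_perm,
              if (length(x$excluded)) paste0("; excluded ",
                                             paste(x$excluded, collapse = ", "))
              else ""))
  invisible(x)
}

#' Mantel test with designated site pairs excluded
#'
#' Convenience wrapper around [mantel_test()] for the outlier-excluded
#' variant: R is computed over all off-diagonal pairs minus the excluded
#' set, and by default the exclusion mask stays fixed to the original pair
#' positions under permutation.
#'
#' @inheritParams mantel_test
#' @param excluded_pairs 2-column matrix / data.frame of site-id pairs.
#' @export
mantel_excluding_pairs <- function(m1, m2, excluded_pairs, n_perm = 10000,
                                   seed = NULL, tail = "two",
                                   exclusion_follows = "positions") {
  mantel_test(m1, m2, n_perm = n_perm, seed = seed, tail = tail,
              exclude = excluded_pairs, exclusion_follows = exclusion_follows)
}

#' Synthetic F_ST matrix with known dependence on dispersal
#'
#' Generates genetic-differentiation matrices whose expectation is
#' log-linear in dispersal: F_ST(i,j) = a + b * log(1/p_ij) + noise for
#' i < j, mirrored, clipped below, zero diagonal. Used as ground truth for
#' testing that the Mantel stage recovers a dispersal-differentiation
#' association.
#'
#' @param p symmetric dispersal-proportion matrix, all off-diagonal entries
#'   in (0, 1].
#' @param a intercept (dimensionless F_ST units).
#' @param b slope per log-unit of 1/p (>= 0 for the expected negative
#'   dispersal-F_ST association).
#' @param sd standard deviation of the added Gaussian noise (>= 0).
#' @param clip lower clip (default 0; F_ST estimates are floored there).
#' @param seed integer seed.
#' @return symmetric F_ST matrix with zero diagonal.
#' @export
generate_synthetic_fst <- function(p, a = 0.01, b = 0.005, sd = 0.003,
                                   clip = 0, seed = 1L) {
  .check_square(p, "p")
  stopifnot(sd >= 0)
  off <- upper.tri(p)
  if (any(is.na(p[off]) | p[off] <= 0))
    stop("all compared pairs need dispersal proportion > 0; ",
         "restrict to connected pairs")
  n <- nrow(p)
  fst <- matrix(0, n, n, dimnames = dimnames(p))
  vals <- a + b * log(1 / p[off])
  if (sd > 0) vals <- vals + with_seed(seed, stats::rnorm(sum(off), 0, sd))
  vals <- pmax(vals, clip)
  fst[off] <- vals
  fst[lower.tri(fst)] <- t(fst)[lower.tri(fst)]
  fst
}
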