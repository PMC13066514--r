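# Passage detection, dispersal percentages, group aggregation, current-region
# entry, and pathway densities.

three_site_layout <- function(hw = 1.5) {
  # sites 20 km apart along the equator so boxes never overlap
  habitat_layout(data.frame(
    site = c("A", "B", "C"),
    lon = 125 + c(0, 20, 40) / 111.19508,
    lat = 0, group = c("g1", "g1", "g2")), box_halfwidth_km = hw)
}

test_that("passage counting follows the age window and pass-through rules", {
  lay <- three_site_layout()
  ages <- c(0, 3, 10, 20)
  lonB <- 125 + 20 / 111.19508
  lonC <- 125 + 40 / 111.19508

  # particle 1 crosses B at age 10 only; particle 2 sits in B at age 3 only
  # (pre-competency); particle 3 crosses B then C; none revisits A's box
  # after the pre-competency age
  mid <- 125 + 10 / 111.19508   # between A and B, in no box
  lon <- rbind(c(125, 125, lonB, mid),
               c(125, lonB, mid, mid),
               c(125, 125, lonB, lonC))
  lat <- matrix(0, 3, 4)
  ens <- make_ensemble(lon, lat, ages, source = c("A", "A", "A"))
  cnt <- detect_passages(ens, lay, pre_competency_days = 4, pld_days = 30)
  expect_equal(cnt["A", "B"], 2L)   # particles 1 and 3; particle 2 too early
  expect_equal(cnt["A", "C"], 1L)   # pass-through: particle 3 counts twice
  expect_equal(cnt["A", "A"], 0L)   # never inside A after age 4

  # each particle counts at most once per sink despite repeat crossings
  lon2 <- rbind(c(125, lonB, lonB, lonB))
  ens2 <- make_ensemble(lon2, matrix(0, 1, 4), ages, source = "A")
  expect_equal(detect_passages(ens2, lay, 4, 30)["A", "B"], 1L)

  # box boundary is inclusive (position exactly 1.5 km from centre counts)
  lon3 <- rbind(c(125, 125, lonB + 1.5 / 111.19508, 125))
  ens3 <- make_ensemble(lon3, matrix(0, 1, 4), ages, source = "A")
  expect_equal(detect_passages(ens3, lay, 4, 30)["A", "B"], 1L)

  # age window: strict > pre-competency, inclusive <= PLD
  ens4 <- make_ensemble(rbind(c(125, 125, 125, lonB)), matrix(0, 1, 4),
                        c(0, 2, 4, 30), source = "A")
  expect_equal(detect_passages(ens4, lay, 4, 30)["A", "B"], 1L)
  ens5 <- make_ensemble(rbind(c(125, 125, lonB, 125)), matrix(0, 1, 4),
                        c(0, 2, 4, 31), source = "A")
  expect_equal(detect_passages(ens5, lay, 4, 30)["A", "B"], 0L)
})

test_that("production passage counts match the naive point-in-box oracle", {
  lay <- three_site_layout()
  set.seed(11)
  n <- 40; m <- 25
  ages <- seq(0, 30, length.out = m)
  lon <- matrix(125 + runif(n * m, -0.01, 0.41) * 111.19508 / 111.19508, n, m)
  lon <- matrix(125 + runif(n * m, -0.02, 0.40), n, m)
  lat <- matrix(runif(n * m, -0.03, 0.03), n, m)
  lon[sample(n * m, 50)] <- NA  # exited samples
  lat[is.na(lon)] <- NA
  ens <- make_ensemble(lon, lat, ages, source = sample(c("A", "B", "C"), n, TRUE))
  expect_identical(detect_passages(ens, lay, 4, 30),
                   oracle_passages(ens, lay, 4, 30))
  # monotone in PLD: longer window can only add passages
  c10 <- detect_passages(ens, lay, 4, 10)
  c30 <- detect_passages(ens, lay, 4, 30)
  expect_true(all(c30 >= c10))
})

test_that("dispersal percentages implement P = 100 N / N_all with bounds", {
  cnt <- matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  cnt["A", "B"] <- 3L; cnt["B", "A"] <- 200L
  P <- dispersal_percentage(cnt, c(A = 200, B = 200))
  expect_equal(P["A", "B"], 100 * 3 / 200)   # 1.5%
  expect_equal(P["A", "A"], 0)
  expect_equal(P["B", "A"], 100)
  expect_true(all(P >= 0 & P <= 100))
  bad <- cnt; bad["A", "B"] <- 300L
  expect_error(dispersal_percentage(bad, 200), "integrity")
  expect_error(dispersal_percentage(cnt, 0), "positive")
})

test_that("island-group aggregation averages all site pairs, diagonal included", {
  lay <- habitat_layout(data.frame(
    site = c("a1", "a2", "b1", "b2"),
    lon = c(125, 125.2, 126, 126.2), lat = 0,
    group = c("gA", "gA", "gB", "gB")))
  P <- matrix(0, 4, 4, dimnames = list(lay$sites$site, lay$sites$site))
  P["a1", "b1"] <- 1; P["a1", "b2"] <- 2; P["a2", "b1"] <- 3; P["a2", "b2"] <- 4
  gt <- aggregate_island_groups(P, lay)
  expect_equal(gt$mean["gA", "gB"], 2.5)
  expect_equal(gt$sd["gA", "gB"], sd(1:4))
  expect_equal(gt$mean["gA", "gA"], 0)   # includes the a1->a1 etc. terms

  # single-site groups reproduce the site matrix
  lay1 <- habitat_layout(data.frame(site = c("x", "y"), lon = c(125, 126),
                                    lat = 0, group = c("gx", "gy")))
  P1 <- matrix(c(5, 1, 2, 7), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  g1 <- aggregate_island_groups(P1, lay1)
  expect_equal(unname(g1$mean), unname(P1))

  # symmetric site matrix gives a symmetric group table
  Ps <- P + t(P)
  gs <- aggregate_island_groups(Ps, lay)
  expect_equal(unname(gs$mean), unname(t(gs$mean)))

  # aggregation commutes with site permutation within groups
  perm <- c("a2", "a1", "b2", "b1")
  gp <- aggregate_island_groups(P[perm, perm], lay)
  expect_equal(gp$mean, gt$mean)
})

test_that("current-region entry fractions follow the threshold rule", {
  lay <- one_site_layout()
  f <- uniform_field(0.5, 0)
  ens <- advect(f, single_release(count = 10), lay,
                integration_params(max_age_days = 1), seed = 1)
  m_all <- current_region_mask(f, threshold = 0.4)
  expect_true(all(m_all$mask))
  expect_equal(current_region_entry_fraction(ens, m_all, "A"), 100)
  m_none <- current_region_mask(f, threshold = 0.6)
  expect_true(!any(m_none$mask))
  expect_equal(current_region_entry_fraction(ens, m_none, "A"), 0)
})

test_that("mean-field averages speed, not velocity", {
  lon <- seq(124, 126, 0.5); lat <- seq(-1, 1, 0.5)
  times <- t_origin + c(0, 3600)
  u <- array(rep(c(1, -1), each = length(lon) * length(lat)),
             c(length(lon), length(lat), 2))
  v <- array(0, dim(u))
  f <- velocity_field(lon, lat, times, u, v)
  ms <- mean_field(f)
  expect_true(all(abs(ms$speed - 1) < 1e-12))     # |u| averaged
  mv <- mean_field(f, of = "velocity")
  expect_true(all(abs(mv$speed) < 1e-12))         # mean vector cancels
  expect_error(mean_field(f, months = 1), "months")
})

test_that("pathway density is a normalized Gaussian KDE with expected modes", {
  # single (near-)stationary particle: maximum at its position
  lon <- matrix(125, 1, 5); lat <- matrix(0.5, 1, 5)
  ens <- make_ensemble(lon, lat, 0:4, source = "A")
  pd <- pathway_density(ens, lon_range = c(124, 126), lat_range = c(-0.5, 1.5),
                        n = 81, bandwidth = c(0.1, 0.1))
  peak <- which(pd$density == max(pd$density), arr.ind = TRUE)
  expect_equal(pd$lon[peak[1]], 125, tolerance = 0.03)
  expect_equal(pd$lat[peak[2]], 0.5, tolerance = 0.03)
  cell <- diff(pd$lon[1:2]) * diff(pd$lat[1:2])
  expect_equal(sum(pd$density) * cell, 1, tolerance = 0.01)

  # two equal clusters: two equal local maxima
  lon2 <- rbind(matrix(124.5, 3, 4), matrix(125.5, 3, 4))
  lat2 <- matrix(0, 6, 4)
  ens2 <- make_ensemble(lon2, lat2, 0:3, source = rep("A", 6))
  pd2 <- pathway_density(ens2, lon_range = c(124, 126), lat_range = c(-1, 1),
                         n = 101, bandwidth = c(0.08, 0.08))
  i1 <- which.min(abs(pd2$lon - 124.5)); i2 <- which.min(abs(pd2$lon - 125.5))
  j0 <- which.min(abs(pd2$lat))
  expect_equal(pd2$density[i1, j0], pd2$density[i2, j0], tolerance = 1e-6)
  expect_gt(pd2$density[i1, j0], pd2$density[which.min(abs(pd2$lon - 125)), j0])

  expect_error(pathway_density(ens, bandwidth = c(0, 0.1)), "bandwidth")
})

test_that("matrix CSV serialization round-trips", {
  P <- matrix(runif(9), 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(P, path)
  expect_equal(read_matrix_csv(path), P, tolerance = 1e-12)
})
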