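# Dispersal networks: construction, betweenness, stepping-stone paths.

chain_P <- function(entries) {
  # entries: named list like list(c("A","B",1), ...) with percent values
  ids <- sort(unique(unlist(lapply(entries, function(e) e[1:2]))))
  P <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in entries) P[e[1], e[2]] <- as.numeric(e[3])
  P
}

test_that("network construction puts edges exactly where P > 0 with log distances", {
  ids <- c("A", "B", "C")
  P0 <- matrix(0, 3, 3, dimnames = list(ids, ids))
  expect_equal(igraph::ecount(build_network(P0)), 0)

  P <- P0; P["A", "B"] <- 1
  net <- build_network(P)
  expect_equal(igraph::ecount(net), 1)
  expect_equal(igraph::E(net)$p, 0.01)
  expect_equal(igraph::E(net)$d, log(100), tolerance = 1e-12)

  P2 <- P0; P2["A", "B"] <- 100
  expect_equal(igraph::E(build_network(P2))$d, 0)

  # self-loops never become edges; negative P rejected
  P3 <- P0; diag(P3) <- 50; P3["B", "C"] <- 2
  expect_equal(igraph::ecount(build_network(P3)), 1)
  P4 <- P0; P4["A", "B"] <- -1
  expect_error(build_network(P4), "negative")
})

test_that("betweenness matches hand enumeration on canonical digraphs", {
  # directed path A->B->C: B lies on 1 of the 2 ordered through-pairs
  P <- chain_P(list(c("A", "B", 1), c("B", "C", 1)))
  for (mode in c("weighted", "unweighted")) {
    b <- betweenness_centrality(build_network(P), mode)
    expect_equal(unname(b[c("A", "B", "C")]), c(0, 0.5, 0), info = mode)
  }

  # directed star centre -> leaves: no through-paths anywhere
  Ps <- chain_P(list(c("S", "a", 5), c("S", "b", 5), c("S", "c", 5)))
  expect_true(all(betweenness_centrality(build_network(Ps), "weighted") == 0))

  # n < 3 normalization undefined
  P2 <- matrix(c(0, 1, 0, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(betweenness_centrality(build_network(P2)), "n < 3")

  # weighted and unweighted can rank differently: a heavy 2-hop detour
  # through D beats a weak direct edge only in the weighted view
  P5 <- chain_P(list(c("A", "C", 0.0001), c("A", "D", 50), c("D", "C", 50),
                     c("C", "B", 10)))
  bw <- betweenness_centrality(build_network(P5), "weighted")
  bu <- betweenness_centrality(build_network(P5), "unweighted")
  expect_gt(bw["D"], 0)
  expect_equal(unname(bu["D"]), 0)
})

test_that("stepping-stone products follow the multiplicative path rule", {
  # chain p = 0.01 then 0.02, no direct edge: product 2e-4, 2 generations
  P <- chain_P(list(c("A", "B", 1), c("B", "C", 2)))
  ss <- stepping_stone(build_network(P))
  expect_equal(ss$proportion["A", "C"], 2e-4, tolerance = 1e-12)
  expect_equal(ss$percent["A", "C"], 0.02, tolerance = 1e-12)
  expect_equal(ss$generations["A", "C"], 2L)
  expect_equal(ss$paths[["A", "C"]], c("A", "B", "C"))
  expect_true(is.na(ss$proportion["C", "A"]))   # unreachable flagged

  # direct edge p = 0.05 beats the 2e-4 two-hop product: 1 generation
  P2 <- P; P2["A", "C"] <- 5
  ss2 <- stepping_stone(build_network(P2))
  expect_equal(ss2$proportion["A", "C"], 0.05)
  expect_equal(ss2$generations["A", "C"], 1L)

  # a pair with only a direct edge returns that edge's proportion
  expect_equal(ss$proportion["A", "B"], 0.01)
  expect_equal(ss$generations["A", "B"], 1L)

  # generation cap: with max_generations = 1 the two-hop route vanishes
  ss1 <- stepping_stone(build_network(P), max_generations = 1)
  expect_true(is.na(ss1$proportion["A", "C"]))

  # log-additivity: product equals exp(-sum of log(1/p)) along the path
  set.seed(21)
  P3 <- random_P(6, 0.5)
  ss3 <- stepping_stone(build_network(P3))
  for (i in 1:6) for (j in 1:6) {
    if (i == j || is.na(ss3$proportion[i, j])) next
    pp <- ss3$paths[[i, j]]
    d_sum <- sum(log(100 / P3[cbind(pp[-length(pp)], pp[-1])]))
    expect_equal(ss3$proportion[i, j], exp(-d_sum), tolerance = 1e-9)
    expect_equal(ss3$generations[i, j], length(pp) - 1L)
  }
})

test_that("generation-capped Floyd-Warshall agrees with exhaustive enumeration", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:7, 1)
    P <- random_P(n, runif(1, 0.3, 0.7))
    gmax <- sample(c(1, 2, 3, n - 1), 1)
    ss <- stepping_stone(build_network(P), max_generations = gmax)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      o <- oracle_best_path(P, i, j, max_edges = gmax)
      if (o$n_best == 0) {
        expect_true(is.na(ss$proportion[i, j]))
      } else {
        expect_equal(ss$proportion[i, j], o$prop, tolerance = 1e-9)
        expect_equal(ss$generations[i, j], o$gen)
      }
    }
  }
})

test_that("adding an edge never weakens any best path (monotonicity)", {
  set.seed(41)
  for (rep in 1:10) {
    P <- random_P(6, 0.4)
    ss_a <- stepping_stone(build_network(P))$proportion
    off <- which(row(P) != col(P) & P == 0)
    if (length(off) == 0) next
    P2 <- P
    P2[sample(off, 1)] <- runif(1, 0.1, 10)
    ss_b <- stepping_stone(build_network(P2))$proportion
    cmp <- ss_b >= ss_a - 1e-12
    cmp[is.na(ss_a)] <- TRUE       # was unreachable
    expect_true(all(cmp[!is.na(cmp)]))
    expect_true(all(!(is.na(ss_b) & !is.na(ss_a))))  # reachability kept
  }
})

test_that("symmetrization takes the larger direction and keeps NA only if both missing", {
  ids <- c("x", "y", "z")
  p <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  diag(p) <- 1
  p["x", "y"] <- 0.01; p["y", "x"] <- 0.03
  p["x", "z"] <- 0.002                    # z->x unreachable
  s <- symmetrize_max(p)
  expect_equal(s["x", "y"], 0.03)
  expect_equal(s["y", "x"], 0.03)
  expect_equal(s["x", "z"], 0.002)        # one-direction pairs keep that value
  expect_true(is.na(s["y", "z"]) && is.na(s["z", "y"]))
  expect_identical(s[!is.na(s)], t(s)[!is.na(s)])

  # symmetric input unchanged
  ps <- matrix(c(1, 0.2, 0.2, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(symmetrize_max(ps), ps)
})

test_that("largest connected subset strips exactly the unconnectable sites", {
  ids <- paste0("s", 1:4)
  p <- matrix(0.1, 4, 4, dimnames = list(ids, ids)); diag(p) <- 1
  expect_equal(largest_connected_subset(p), ids)   # already complete
  # s4 disconnected from everyone; the rest complete
  p2 <- p; p2["s4", ] <- p2[, "s4"] <- 0; diag(p2) <- 1
  expect_equal(largest_connected_subset(p2), ids[1:3])
  # one missing pair: one of its two sites is dropped
  p3 <- p; p3["s1", "s2"] <- p3["s2", "s1"] <- NA
  keep <- largest_connected_subset(p3)
  expect_equal(length(keep), 3)
  expect_true(all(c("s3", "s4") %in% keep))
})

test_that("generations-to-connect is the largest pairwise hop requirement", {
  # complete direct network
  ids <- c("A", "B", "C")
  Pc <- matrix(1, 3, 3, dimnames = list(ids, ids)); diag(Pc) <- 0
  expect_equal(generations_to_connect(build_network(Pc)), 1)

  # chain of 4 connected only consecutively (one direction): 3 generations
  P4 <- chain_P(list(c("a", "b", 1), c("b", "c", 1), c("c", "d", 1)))
  expect_equal(generations_to_connect(build_network(P4)), 3)

  # disconnected pair: infinite
  P5 <- chain_P(list(c("a", "b", 1), c("c", "d", 1)))
  P5["b", "a"] <- 1
  expect_equal(generations_to_connect(build_network(P5)), Inf)

  # subsets restrict the requirement
  expect_equal(generations_to_connect(build_network(P4), c("a", "b")), 1)
})

test_that("network exports write well-formed edge lists and GraphML", {
  P <- chain_P(list(c("A", "B", 1), c("B", "C", 2), c("A", "C", 0.5)))
  net <- build_network(P)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_network_csv(net, csv)
  el <- read.csv(csv)
  expect_equal(nrow(el), 3)
  expect_equal(sort(names(el)), sort(c("source", "target", "P", "p", "d")))
  expect_equal(el$d, log(1 / el$p), tolerance = 1e-9)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), 3)
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C"))
})
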