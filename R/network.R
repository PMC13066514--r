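# Directed dispersal networks: betweenness centrality and multi-generation
# stepping-stone dispersal (generation-capped Floyd-Warshall).

#' Build the directed dispersal network
#'
#' Nodes are sites; a directed edge A -> B exists wherever P(A,B) > 0 and
#' A != B. Each edge carries the percentage `P`, the proportion `p = P/100`,
#' and the distance `d = log(1/p)`. Working on proportions keeps every
#' distance nonnegative (p <= 1), so shortest paths are well defined and
#' path products are probabilities.
#'
#' @param P square matrix of dispersal percentages with site-id dimnames
#'   (e.g. a `dispersal_matrix`).
#' @return igraph object of class `dispersal_network` with vertex attribute
#'   `name` and edge attributes `P`, `p`, `d`.
#' @export
build_network <- function(P) {
  if (is.null(rownames(P)) || !identical(rownames(P), colnames(P)))
    stop("P must be square with matching site-id dimnames")
  if (any(P < 0)) stop("negative dispersal percentage")
  if (any(P > 100)) stop("dispersal percentage above 100")
  A <- unclass(P)
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "directed")
  el <- igraph::as_edgelist(g, names = FALSE)
  pct <- A[el]
  igraph::E(g)$P <- pct
  igraph::E(g)$p <- pct / 100
  igraph::E(g)$d <- log(1 / (pct / 100))
  stopifnot(all(igraph::E(g)$d >= 0))  # no negative cycles possible
  class(g) <- c("dispersal_network", class(g))
  g
}

# distance matrix (log 1/p; Inf off-edges, 0 diagonal) from a network
.distance_matrix <- function(network) {
  n <- igraph::vcount(network)
  ids <- igraph::V(network)$name
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  el <- igraph::as_edgelist(network, names = FALSE)
  D[el] <- igraph::E(network)$d
  diag(D) <- 0
  D
}

#' Normalized betweenness centrality
#'
#' Fraction of shortest paths between ordered node pairs (s, t), s != t !=
#' v, that pass through v, normalized by 1/((n-1)(n-2)). `"weighted"` mode
#' measures path length by the edge distances d = log(1/p) (emphasizing
#' routes carrying more particles); `"unweighted"` mode uses hop counts.
#'
#' @param network a `dispersal_network`.
#' @param mode `"weighted"` or `"unweighted"`.
#' @return named numeric vector of scores in `[0, 1]`, with attributes
#'   `mode` and `normalization`.
#' @export
betweenness_centrality <- function(network, mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  n <- igraph::vcount(network)
  if (n < 3) stop("betweenness normalization undefined for n < 3 nodes")
  w <- if (mode == "weighted") pmax(igraph::E(network)$d, 1e-12) else NA
  raw <- igraph::betweenness(network, directed = TRUE, weights = w)
  out <- raw / ((n - 1) * (n - 2))
  structure(stats::setNames(as.numeric(out), igraph::V(network)$name),
            mode = mode, normalization = 1 / ((n - 1) * (n - 2)))
}

#' Multi-generation stepping-stone dispersal
#'
#' For every ordered site pair (i, j), finds the dispersal path maximizing
#' the product of per-generation proportions (equivalently minimizing the
#' summed distances log(1/p)), subject to the path using at most
#' `max_generations` edges. Solved by generation-indexed dynamic
#' programming (a hop-capped Floyd-Warshall: the uncapped result is the
#' `max_generations = n - 1` limit). Ties are broken toward fewer
#' generations, then toward the smallest intermediate node index, so
#' results are deterministic.
#'
#' @param network a `dispersal_network` (or a percentage matrix accepted by
#'   [build_network()]).
#' @param max_generations maximum number of edges per path (default
#'   unbounded, i.e. n - 1).
#' @return list of class `stepping_stone_result`:
#'   `proportion` (matrix of best-path products, NA where unreachable),
#'   `percent` (same, x 100), `generations` (edge counts, NA where
#'   unreachable; 0 diagonal), `paths` (n x n list of node-id vectors), and
#'   `max_generations`.
#' @export
stepping_stone <- function(network, max_generations = Inf) {
  if (is.matrix(network)) network <- build_network(network)
  d <- .distance_matrix(network)
  n <- nrow(d)
  ids <- rownames(d)
  gmax <- min(max_generations, n - 1)
  if (gmax < 1) stop("max_generations must be >= 1")

  # D[g]: best distance using <= g edges; pred[[g]][i,j]: predecessor of j
  edge_d <- d; diag(edge_d) <- Inf      # single-edge distances
  D <- edge_d
  pred <- matrix(NA_integer_, n, n)
  pred[is.finite(edge_d)] <- row(edge_d)[is.finite(edge_d)]
  preds <- vector("list", gmax)
  gen <- matrix(NA_integer_, n, n)
  gen[is.finite(edge_d)] <- 1L
  best <- edge_d
  best_pred_level <- matrix(NA_integer_, n, n)
  best_pred_level[is.finite(edge_d)] <- 1L
  preds[[1]] <- pred

  if (gmax >= 2) {
    for (g in 2:gmax) {
      Dg <- D
      predg <- preds[[g - 1]]
      for (j in seq_len(n)) {
        # candidate: i -> ... -> k (<= g-1 edges) -> j
        cand <- D + matrix(edge_d[, j], n, n, byrow = TRUE)  # over k columns
        k_best <- max.col(-cand, ties.method = "first")
        v_best <- cand[cbind(seq_len(n), k_best)]
        upd <- v_best < Dg[, j]
        if (any(upd)) {
          Dg[upd, j] <- v_best[upd]
          predg[upd, j] <- k_best[upd]
        }
      }
      preds[[g]] <- predg
      improved <- Dg < best - 1e-15
      if (any(improved)) {
        best[improved] <- Dg[improved]
        gen[improved] <- as.integer(g)
        best_pred_level[improved] <- as.integer(g)
      }
      D <- Dg
    }
  }
  diag(best) <- 0
  diag(gen) <- 0L

  paths <- vector("list", n * n)
  dim(paths) <- c(n, n)
  dimnames(paths) <- list(ids, ids)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { paths[[i, j]] <- ids[i]; next }
    if (!is.finite(best[i, j])) next
    lvl <- best_pred_level[i, j]
    node <- j
    rev_path <- integer(0)
    while (node != i) {
      rev_path <- c(rev_path, node)
      node_prev <- preds[[lvl]][i, node]
      lvl <- max(lvl - 1L, 1L)
      node <- node_prev
    }
    paths[[i, j]] <- ids[c(i, rev(rev_path))]
  }

  prop <- exp(-best)
  prop[!is.finite(best)] <- NA_real_
  diag(prop) <- 1
  dimnames(prop) <- dimnames(gen) <- list(ids, ids)
  structure(list(proportion = prop, percent = 100 * prop,
                 generations = gen, paths = paths,
                 max_generations = gmax),
            class = "stepping_stone_result")
}

#' Symmetrize stepping-stone proportions by the larger direction
#'
#' Dispersal is directional; for comparison with (symmetric) genetic
#' differentiation the larger of the two directed proportions defines the
#' pairwise value. Pairs unreachable in one direction take the reachable
#' direction's value; pairs unreachable in both stay NA.
#'
#' @param result a `stepping_stone_result`, or a square proportion matrix.
#' @return symmetric proportion matrix with unit diagonal.
#' @export
symmetrize_max <- function(result) {
  p <- if (inherits(result, "stepping_stone_result")) result$proportion else result
  out <- pmax(p, t(p), na.rm = TRUE)
  out[is.na(p) & is.na(t(p))] <- NA_real_
  out
}

#' Largest subset of sites with all pairwise dispersal defined
#'
#' Mantel comparisons need every compared pair to carry a positive
#' (symmetrized) dispersal proportion. This strips sites greedily — always
#' removing the site with the most missing/zero pairs — until the
#' remaining matrix has none, which gives a maximal (not necessarily
#' maximum) fully connected subset deterministically.
#'
#' @param p symmetric proportion matrix (NA or 0 = unconnected pair).
#' @return character vector of retained site ids (chain order).
#' @export
largest_connected_subset <- function(p) {
  stopifnot(is.matrix(p), !is.null(rownames(p)))
  keep <- rownames(p)
  repeat {
    m <- p[keep, keep, drop = FALSE]
    bad <- is.na(m) | m <= 0
    diag(bad) <- FALSE
    if (!any(bad) || length(keep) == 0) return(keep)
    worst <- which.max(rowSums(bad))
    keep <- keep[-worst]
  }
}

#' Minimal generations connecting a set of sites
#'
#' Smallest g such that every unordered pair of the subset is linked, in at
#' least one direction, by a dispersal path of at most g edges. Uses
#' unweighted (hop-count) shortest paths: connectivity is about existence
#' of a route, not its strength. Returns Inf if some pair is unreachable
#' in both directions.
#'
#' @param network a `dispersal_network`.
#' @param site_subset site ids (default all nodes).
#' @return single number (possibly Inf).
#' @export
generations_to_connect <- function(network, site_subset = NULL) {
  ids <- igraph::V(network)$name
  site_subset <- site_subset %||% ids
  if (!all(site_subset %in% ids)) stop("unknown site ids in subset")
  hops <- igraph::distances(network, v = site_subset, to = site_subset,
                            mode = "out", weights = NA)
  pairmin <- pmin(hops, t(hops))
  m <- max(pairmin[upper.tri(pairmin)])
  if (length(site_subset) < 2) 0 else m
}

#' Export a dispersal network as an edge-list CSV (source, target, P, p, d)
#' @param network a `dispersal_network`.
#' @param path file path.
#' @export
write_network_csv <- function(network, path) {
  el <- igraph::as_edgelist(network)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   P = igraph::E(network)$P, p = igraph::E(network)$p,
                   d = igraph::E(network)$d)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a dispersal network as GraphML
#' @param network a `dispersal_network`.
#' @param path file path.
#' @export
write_network_graphml <- function(network, path) {
  g <- network
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
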