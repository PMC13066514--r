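# Independent brute-force oracles: exhaustive simple-path enumeration for
# shortest paths and betweenness, naive point-in-box passage scanning, and
# exact Mantel permutation enumeration.

# all simple paths s -> t in an adjacency matrix (TRUE/FALSE), as lists of
# node index vectors, with at most max_edges edges
enumerate_simple_paths <- function(adj, s, t, max_edges = nrow(adj) - 1) {
  paths <- list()
  walk <- function(node, visited, path) {
    if (length(path) - 1 > max_edges) return()
    if (node == t && length(path) > 1) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    if (length(path) - 1 == max_edges) return()
    for (nxt in which(adj[node, ])) {
      if (!visited[nxt]) walk(nxt, `[<-`(visited, nxt, TRUE), c(path, nxt))
    }
  }
  walk(s, `[<-`(logical(nrow(adj)), s, TRUE), s)
  paths
}

# oracle for stepping_stone: best product path by exhaustive enumeration
oracle_best_path <- function(P, s, t, max_edges = nrow(P) - 1) {
  adj <- P > 0; diag(adj) <- FALSE
  paths <- enumerate_simple_paths(adj, s, t, max_edges)
  if (length(paths) == 0)
    return(list(prop = NA_real_, gen = NA_integer_, n_best = 0L))
  prods <- vapply(paths, function(pp) {
    prod(P[cbind(pp[-length(pp)], pp[-1])] / 100)
  }, numeric(1))
  best <- max(prods)
  cand <- which(prods >= best * (1 - 1e-12))
  gens <- vapply(paths[cand], length, integer(1)) - 1L
  list(prop = best, gen = min(gens), n_best = length(cand))
}

# oracle for betweenness: count shortest paths through each node
oracle_betweenness <- function(P, weighted = TRUE) {
  n <- nrow(P)
  adj <- P > 0; diag(adj) <- FALSE
  w <- matrix(Inf, n, n)
  w[adj] <- if (weighted) log(100 / P[adj]) else 1
  score <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- enumerate_simple_paths(adj, s, t)
    if (length(paths) == 0) next
    costs <- vapply(paths, function(pp)
      sum(w[cbind(pp[-length(pp)], pp[-1])]), numeric(1))
    best <- min(costs)
    sel <- which(costs <= best + 1e-9 * max(1, abs(best)))
    sigma <- length(sel)
    through <- integer(n)
    for (k in sel) {
      mid <- setdiff(paths[[k]], c(s, t))
      through[mid] <- through[mid] + 1L
    }
    score <- score + through / sigma
  }
  score / ((n - 1) * (n - 2))
}

# naive passage scan: per particle, per recorded position, per sink box
oracle_passages <- function(ensemble, layout, pre, pld) {
  sites <- layout$sites
  hw <- layout$box_halfwidth_km
  counts <- matrix(0L, nrow(sites), nrow(sites),
                   dimnames = list(source = sites$site, sink = sites$site))
  for (i in seq_len(nrow(ensemble$lon))) {
    hit_sinks <- character(0)
    for (ob in seq_along(ensemble$age_days)) {
      a <- ensemble$age_days[ob]
      if (!(a > pre && a <= pld)) next
      x <- ensemble$lon[i, ob]; y <- ensemble$lat[i, ob]
      if (is.na(x)) next
      for (b in seq_len(nrow(sites))) {
        km <- lonlat_to_km(x, y, sites$lon[b], sites$lat[b])
        if (abs(km$x) <= hw && abs(km$y) <= hw)
          hit_sinks <- union(hit_sinks, sites$site[b])
      }
    }
    src <- ensemble$source[i]
    for (b in hit_sinks) counts[src, b] <- counts[src, b] + 1L
  }
  counts
}

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_permutations(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos - 1)
    }
  }
  out
}

# exact Mantel p by enumeration over all n! relabelings (two-tailed)
oracle_mantel_p <- function(m1, m2) {
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  r_obs <- cor(v1, m2[ut])
  perms <- all_permutations(nrow(m1))
  rs <- vapply(perms, function(pm) cor(v1, m2[pm, pm][ut]), numeric(1))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# random dispersal-percentage matrix on n nodes (seeded by caller)
random_P <- function(n, edge_prob = 0.5, max_pct = 30) {
  P <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  off <- which(row(P) != col(P))
  on <- off[runif(length(off)) < edge_prob]
  P[on] <- runif(length(on), 0.05, max_pct)
  P
}
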