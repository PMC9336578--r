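# Independent oracles for the distance / closeness computations. These stay
# deliberately naive: exhaustive enumeration and textbook algorithms, sharing
# no code with the package's Dijkstra-based implementation.

# exhaustive simple-path enumeration: minimum over all directed simple paths
# of the summed hop costs (1/w)^alpha; feasible for graphs of <= 7 nodes
brute_force_distances <- function(nodes, edges, alpha) {
  best <- matrix(Inf, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  diag(best) <- 0
  adj <- split(seq_len(nrow(edges)), edges$from)
  recurse <- function(start, current, visited, acc) {
    for (e in adj[[current]]) {
      nxt <- edges$to[e]
      if (nxt %in% visited) next
      c2 <- acc + (1 / edges$weight[e])^alpha
      if (c2 < best[start, nxt]) best[start, nxt] <<- c2
      recurse(start, nxt, c(visited, nxt), c2)
    }
  }
  for (s in nodes) recurse(s, s, s, 0)
  best
}

brute_force_closeness <- function(nodes, edges, alpha) {
  d <- brute_force_distances(nodes, edges, alpha)
  vapply(nodes, function(i) {
    di <- d[i, setdiff(nodes, i)]
    di <- di[is.finite(di)]
    if (length(di) == 0 || sum(di) == 0) 0 else 1 / sum(di)
  }, numeric(1))
}

# breadth-first hop-count closeness (the alpha = 0 limit), no weights touched
bfs_closeness <- function(nodes, edges) {
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  adj <- split(edges$to, edges$from)
  vapply(nodes, function(s) {
    dist_sum <- 0; n_reached <- 0
    seen <- s; frontier <- s; d <- 0
    repeat {
      d <- d + 1
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      if (length(nxt) == 0) break
      dist_sum <- dist_sum + d * length(nxt)
      n_reached <- n_reached + length(nxt)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (n_reached == 0) 0 else 1 / dist_sum
  }, numeric(1))
}

# textbook Floyd-Warshall on a cost matrix (the alpha = 1 limit uses 1/w)
floyd_warshall <- function(cost) {
  n <- nrow(cost)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        cand <- cost[i, k] + cost[k, j]
        if (cand < cost[i, j]) cost[i, j] <- cand
      }
    }
  }
  cost
}

random_digraph <- function(n_nodes, p_edge = 0.4, allow_loops = FALSE) {
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  if (!allow_loops) pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p_edge
  edges <- pairs[keep, , drop = FALSE]
  edges$weight <- rlnorm(nrow(edges), meanlog = 0, sdlog = 1.5)
  list(nodes = nodes, edges = edges)
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                vertices = data.frame(name = g$nodes))
}
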