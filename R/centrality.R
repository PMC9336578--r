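#' Configuration for centrality computations
#'
#' Houses the tuning parameter \eqn{\alpha} of the generalized closeness
#' centrality together with the direction convention and the policy for
#' unreachable node pairs on a directed, typically non-strongly-connected,
#' funding network.
#'
#' @param alpha Non-negative tuning parameter balancing tie count against tie
#'   intensity: each hop on a path costs \eqn{(1/w)^\alpha}, so
#'   \eqn{\alpha = 0} reduces to binary hop counting and \eqn{\alpha = 1} to
#'   classic weighted distance on costs \eqn{1/w}. Default 0.5.
#' @param direction `"out"` (default; how quickly a node reaches the rest of
#'   the network along the money flow), `"in"`, or `"undirected"`.
#' @param unreachable_policy `"reachable_only"` (default): sum distances over
#'   the targets a node actually reaches; `"zero_if_any_unreachable"`: the
#'   literal reciprocal-of-total-distance reading, under which any
#'   unreachable target makes the sum infinite and the closeness 0.
#' @return An object of class `dah_metric_config`.
#' @export
metric_config <- function(alpha = 0.5,
                          direction = c("out", "in", "undirected"),
                          unreachable_policy = c("reachable_only",
                                                 "zero_if_any_unreachable")) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha < 0) {
    abort("`alpha` must be a single finite non-negative number.")
  }
  structure(
    list(alpha = alpha, direction = match.arg(direction),
         unreachable_policy = match.arg(unreachable_policy)),
    class = "dah_metric_config"
  )
}

#' @export
print.dah_metric_config <- function(x, ...) {
  cat(sprintf("<dah_metric_config> alpha = %g, direction = %s, unreachable = %s\n",
              x$alpha, x$direction, x$unreachable_policy))
  invisible(x)
}

#' Out-degree and in-degree
#'
#' Number of distinct successors (out) or predecessors (in) of each node.
#' On the source-to-channel projection, a source's out-degree is the number
#' of channels it funds directly; on the channel-to-recipient projection, a
#' country's in-degree is the number of channels disbursing to it. Degrees
#' are weight-blind; self-loops are excluded.
#'
#' @param network An igraph object.
#' @return A named integer vector over all nodes.
#' @export
out_degree <- function(network) {
  deg <- igraph::degree(network, mode = "out", loops = FALSE)
  setNames(as.integer(deg), names(deg))
}

#' @rdname out_degree
#' @export
in_degree <- function(network) {
  deg <- igraph::degree(network, mode = "in", loops = FALSE)
  setNames(as.integer(deg), names(deg))
}

#' Degree centrality of channels across both bipartite projections
#'
#' Counts all edges incident to a channel in the two bipartite graphs of the
#' same year: the number of distinct sources funding it plus the number of
#' distinct recipient countries it funds. Channels present in neither graph
#' are omitted.
#'
#' @param bipartite_sc Source-to-channel graph from [build_bipartite()].
#' @param bipartite_cr Channel-to-recipient graph for the same year.
#' @return A named integer vector over channels.
#' @export
channel_degree_centrality <- function(bipartite_sc, bipartite_cr) {
  in_sc <- in_degree(bipartite_sc)
  out_cr <- out_degree(bipartite_cr)
  # channels are the funded side of one graph and the funding side of the other
  ch_sc <- names(in_sc)[in_sc > 0]
  ch_cr <- names(out_cr)[out_cr > 0]
  channels <- union(ch_sc, ch_cr)
  val <- setNames(integer(length(channels)), channels)
  val[ch_sc] <- val[ch_sc] + in_sc[ch_sc]
  val[ch_cr] <- val[ch_cr] + out_cr[ch_cr]
  val
}

# per-hop costs of the alpha transform; self-loops get +Inf cost so they can
# never lie on a shortest path
alpha_costs <- function(network, alpha) {
  if (igraph::ecount(network) == 0) return(numeric(0))
  w <- igraph::E(network)$weight
  if (is.null(w)) abort("network has no edge weights")
  if (any(w <= 0)) abort("all edge weights must be strictly positive")
  cost <- (1 / w)^alpha
  cost[igraph::which_loop(network)] <- Inf
  cost
}

#' Generalized shortest distances from one node
#'
#' The distance \eqn{d^{w\alpha}(i, j)} is the minimum over directed paths
#' from `i` to `j` of the summed hop costs \eqn{(1/w_{hop})^\alpha}: with
#' \eqn{\alpha = 0} every hop costs 1 and the distance is the hop count; with
#' \eqn{\alpha = 1} it is the classic weighted distance on costs
#' \eqn{1/w}; intermediate \eqn{\alpha} trades the number of ties against
#' their intensity, so a heavier two-hop route can beat a weak direct tie.
#' Computed by Dijkstra's algorithm (all costs are positive).
#'
#' @param network An igraph object with positive edge weights.
#' @param from Node name (or index) to measure from.
#' @param config A [metric_config()]; `direction` selects outgoing (default),
#'   incoming or undirected paths.
#' @return A named numeric vector of distances to the reachable nodes only
#'   (unreachable targets are absent); `d(i, i) = 0` is included.
#' @export
shortest_distance_alpha <- function(network, from, config = metric_config()) {
  d <- igraph::distances(
    network, v = from, mode = ig_mode(config$direction),
    weights = alpha_costs(network, config$alpha), algorithm = "dijkstra"
  )[1, ]
  d[is.finite(d)]
}

ig_mode <- function(direction) {
  switch(direction, out = "out", `in` = "in", undirected = "all")
}

#' Generalized closeness centrality
#'
#' For each node \eqn{i}, the reciprocal of its summed generalized shortest
#' distances \eqn{[\sum_j d^{w\alpha}(i, j)]^{-1}}, with
#' \eqn{\alpha} (default 0.5) balancing the number of ties against the
#' amounts flowing over them. High closeness marks an actor that is deeply
#' embedded: connected to much of the network through few, heavy funding
#' ties.
#'
#' On a sparse directed aid network most node pairs are mutually
#' unreachable; under the default `reachable_only` policy the sum runs over
#' the targets \eqn{j \ne i} that `i` actually reaches, and a node reaching
#' no others (e.g. a pure recipient, measured in the outgoing direction)
#' scores 0. Under `zero_if_any_unreachable` the sum is infinite — and the
#' closeness 0 — as soon as any target is unreachable.
#'
#' @inheritParams shortest_distance_alpha
#' @param network An igraph object with positive edge weights.
#' @return A named numeric vector over all nodes (no normalization by
#'   \eqn{N - 1}).
#' @export
generalized_closeness <- function(network, config = metric_config()) {
  n <- igraph::vcount(network)
  nodes <- igraph::V(network)$name
  if (n == 0) return(setNames(numeric(0), character(0)))
  d <- igraph::distances(
    network, mode = ig_mode(config$direction),
    weights = alpha_costs(network, config$alpha), algorithm = "dijkstra"
  )
  diag(d) <- NA  # self-distances never enter the sum
  value <- vapply(seq_len(n), function(i) {
    di <- d[i, ]
    di <- di[!is.na(di)]
    if (config$unreachable_policy == "reachable_only") di <- di[is.finite(di)]
    if (length(di) == 0 || any(!is.finite(di))) return(0)
    s <- sum(di)
    if (s == 0) 0 else 1 / s
  }, numeric(1))
  setNames(value, nodes)
}

#' Rank actors by a metric
#'
#' Ordinal ranks 1..k by descending value; ties are broken lexicographically
#' by actor id so rankings are fully deterministic and invariant to input
#' order.
#'
#' @param values Named numeric vector (names = actor ids).
#' @param year Calendar year for the output rows.
#' @param metric_name Label for the metric column.
#' @return A tibble with columns `year, actor_id, metric, value, rank`,
#'   ordered by rank.
#' @export
rank_actors <- function(values, year, metric_name) {
  if (length(values) == 0) {
    abort("`values` must be non-empty")
  }
  ord <- order(-values, names(values), method = "radix")
  tibble::tibble(
    year = as.integer(year),
    actor_id = names(values)[ord],
    metric = metric_name,
    value = unname(values[ord]),
    rank = seq_along(values)
  )
}

#' Average closeness centrality by actor type
#'
#' Arithmetic mean of closeness values over the actors of each typology
#' category present in the year; categories with no active actor yield no
#' row.
#'
#' @param closeness Named numeric vector from [generalized_closeness()].
#' @param registry Registry tibble resolving every actor to a category.
#' @param year Calendar year for the output rows.
#' @param policy `"permissive"` (unresolvable actors grouped as `UNKNOWN`)
#'   or `"strict"` (unresolvable actors are an error).
#' @return A tibble with columns `year, category, mean_closeness, n_actors`.
#' @export
average_closeness_by_type <- function(closeness, registry, year,
                                      policy = c("permissive", "strict")) {
  policy <- match.arg(policy)
  m <- match(names(closeness), registry$actor_id)
  if (any(is.na(m)) && policy == "strict") {
    abort(sprintf("actor(s) missing from registry: %s",
                  paste(head(names(closeness)[is.na(m)], 5), collapse = ", ")))
  }
  cat <- ifelse(is.na(m), "UNKNOWN", registry$category[m])
  tibble::tibble(year = as.integer(year), category = cat,
                 value = unname(closeness)) |>
    dplyr::group_by(.data$year, .data$category) |>
    dplyr::summarise(mean_closeness = mean(.data$value),
                     n_actors = dplyr::n(), .groups = "drop")
}

#' Centrality table for a series of annual networks
#'
#' Convenience wrapper computing, per year, the ranked out-degree, in-degree
#' and generalized closeness on the unimodal graph, stacked in long format.
#'
#' @param series Named list of unimodal graphs from [graph_series()].
#' @param config A [metric_config()].
#' @return A tibble `year, actor_id, metric, value, rank`.
#' @export
centrality_table <- function(series, config = metric_config()) {
  rows <- lapply(names(series), function(yr) {
    g <- series[[yr]]
    if (igraph::vcount(g) == 0) return(NULL)
    dplyr::bind_rows(
      rank_actors(out_degree(g), yr, "out_degree"),
      rank_actors(in_degree(g), yr, "in_degree"),
      rank_actors(generalized_closeness(g, config), yr, "closeness")
    )
  })
  dplyr::bind_rows(rows)
}
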