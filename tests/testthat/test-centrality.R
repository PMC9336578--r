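graph_from_edges <- function(...) {
  igraph::graph_from_data_frame(data.frame(...), directed = TRUE)
}

test_that("degrees count distinct partners, blind to weights and loops", {
  g <- graph_from_edges(from = c("A", "A"), to = c("B", "C"), weight = c(1, 1))
  expect_identical(out_degree(g)[["A"]], 2L)
  expect_identical(in_degree(g)[["B"]], 1L)
  expect_identical(out_degree(g)[["B"]], 0L)

  heavy <- graph_from_edges(from = c("A", "A"), to = c("B", "C"),
                            weight = c(100, 1))
  expect_identical(out_degree(heavy), out_degree(g))

  loopy <- graph_from_edges(from = c("A", "A"), to = c("A", "B"),
                            weight = c(5, 1))
  expect_identical(out_degree(loopy)[["A"]], 1L)
  expect_identical(in_degree(loopy)[["A"]], 0L)
})

test_that("handshake identity holds on random digraphs", {
  set.seed(10)
  for (i in 1:20) {
    g <- random_digraph(sample(3:10, 1), runif(1, 0.2, 0.7))
    if (nrow(g$edges) == 0) next
    ig <- as_igraph(g)
    expect_identical(sum(out_degree(ig)), sum(in_degree(ig)))
    expect_identical(sum(out_degree(ig)), as.integer(igraph::ecount(ig)))
  }
})

test_that("channel degree centrality spans both bipartite projections", {
  flows <- tibble::tibble(
    year = 2000L,
    source_id = c("S1", "S2", "S1", "S1", "S1"),
    channel_id = "B",
    recipient_id = c("R1", "R1", "R1", "R2", "R3"),
    health_area = "malaria", amount_usd = 1
  )
  sc <- build_bipartite(flows, 2000, "source_channel")
  cr <- build_bipartite(flows, 2000, "channel_recipient")
  cd <- channel_degree_centrality(sc, cr)
  expect_identical(cd[["B"]], 5L)  # 2 sources + 3 recipients

  # a channel with sources only has centrality equal to its in-degree
  src_only <- flows[1:2, ]
  sc2 <- build_bipartite(src_only, 2000, "source_channel")
  cr2 <- build_bipartite(src_only[0, ], 2000, "channel_recipient")
  cd2 <- channel_degree_centrality(sc2, cr2)
  expect_identical(cd2[["B"]], in_degree(sc2)[["B"]])
})

test_that("channel degree equals total degree in the merged tripartite graph", {
  set.seed(21)
  flows <- random_flow_table(300)
  for (yr in unique(flows$year)) {
    sc <- build_bipartite(flows, yr, "source_channel")
    cr <- build_bipartite(flows, yr, "channel_recipient")
    cd <- channel_degree_centrality(sc, cr)
    # independent recount on the merged two-hop edge list
    sub <- flows[flows$year == yr, ]
    merged <- unique(rbind(
      data.frame(from = sub$source_id, to = sub$channel_id),
      data.frame(from = sub$channel_id, to = sub$recipient_id)
    ))
    for (ch in names(cd)) {
      expect_identical(cd[[ch]],
                       sum(merged$to == ch) + sum(merged$from == ch))
    }
  }
})

test_that("alpha-transformed distances match hand computations", {
  cfg <- metric_config(alpha = 0.5)
  path_g <- graph_from_edges(from = c("A", "B"), to = c("B", "C"),
                             weight = c(4, 4))
  d <- shortest_distance_alpha(path_g, "A", cfg)
  expect_equal(d[["C"]], 1.0)  # (1/4)^0.5 + (1/4)^0.5
  expect_equal(d[["A"]], 0)

  # binary limit: every hop costs one
  d0 <- shortest_distance_alpha(path_g, "A", metric_config(alpha = 0))
  expect_equal(d0[["C"]], 2)

  # a heavier two-hop route beats a weak direct tie
  tri <- graph_from_edges(from = c("A", "A", "B"), to = c("C", "B", "C"),
                          weight = c(1, 9, 9))
  expect_equal(shortest_distance_alpha(tri, "A", cfg)[["C"]], 2 / 3)

  # unreachable targets are absent from the mapping
  expect_named(shortest_distance_alpha(path_g, "C", cfg), "C")
  expect_error(
    shortest_distance_alpha(
      graph_from_edges(from = "A", to = "B", weight = 0), "A", cfg),
    "positive"
  )
})

test_that("closeness matches hand computations and degenerate cases", {
  chain <- graph_from_edges(from = c("A", "B"), to = c("B", "C"),
                            weight = c(1, 1))
  for (alpha in c(0, 0.5, 1)) {
    cc <- generalized_closeness(chain, metric_config(alpha = alpha))
    expect_equal(cc[["A"]], 1 / 3)  # d(A,B) + d(A,C) = 1 + 2
    expect_equal(cc[["C"]], 0)      # a sink reaches no one
  }
  single <- igraph::make_empty_graph(1, directed = TRUE)
  igraph::V(single)$name <- "A"
  expect_equal(generalized_closeness(single)[["A"]], 0)
})

test_that("uniform weights scale closeness by c^alpha", {
  set.seed(33)
  for (i in 1:10) {
    g <- random_digraph(sample(3:7, 1), 0.5)
    if (nrow(g$edges) == 0) next
    g$edges$weight <- 1
    base <- generalized_closeness(as_igraph(g), metric_config(alpha = 0.5))
    for (const in c(4, 0.25)) {
      g2 <- g
      g2$edges$weight <- const
      scaled <- generalized_closeness(as_igraph(g2),
                                      metric_config(alpha = 0.5))
      expect_equal(scaled, base * const^0.5)
    }
  }
})

test_that("closeness agrees with the exhaustive-path oracle", {
  set.seed(101)
  for (i in 1:60) {
    g <- random_digraph(sample(2:7, 1), runif(1, 0.2, 0.6))
    if (nrow(g$edges) == 0) next
    ig <- as_igraph(g)
    for (alpha in c(0, 0.5, 1, 2)) {
      mine <- generalized_closeness(ig, metric_config(alpha = alpha))
      oracle <- brute_force_closeness(g$nodes, g$edges, alpha)
      expect_equal(unname(mine[g$nodes]), unname(oracle), tolerance = 1e-12)
    }
  }
})

test_that("adding an edge never increases distances within a reachable set", {
  set.seed(55)
  cfg <- metric_config(alpha = 0.5)
  for (i in 1:10) {
    g <- random_digraph(6, 0.4)
    if (nrow(g$edges) < 2) next
    ig <- as_igraph(g)
    d_before <- igraph::distances(ig, mode = "out",
                                  weights = (1 / igraph::E(ig)$weight)^0.5)
    # add one new edge
    missing <- expand.grid(from = g$nodes, to = g$nodes,
                           stringsAsFactors = FALSE)
    missing <- missing[missing$from != missing$to, ]
    key <- paste(missing$from, missing$to)
    have <- paste(g$edges$from, g$edges$to)
    missing <- missing[!key %in% have, ]
    if (nrow(missing) == 0) next
    new_edge <- missing[sample(nrow(missing), 1), ]
    g$edges <- rbind(g$edges, cbind(new_edge, weight = rlnorm(1)))
    ig2 <- as_igraph(g)
    d_after <- igraph::distances(ig2, mode = "out",
                                 weights = (1 / igraph::E(ig2)$weight)^0.5)
    expect_true(all(d_after[g$nodes, g$nodes] <=
                      d_before[g$nodes, g$nodes] + 1e-12))
  }
})

test_that("zero_if_any_unreachable reproduces the literal formula", {
  chain <- graph_from_edges(from = c("A", "B"), to = c("B", "C"),
                            weight = c(1, 1))
  literal <- generalized_closeness(
    chain, metric_config(unreachable_policy = "zero_if_any_unreachable"))
  expect_equal(unname(literal), c(1 / 3, 0, 0))  # only A reaches everyone
  # direction convention: incoming distances invert the roles
  incoming <- generalized_closeness(chain, metric_config(direction = "in"))
  expect_equal(incoming[["C"]], 1 / 3)
  expect_equal(incoming[["A"]], 0)
})

test_that("rankings are deterministic with lexicographic tie-breaks", {
  ranked <- rank_actors(c(A = 3, B = 3, C = 1), 2000, "out_degree")
  expect_identical(ranked$actor_id, c("A", "B", "C"))
  expect_identical(ranked$rank, 1:3)

  one <- rank_actors(c(Z = 0.5), 2000, "closeness")
  expect_identical(one$rank, 1L)

  set.seed(8)
  vals <- setNames(sample(c(1, 2, 2, 3, 5)), c("e", "d", "c", "b", "a"))
  shuffled <- vals[sample(length(vals))]
  expect_identical(rank_actors(vals, 2000, "m"),
                   rank_actors(shuffled, 2000, "m"))
  expect_error(rank_actors(setNames(numeric(0), character(0)), 2000, "m"),
               "non-empty")
})

test_that("average closeness by type aggregates correctly", {
  reg <- tiny_registry()
  cc <- c(A = 0.1, B = 0.2, C = 0.3, R1 = 0, R2 = 0.4)
  out <- average_closeness_by_type(cc, reg, 2000)
  expect_equal(out$mean_closeness[out$category == "CSO"], 0.2)
  expect_equal(out$mean_closeness[out$category == "PUBLIC"], mean(c(0.1, 0, 0.4)))
  expect_false("PRIVATE" %in% out$category)
  # grand mean equals the size-weighted mean of category means
  expect_equal(weighted.mean(out$mean_closeness, out$n_actors), mean(cc))
  expect_error(
    average_closeness_by_type(c(ghost = 1), reg, 2000, policy = "strict"),
    "ghost"
  )
})
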