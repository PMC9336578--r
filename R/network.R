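#' Build a one-year bipartite funding network
#'
#' Projects one year of cleaned flow records onto a directed weighted
#' bipartite graph: either sources to channels (`"source_channel"`) or
#' channels to recipient countries (`"channel_recipient"`). Parallel flows —
#' over health areas and duplicate actor pairs — are summed into a single
#' edge, so the graph is simple and its total edge weight equals the summed
#' amounts of that year's records. Edge direction follows the money, donor
#' to recipient of funds.
#'
#' @param flows Cleaned flow-record tibble (no unspecified endpoints).
#' @param year Calendar year to project.
#' @param mode `"source_channel"` or `"channel_recipient"`.
#' @param registry Optional registry tibble; when supplied, node `category`
#'   and `subgroup` attributes are attached.
#' @param health_area Optional label: restrict to records of one health area
#'   before projecting.
#' @return An igraph object with graph attributes `year` and `projection`,
#'   a `mode` vertex attribute (`"source"`/`"channel"`/`"recipient"`), and a
#'   `weight` edge attribute. A year with no records yields an empty graph.
#' @export
build_bipartite <- function(flows, year,
                            mode = c("source_channel", "channel_recipient"),
                            registry = NULL, health_area = NULL) {
  mode <- match.arg(mode)
  cols <- if (mode == "source_channel") {
    c(from = "source_id", to = "channel_id")
  } else {
    c(from = "channel_id", to = "recipient_id")
  }
  sub <- flows[flows$year == year, , drop = FALSE]
  if (!is.null(health_area)) {
    sub <- sub[sub$health_area == health_area, , drop = FALSE]
  }
  edges <- aggregate_flows(sub, c("year", unname(cols)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[[cols[["from"]]]], to = edges[[cols[["to"]]]],
               weight = edges$amount_usd),
    directed = TRUE
  )
  modes <- c(source_channel = "source", channel_recipient = "channel")
  tail_mode <- modes[[mode]]
  head_mode <- if (mode == "source_channel") "channel" else "recipient"
  igraph::V(g)$mode <- ifelse(
    igraph::V(g)$name %in% edges[[cols[["from"]]]], tail_mode, head_mode
  )
  g <- annotate_graph(g, year, paste0("bipartite_", mode), registry)
  g
}

#' Build a one-year unimodal all-actors network
#'
#' Projects one year of cleaned flows onto a single-node-type directed
#' weighted graph of global health actors. Each record deposits its amount on
#' both of its hops — source to channel and channel to recipient — and
#' parallel contributions are summed, so the total edge weight is exactly
#' twice the summed record amounts. An actor occupying several roles (e.g.
#' source and channel, or a recipient country that also donates) is a single
#' node; a per-node `roles` attribute records the functions it performs that
#' year. Self-loops (an actor funding itself) are retained as data but are
#' ignored by all metrics.
#'
#' @inheritParams build_bipartite
#' @return An igraph object as for [build_bipartite()], with a `roles` vertex
#'   attribute (comma-separated subset of `source,channel,recipient`).
#' @export
build_unimodal <- function(flows, year, registry = NULL, health_area = NULL) {
  sub <- flows[flows$year == year, , drop = FALSE]
  if (!is.null(health_area)) {
    sub <- sub[sub$health_area == health_area, , drop = FALSE]
  }
  hops <- dplyr::bind_rows(
    tibble::tibble(year = sub$year, from = sub$source_id,
                   to = sub$channel_id, amount_usd = sub$amount_usd),
    tibble::tibble(year = sub$year, from = sub$channel_id,
                   to = sub$recipient_id, amount_usd = sub$amount_usd)
  )
  edges <- hops |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(weight = sum(.data$amount_usd), .groups = "drop")
  edges <- edges[edges$weight > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = TRUE)

  roles <- lapply(setNames(igraph::V(g)$name, igraph::V(g)$name),
                  function(id) character(0))
  add_role <- function(ids, role) {
    for (id in unique(ids)) roles[[id]] <<- union(roles[[id]], role)
  }
  add_role(sub$source_id, "source")
  add_role(sub$channel_id, "channel")
  add_role(sub$recipient_id, "recipient")
  igraph::V(g)$roles <- vapply(roles[igraph::V(g)$name], paste,
                               character(1), collapse = ",")
  annotate_graph(g, year, "unimodal", registry)
}

annotate_graph <- function(g, year, projection, registry) {
  g <- igraph::set_graph_attr(g, "year", as.integer(year))
  g <- igraph::set_graph_attr(g, "projection", projection)
  if (!is.null(registry) && igraph::vcount(g) > 0) {
    m <- match(igraph::V(g)$name, registry$actor_id)
    igraph::V(g)$category <- ifelse(is.na(m), "UNKNOWN", registry$category[m])
    igraph::V(g)$subgroup <- ifelse(is.na(m), "UNKNOWN", registry$subgroup[m])
  }
  g
}

#' Build the annual series of networks
#'
#' One graph per requested year; years with no records yield empty graphs.
#'
#' @param flows Cleaned flow-record tibble.
#' @param years Years to build (default: the range present in `flows`).
#' @param projection `"unimodal"` (default), `"source_channel"` or
#'   `"channel_recipient"`.
#' @inheritParams build_bipartite
#' @return A named list (names = years) of igraph objects.
#' @export
graph_series <- function(flows, years = NULL,
                         projection = c("unimodal", "source_channel",
                                        "channel_recipient"),
                         registry = NULL) {
  projection <- match.arg(projection)
  if (is.null(years)) {
    if (nrow(flows) == 0) return(list())
    years <- seq(min(flows$year), max(flows$year))
  }
  build <- function(y) {
    if (projection == "unimodal") {
      build_unimodal(flows, y, registry = registry)
    } else {
      build_bipartite(flows, y, mode = projection, registry = registry)
    }
  }
  setNames(lapply(years, build), as.character(years))
}

#' Export a network to a standard graph format
#'
#' Writes GraphML (via igraph), GEXF 1.2, or the edge-list CSV dialect
#' `year,from,to,weight_usd`. Node attributes (`category`, `roles`, `mode`)
#' and edge weights round-trip losslessly at full double precision through
#' [import_graph()].
#'
#' @param network An igraph object from the builders above.
#' @param path Output file path.
#' @param format `"graphml"`, `"gexf"` or `"edgelist"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(network, path,
                         format = c("graphml", "gexf", "edgelist")) {
  format <- match.arg(format)
  switch(format,
    graphml = igraph::write_graph(network, path, format = "graphml"),
    gexf = write_gexf(network, path),
    edgelist = {
      el <- igraph::as_data_frame(network, what = "edges")
      year <- igraph::graph_attr(network, "year") %||% NA_integer_
      out <- data.frame(year = rep(year, nrow(el)), from = el$from,
                        to = el$to, weight_usd = el$weight)
      out$weight_usd <- format(out$weight_usd, digits = 17, trim = TRUE,
                               scientific = FALSE)
      write.csv(out, path, row.names = FALSE, quote = FALSE)
    }
  )
  invisible(path)
}

#' Import a network written by [export_graph()]
#'
#' @param path File path.
#' @param format `"graphml"`, `"gexf"` or `"edgelist"`.
#' @return An igraph object.
#' @export
import_graph <- function(path, format = c("graphml", "gexf", "edgelist")) {
  format <- match.arg(format)
  switch(format,
    graphml = igraph::read_graph(path, format = "graphml"),
    gexf = read_gexf(path),
    edgelist = {
      df <- read.csv(path, colClasses = c("integer", "character",
                                          "character", "numeric"))
      g <- igraph::graph_from_data_frame(
        data.frame(from = df$from, to = df$to, weight = df$weight_usd),
        directed = TRUE
      )
      if (nrow(df) > 0) {
        g <- igraph::set_graph_attr(g, "year", df$year[1])
      }
      g
    }
  )
}

num17 <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)

# GEXF 1.2 writer: directed weighted graph with string node attributes
write_gexf <- function(network, path) {
  doc <- xml2::xml_new_root(
    "gexf",
    xmlns = "http://www.gexf.net/1.2draft",
    version = "1.2"
  )
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed",
                               mode = "static")
  vattrs <- setdiff(igraph::vertex_attr_names(network), "name")
  if (length(vattrs) > 0) {
    attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
    for (i in seq_along(vattrs)) {
      xml2::xml_add_child(attrs, "attribute", id = as.character(i - 1),
                          title = vattrs[i], type = "string")
    }
  }
  nodes <- xml2::xml_add_child(graph, "nodes")
  vnames <- igraph::V(network)$name
  for (v in seq_along(vnames)) {
    node <- xml2::xml_add_child(nodes, "node", id = vnames[v],
                                label = vnames[v])
    if (length(vattrs) > 0) {
      av <- xml2::xml_add_child(node, "attvalues")
      for (i in seq_along(vattrs)) {
        val <- igraph::vertex_attr(network, vattrs[i], v)
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1),
                            value = as.character(val))
      }
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  el <- igraph::as_data_frame(network, what = "edges")
  for (e in seq_len(nrow(el))) {
    xml2::xml_add_child(edges, "edge", id = as.character(e - 1),
                        source = el$from[e], target = el$to[e],
                        weight = num17(el$weight[e]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  node_xml <- xml2::xml_find_all(doc, ".//nodes/node")
  ids <- xml2::xml_attr(node_xml, "id")
  attr_defs <- xml2::xml_find_all(doc, ".//attributes[@class='node']/attribute")
  attr_titles <- setNames(xml2::xml_attr(attr_defs, "title"),
                          xml2::xml_attr(attr_defs, "id"))
  edge_xml <- xml2::xml_find_all(doc, ".//edges/edge")
  el <- data.frame(
    from = xml2::xml_attr(edge_xml, "source"),
    to = xml2::xml_attr(edge_xml, "target"),
    weight = as.numeric(xml2::xml_attr(edge_xml, "weight"))
  )
  g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                     vertices = data.frame(name = ids))
  for (aid in names(attr_titles)) {
    vals <- vapply(node_xml, function(n) {
      v <- xml2::xml_find_first(n, sprintf(".//attvalue[@for='%s']", aid))
      xml2::xml_attr(v, "value")
    }, character(1))
    g <- igraph::set_vertex_attr(g, attr_titles[[aid]],
                                 index = match(ids, igraph::V(g)$name),
                                 value = vals)
  }
  g
}
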