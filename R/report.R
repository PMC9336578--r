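#' Annual disbursement totals
#'
#' Sums amounts per year, counting each record once (on its
#' source-to-channel hop).
#'
#' @param flows Flow-record tibble.
#' @return A tibble `year, total_usd`; empty input yields an empty table.
#' @export
annual_totals <- function(flows) {
  out <- aggregate_flows(flows, "year")
  tibble::tibble(year = out$year, total_usd = out$amount_usd)
}

#' Node and edge counts of an annual network series
#'
#' @param series Named list of graphs from [graph_series()].
#' @return A tibble `year, n_nodes, n_edges`.
#' @export
node_edge_counts <- function(series) {
  tibble::tibble(
    year = as.integer(names(series)),
    n_nodes = unname(vapply(series, igraph::vcount, numeric(1))),
    n_edges = unname(vapply(series, igraph::ecount, numeric(1)))
  )
}

#' Proportional distribution of DAH by actor category
#'
#' Per year, the share of total disbursements attributed to each typology
#' category in the given role. Each record is counted exactly once: in the
#' `source` role it is attributed to its source's category (the
#' source-to-channel hop), in the `channel` role to its channel's category
#' (the channel-to-recipient hop), so the two role views never double-count
#' and each sums to 1 per year.
#'
#' @param flows Cleaned flow-record tibble.
#' @param registry Registry tibble resolving the role's actor ids.
#' @param role `"source"` or `"channel"`.
#' @param policy `"permissive"` (unresolved ids share an `UNKNOWN` row) or
#'   `"strict"` (unresolved ids are an error).
#' @return A tibble `year, category, share`, shares summing to 1 per year.
#' @export
proportional_distribution <- function(flows, registry,
                                      role = c("source", "channel"),
                                      policy = c("permissive", "strict")) {
  role <- match.arg(role)
  policy <- match.arg(policy)
  id_col <- paste0(role, "_id")
  m <- match(flows[[id_col]], registry$actor_id)
  if (any(is.na(m))) {
    if (policy == "strict") {
      abort(sprintf("unresolved %s id(s): %s", role,
                    paste(head(unique(flows[[id_col]][is.na(m)]), 5),
                          collapse = ", ")))
    }
    warn(sprintf("%d %s id(s) not in registry; attributed to UNKNOWN",
                 length(unique(flows[[id_col]][is.na(m)])), role))
  }
  tibble::tibble(
    year = flows$year,
    category = ifelse(is.na(m), "UNKNOWN", registry$category[m]),
    amount_usd = flows$amount_usd
  ) |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(year_total = sum(.data$amount_usd)) |>
    dplyr::group_by(.data$year, .data$category) |>
    dplyr::summarise(share = sum(.data$amount_usd) / .data$year_total[1],
                     .groups = "drop")
}

#' Share of CSO channels funding a single health area
#'
#' Among actors of category CSO that ever act as a channel over the pooling
#' window (default: all years in `flows`), the count and fraction whose
#' channel records carry exactly one distinct health area. Cause-specific
#' CSOs of this kind are a marked feature of the aid landscape,
#' concentrated on causes such as HIV/AIDS, malaria, and child and maternal
#' health.
#'
#' @param flows Cleaned flow-record tibble.
#' @param registry Registry tibble.
#' @param years Optional year subset defining the pooling window.
#' @return A list with `n_cso_channels`, `n_single_area`, and `fraction`
#'   (`NA` with a warning when no CSO acts as channel).
#' @export
single_health_area_share <- function(flows, registry, years = NULL) {
  if (!is.null(years)) flows <- flows[flows$year %in% years, , drop = FALSE]
  cso_ids <- registry$actor_id[registry$category == "CSO"]
  ch <- flows[flows$channel_id %in% cso_ids, , drop = FALSE]
  if (nrow(ch) == 0) {
    warn("no CSO channels in the pooling window")
    return(list(n_cso_channels = 0L, n_single_area = 0L, fraction = NA_real_))
  }
  areas_per_channel <- ch |>
    dplyr::distinct(.data$channel_id, .data$health_area) |>
    dplyr::count(.data$channel_id)
  n_single <- sum(areas_per_channel$n == 1)
  list(
    n_cso_channels = nrow(areas_per_channel),
    n_single_area = as.integer(n_single),
    fraction = n_single / nrow(areas_per_channel)
  )
}

#' Top-ranked actors for one year and metric
#'
#' First `n` actors by rank, optionally restricted to one typology category
#' (e.g. the leading CSOs by closeness). When filtering, the unfiltered rank
#' is kept alongside as `rank_all_actors`.
#'
#' @param centrality A tibble from [centrality_table()] / [rank_actors()].
#' @param year Calendar year.
#' @param metric Metric name.
#' @param n Number of actors to keep (whole table if fewer are ranked).
#' @param category Optional category filter; requires `registry`.
#' @param registry Registry tibble (needed with `category`).
#' @return A tibble of at most `n` rows ordered by rank.
#' @export
top_n_actors <- function(centrality, year, metric, n, category = NULL,
                         registry = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0) {
    abort("`n` must be a positive count")
  }
  sub <- centrality[centrality$year == year & centrality$metric == metric, ,
                    drop = FALSE]
  sub <- sub[order(sub$rank), , drop = FALSE]
  if (!is.null(category)) {
    if (is.null(registry)) abort("`registry` is required with `category`")
    m <- match(sub$actor_id, registry$actor_id)
    sub <- sub[!is.na(m) & registry$category[m] == category, , drop = FALSE]
    sub$rank_all_actors <- sub$rank
    sub$rank <- seq_len(nrow(sub))
  }
  head(sub, n)
}

#' Per-year landscape summary
#'
#' Assembles the descriptive view of the funding landscape: annual totals,
#' node and edge counts of the unimodal graph, and the category shares of
#' source and channel amounts (wide columns `source_share_*`,
#' `channel_share_*`).
#'
#' @param flows Cleaned flow-record tibble.
#' @param registry Registry tibble.
#' @return A tibble with one row per year.
#' @export
landscape_summary <- function(flows, registry) {
  totals <- annual_totals(flows)
  counts <- node_edge_counts(graph_series(flows))
  widen <- function(role) {
    proportional_distribution(flows, registry, role) |>
      tidyr::pivot_wider(names_from = "category", values_from = "share",
                         names_prefix = paste0(role, "_share_"),
                         values_fill = 0)
  }
  totals |>
    dplyr::left_join(counts, by = "year") |>
    dplyr::left_join(widen("source"), by = "year") |>
    dplyr::left_join(widen("channel"), by = "year")
}
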