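#' Run the full DAH network analysis pipeline
#'
#' Generate (or accept) a flow table, clean it, build the annual graphs,
#' compute degree and generalized-closeness metrics, and write the
#' landscape summary, centrality tables, rankings and graph exports to a
#' directory. The run is a pure function of the configuration and seed:
#' repeated runs produce byte-identical outputs (the manifest records the
#' seed and a configuration hash, never a timestamp).
#'
#' Files written to `outdir`: `flow_table.csv`, `actor_registry.csv`,
#' `config.yaml`, `landscape_summary.csv`, `centrality.csv`,
#' `avg_closeness_by_type.csv`, `rankings_<year>_<metric>.csv` for each
#' report year and metric, `top_cso_closeness.csv`,
#' `network_<year>.graphml` / `.gexf` for each report year, and
#' `manifest.json`.
#'
#' @param config A [dah_generator_config()] (default:
#'   [default_config_mdg_era()]).
#' @param outdir Output directory (created if missing).
#' @param seed Optional integer overriding the configuration's seed.
#' @param metric_cfg A [metric_config()] for the closeness computation.
#' @param report_years Years for which ranking tables and graph exports are
#'   written (default: first, middle and last year of the window).
#' @param n_top Number of actors per ranking table.
#' @param n_top_cso Number of CSOs in the closeness-ranked CSO table.
#' @return Invisibly, a list with the in-memory results (`sim`, `flows`,
#'   `series`, `centrality`, `landscape`, `single_area`, `manifest`).
#' @export
run_dah_pipeline <- function(config = default_config_mdg_era(),
                             outdir,
                             seed = NULL,
                             metric_cfg = metric_config(),
                             report_years = NULL,
                             n_top = 10,
                             n_top_cso = 25) {
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  validate_generator_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)

  sim <- generate_dah(config)
  write_flow_table(sim$flows, p("flow_table.csv"))
  write_actor_registry(sim$registry, p("actor_registry.csv"))
  write_config_yaml(config, p("config.yaml"))

  flows <- drop_unspecified(read_flow_table(p("flow_table.csv")))
  registry <- sim$registry

  series <- graph_series(flows, years = config$years, registry = registry)
  centrality <- centrality_table(series, metric_cfg)
  landscape <- landscape_summary(flows, registry)
  single_area <- single_health_area_share(flows, registry)

  by_type <- dplyr::bind_rows(lapply(names(series), function(yr) {
    g <- series[[yr]]
    if (igraph::vcount(g) == 0) return(NULL)
    average_closeness_by_type(generalized_closeness(g, metric_cfg),
                              registry, yr)
  }))

  write_csv_plain(landscape, p("landscape_summary.csv"))
  write_csv_plain(centrality, p("centrality.csv"))
  write_csv_plain(by_type, p("avg_closeness_by_type.csv"))

  if (is.null(report_years)) {
    yrs <- config$years
    report_years <- unique(c(yrs[1], yrs[ceiling(length(yrs) / 2)],
                             yrs[length(yrs)]))
  }
  for (yr in report_years) {
    for (metric in c("out_degree", "in_degree", "closeness")) {
      write_csv_plain(
        top_n_actors(centrality, yr, metric, n_top),
        p(sprintf("rankings_%d_%s.csv", yr, metric))
      )
    }
    export_graph(series[[as.character(yr)]], p(sprintf("network_%d.graphml", yr)),
                 "graphml")
    export_graph(series[[as.character(yr)]], p(sprintf("network_%d.gexf", yr)),
                 "gexf")
  }
  last_year <- max(config$years)
  write_csv_plain(
    top_n_actors(centrality, last_year, "closeness", n_top_cso,
                 category = "CSO", registry = registry),
    p("top_cso_closeness.csv")
  )

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    alpha = metric_cfg$alpha,
    direction = metric_cfg$direction,
    unreachable_policy = metric_cfg$unreachable_policy,
    n_records_generated = nrow(sim$flows),
    n_records_retained = nrow(flows),
    n_actors = nrow(registry),
    years = range(config$years),
    single_area_cso = single_area,
    package_version = as.character(utils::packageVersion("dahnet")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(sim = sim, flows = flows, series = series,
                 centrality = centrality, landscape = landscape,
                 by_type = by_type, single_area = single_area,
                 manifest = manifest, outdir = outdir))
}

# deterministic CSV writer: full precision, no quoting surprises
write_csv_plain <- function(df, path) {
  out <- as.data.frame(df)
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- format(out[[col]], digits = 17, trim = TRUE,
                           scientific = FALSE)
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
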