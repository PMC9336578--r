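#' Read a DAH flow table from CSV
#'
#' Parses the canonical flow-table dialect (header
#' `year,source_id,channel_id,recipient_id,health_area,amount_usd`, UTF-8,
#' [UNSPECIFIED] sentinel for unattributed endpoints) into a tibble of flow
#' records, preserving row order. Malformed rows — non-numeric or negative
#' amounts, non-integer years, empty identifiers — are reported with their
#' line numbers in a single parse error. Zero-amount records are retained;
#' disbursements cannot be negative.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `year, source_id, channel_id, recipient_id,
#'   health_area, amount_usd`.
#' @seealso [write_flow_table()], [drop_unspecified()]
#' @export
read_flow_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("flow table not found: %s", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  missing_cols <- setdiff(flow_table_columns, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("flow table %s is missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(
      year = integer(), source_id = character(), channel_id = character(),
      recipient_id = character(), health_area = character(),
      amount_usd = numeric()
    ))
  }
  # file line = data row + 1 for the header
  line <- seq_len(nrow(raw)) + 1L

  year <- suppressWarnings(as.numeric(raw$year))
  amount <- suppressWarnings(as.numeric(raw$amount_usd))
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad)) {
      problems <<- c(problems, sprintf(
        "%s on line(s) %s", what,
        paste(line[bad], collapse = ", ")
      ))
    }
  }
  flag(is.na(year) | year != floor(year), "non-integer year")
  flag(is.na(amount), "non-numeric amount")
  flag(!is.na(amount) & amount < 0, "negative amount")
  for (col in c("source_id", "channel_id", "recipient_id")) {
    flag(!nzchar(trimws(raw[[col]])), sprintf("empty %s", col))
  }
  if (length(problems) > 0) {
    abort(paste0("malformed flow table ", path, ":\n  ",
                 paste(problems, collapse = "\n  ")))
  }

  tibble::tibble(
    year = as.integer(year),
    source_id = raw$source_id,
    channel_id = raw$channel_id,
    recipient_id = raw$recipient_id,
    health_area = raw$health_area,
    amount_usd = amount
  )
}

#' Write a DAH flow table to CSV
#'
#' Writes the canonical dialect read back by [read_flow_table()]. Amounts are
#' written at full double precision so a write/read round trip is exact.
#'
#' @param flows Flow-record tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_flow_table <- function(flows, path) {
  out <- as.data.frame(flows)[, flow_table_columns]
  out$amount_usd <- format(out$amount_usd, digits = 17, trim = TRUE,
                           scientific = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Drop records with unspecified endpoints
#'
#' Flows whose source, channel or recipient is the [UNSPECIFIED] sentinel
#' cannot be attributed to an actor and are excluded from all analyses. The
#' number of dropped records is reported as a message; if every record is
#' dropped a warning is raised.
#'
#' @param flows Flow-record tibble.
#' @return The retained records, in their original order. Idempotent.
#' @export
drop_unspecified <- function(flows) {
  keep <- flows$source_id != UNSPECIFIED &
    flows$channel_id != UNSPECIFIED &
    flows$recipient_id != UNSPECIFIED
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("drop_unspecified: removed %d of %d records with an unspecified endpoint",
                   n_drop, length(keep)))
  }
  out <- flows[keep, , drop = FALSE]
  if (nrow(out) == 0 && n_drop > 0) {
    warn("drop_unspecified: all records had unspecified endpoints; returning an empty table")
  }
  out
}

#' Read an actor registry from CSV
#'
#' Expects the dialect `actor_id,name,category,subgroup,is_oecd_dac,iso3`.
#'
#' @param path Path to the registry CSV.
#' @return A registry tibble.
#' @export
read_actor_registry <- function(path) {
  if (!file.exists(path)) abort(sprintf("actor registry not found: %s", path))
  raw <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(registry_columns, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("actor registry %s is missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(raw[, registry_columns])
  out$is_oecd_dac <- as.logical(out$is_oecd_dac)
  out$iso3[!nzchar(out$iso3)] <- NA_character_
  validate_registry(out)
  out
}

#' Write an actor registry to CSV
#'
#' @param registry Registry tibble (extra columns beyond the standard six are
#'   dropped).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_actor_registry <- function(registry, path) {
  out <- as.data.frame(registry)[, registry_columns]
  out$iso3[is.na(out$iso3)] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

validate_registry <- function(registry) {
  if (anyDuplicated(registry$actor_id)) {
    abort("actor registry has duplicated actor_id values")
  }
  known <- registry$category %in% c(dah_categories, "UNKNOWN")
  if (!all(known)) {
    abort(sprintf("unknown category value(s): %s",
                  paste(unique(registry$category[!known]), collapse = ", ")))
  }
  ok <- mapply(function(cat, sub) {
    cat == "UNKNOWN" || sub %in% dah_subgroups[[cat]]
  }, registry$category, registry$subgroup)
  if (!all(ok)) {
    abort(sprintf(
      "subgroup inconsistent with category for actor(s): %s",
      paste(head(registry$actor_id[!ok], 5), collapse = ", ")
    ))
  }
  dac_bad <- registry$is_oecd_dac & registry$subgroup != "national_government"
  if (any(dac_bad)) {
    abort("is_oecd_dac is only valid for national governments")
  }
  invisible(TRUE)
}

#' Canonicalize actor identifiers
#'
#' Case-folds and collapses internal whitespace so that cosmetic variants of
#' an identifier resolve to the same actor key. A government and its
#' bilateral agency remain distinct unless the registry maps them together.
#'
#' @param ids Character vector of raw identifiers.
#' @return Canonical keys.
#' @export
canonicalize_id <- function(ids) {
  out <- tolower(trimws(ids))
  gsub("\\s+", " ", out)
}

#' Resolve actor identifiers to the typology
#'
#' Annotates every identifier with a category and subgroup. Resolution order:
#' (1) membership of the PPP list overrides everything (entities on the
#' configured partnership list are categorized as PPPs); (2) a registry entry
#' supplies category and subgroup; (3) an ISO3-shaped identifier (three
#' capital letters) is a recipient country and typed PUBLIC /
#' national_government — the typology covers organizations, and this
#' convention keeps the all-actor graph fully typed while the per-year role
#' attribute records function. Unresolvable identifiers are an error in
#' `strict` mode and are typed `UNKNOWN` with a warning in `permissive` mode.
#'
#' @param ids Character vector of actor identifiers appearing in flows.
#' @param registry Registry tibble (may be `NULL`).
#' @param ppp_list Character vector of PPP actor ids (may be empty).
#' @param policy `"permissive"` (default) or `"strict"`.
#' @return A registry tibble covering every id in `ids`.
#' @export
assign_typology <- function(ids, registry = NULL, ppp_list = character(0),
                            policy = c("permissive", "strict")) {
  policy <- match.arg(policy)
  ids <- unique(ids)
  ids <- ids[ids != UNSPECIFIED]
  out <- tibble::tibble(
    actor_id = ids,
    name = ids,
    category = NA_character_,
    subgroup = NA_character_,
    is_oecd_dac = FALSE,
    iso3 = NA_character_
  )

  if (!is.null(registry)) {
    m <- match(out$actor_id, registry$actor_id)
    hit <- !is.na(m)
    for (col in c("name", "category", "subgroup", "iso3")) {
      out[[col]][hit] <- registry[[col]][m[hit]]
    }
    out$is_oecd_dac[hit] <- registry$is_oecd_dac[m[hit]]
  }

  iso3_like <- is.na(out$category) & grepl("^[A-Z]{3}$", out$actor_id)
  out$category[iso3_like] <- "PUBLIC"
  out$subgroup[iso3_like] <- "national_government"
  out$iso3[iso3_like] <- out$actor_id[iso3_like]

  on_ppp <- out$actor_id %in% ppp_list
  out$category[on_ppp] <- "PPP"
  out$subgroup[on_ppp] <- "global_health_initiative"
  out$is_oecd_dac[on_ppp] <- FALSE

  unresolved <- is.na(out$category)
  if (any(unresolved)) {
    if (policy == "strict") {
      abort(sprintf("unresolvable actor id(s) in strict mode: %s",
                    paste(head(out$actor_id[unresolved], 10), collapse = ", ")))
    }
    warn(sprintf("%d actor id(s) could not be resolved; typed UNKNOWN",
                 sum(unresolved)))
    out$category[unresolved] <- "UNKNOWN"
    out$subgroup[unresolved] <- "UNKNOWN"
  }
  out
}

#' Aggregate flow amounts over grouping keys
#'
#' Sums `amount_usd` over records sharing the grouping keys, e.g.
#' `c("year", "source_id", "channel_id")` for edge weights or
#' `c("year")` for annual totals. The grand total is conserved exactly
#' (pairwise summation order is the column order of the input). Zero-amount
#' records contribute nothing and are dropped from the aggregate.
#'
#' @param flows Flow-record tibble.
#' @param keys Character vector of grouping column names.
#' @return A tibble with the key columns and a summed `amount_usd`.
#' @export
aggregate_flows <- function(flows, keys) {
  unknown <- setdiff(keys, setdiff(flow_table_columns, "amount_usd"))
  if (length(unknown) > 0) {
    abort(sprintf("unknown grouping key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  out <- flows |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(amount_usd = sum(.data$amount_usd), .groups = "drop")
  out[out$amount_usd > 0, , drop = FALSE]
}
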