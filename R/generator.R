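#' Configuration for the synthetic DAH flow generator
#'
#' Defines the study conditions that [generate_dah()] emulates: the calendar
#' window, how many actors of each category are active each year, how much
#' money is disbursed annually, and how that money splits across actor
#' categories on the source side and the channel side.
#'
#' Schedules are matrices with one row per year (rownames are years) and one
#' column per category (`PUBLIC`, `PRIVATE`, `CSO`, `PPP`). Share rows must
#' sum to 1. When a schedule is omitted, category shares default to being
#' proportional to the number of role-capable actors of that category active
#' in the year, which guarantees a valid (positive where needed) schedule for
#' small ad-hoc configurations.
#'
#' @param years Integer vector of consecutive calendar years (default
#'   1990:2015).
#' @param n_recipients Number of recipient countries; held constant over the
#'   whole window.
#' @param initial_actors Named integer vector: actors per category active in
#'   the first year. Used to build a flat growth schedule when
#'   `growth_schedule` is `NULL`.
#' @param growth_schedule Named list of per-category numeric vectors (names =
#'   years) giving the target number of active actors; must be non-decreasing
#'   (actors are never retired).
#' @param annual_total Named numeric vector (names = years): total disbursed
#'   amount per year in constant USD.
#' @param source_share_schedule,channel_share_schedule Year-by-category share
#'   matrices for the source side and the channel side of flows.
#' @param single_area_prob Probability that a CSO with channel capability is
#'   cause-specific, i.e. disburses for exactly one health area.
#' @param n_health_areas Number of health-area labels.
#' @param health_areas Optional character vector of area labels (defaults to
#'   the first `n_health_areas` entries of [dah_health_areas]).
#' @param unspecified_rate Fraction of records whose source or recipient is
#'   relabelled to the [UNSPECIFIED] sentinel, exercising the drop filter.
#' @param hybrid_recipient_donor_rate Fraction of recipient countries that
#'   also act as (public) sources.
#' @param records_per_year Optional named numeric vector overriding the
#'   number of flow records drawn per year.
#' @param seed Integer RNG seed; the generator is a pure function of the
#'   configuration including this seed.
#'
#' @return An object of class `dah_generator_config`.
#' @seealso [default_config_mdg_era()] for the calibrated 1990-2015 default.
#' @export
dah_generator_config <- function(years = 1990:2015,
                                 n_recipients = 40,
                                 initial_actors = c(PUBLIC = 20, PRIVATE = 4,
                                                    CSO = 6, PPP = 0),
                                 growth_schedule = NULL,
                                 annual_total = NULL,
                                 source_share_schedule = NULL,
                                 channel_share_schedule = NULL,
                                 single_area_prob = 0.33,
                                 n_health_areas = 22,
                                 health_areas = NULL,
                                 unspecified_rate = 0.02,
                                 hybrid_recipient_donor_rate = 0.1,
                                 records_per_year = NULL,
                                 seed = 1990L) {
  years <- as.integer(years)
  yr_chr <- as.character(years)

  if (is.null(growth_schedule)) {
    ia <- initial_actors[dah_categories]
    ia[is.na(ia)] <- 0
    names(ia) <- dah_categories
    growth_schedule <- lapply(ia, function(n) {
      setNames(rep(as.numeric(n), length(years)), yr_chr)
    })
  }
  if (is.null(annual_total)) {
    annual_total <- setNames(rep(1e9, length(years)), yr_chr)
  }

  config <- structure(
    list(
      years = years,
      n_recipients = as.integer(n_recipients),
      growth_schedule = growth_schedule,
      annual_total = annual_total,
      source_share_schedule = source_share_schedule,
      channel_share_schedule = channel_share_schedule,
      single_area_prob = single_area_prob,
      n_health_areas = as.integer(n_health_areas),
      health_areas = health_areas %||%
        dah_health_areas[seq_len(n_health_areas)],
      unspecified_rate = unspecified_rate,
      hybrid_recipient_donor_rate = hybrid_recipient_donor_rate,
      records_per_year = records_per_year,
      seed = as.integer(seed)
    ),
    class = "dah_generator_config"
  )
  validate_generator_config(config)
  config
}

#' Validate a generator configuration
#'
#' Checks every structural invariant of a [dah_generator_config()]: complete
#' non-decreasing growth schedules, strictly positive annual totals, share
#' rows summing to 1 within 1e-9 with entries in \[0, 1\], and probabilities
#' in \[0, 1\]. Errors name the offending field.
#'
#' @param config A `dah_generator_config`.
#' @return Invisibly `TRUE` if valid; otherwise an error.
#' @export
validate_generator_config <- function(config) {
  stopifnot(inherits(config, "dah_generator_config"))
  years <- config$years
  yr_chr <- as.character(years)

  if (length(years) < 1 || any(diff(years) != 1)) {
    abort("`years` must be a non-empty run of consecutive calendar years.")
  }
  if (is.na(config$n_recipients) || config$n_recipients < 1) {
    abort("`n_recipients` must be a positive count.")
  }
  gs <- config$growth_schedule
  if (!all(dah_categories %in% names(gs))) {
    abort("`growth_schedule` must have one entry per category (PUBLIC, PRIVATE, CSO, PPP).")
  }
  for (cat in dah_categories) {
    v <- gs[[cat]]
    if (!all(yr_chr %in% names(v))) {
      abort(sprintf("`growth_schedule` for %s must cover every year.", cat))
    }
    v <- v[yr_chr]
    if (any(v < 0) || any(v != floor(v))) {
      abort(sprintf("`growth_schedule` for %s must be non-negative integers.", cat))
    }
    if (any(diff(v) < 0)) {
      abort(sprintf("`growth_schedule` for %s must be non-decreasing (actors are never retired).", cat))
    }
  }
  at <- config$annual_total
  if (!all(yr_chr %in% names(at)) || any(at[yr_chr] <= 0)) {
    abort("`annual_total` must be strictly positive and cover every year.")
  }
  for (field in c("source_share_schedule", "channel_share_schedule")) {
    m <- config[[field]]
    if (is.null(m)) next
    if (!all(yr_chr %in% rownames(m)) || !all(dah_categories %in% colnames(m))) {
      abort(sprintf("`%s` must have one row per year and one column per category.", field))
    }
    m <- m[yr_chr, dah_categories, drop = FALSE]
    if (any(m < 0 | m > 1)) {
      abort(sprintf("`%s` entries must lie in [0, 1].", field))
    }
    if (any(abs(rowSums(m) - 1) > 1e-9)) {
      abort(sprintf("`%s` rows must sum to 1 within 1e-9.", field))
    }
  }
  for (field in c("single_area_prob", "unspecified_rate",
                  "hybrid_recipient_donor_rate")) {
    p <- config[[field]]
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      abort(sprintf("`%s` must be a probability in [0, 1].", field))
    }
  }
  if (config$n_health_areas < 1 ||
      length(config$health_areas) != config$n_health_areas) {
    abort("`n_health_areas` must match the number of health-area labels.")
  }
  if (is.na(config$seed)) abort("`seed` must be an integer.")
  invisible(TRUE)
}

#' Calibrated default configuration for the 1990-2015 (MDG-era) landscape
#'
#' Encodes, at desk scale, the stylized facts of the DAH system over
#' 1990-2015: roughly five-fold growth in the number of organizations with a
#' steep CSO ramp between 2005 and 2011 and PPP entry from 2000; total
#' disbursements growing log-linearly from USD 7 billion to USD 36 billion;
#' the public share of funding sources declining from 94.5% to 81.3% and the
#' public share of channels from 92.4% to 49.9% (linear between anchors);
#' and one third of channel-capable CSOs dedicated to a single health area.
#'
#' @param seed Integer RNG seed stored in the configuration.
#' @return A validated [dah_generator_config()].
#' @export
default_config_mdg_era <- function(seed = 1990L) {
  years <- 1990:2015
  yr_chr <- as.character(years)
  n <- length(years)

  interp <- function(anchors) {
    # anchors: named numeric, names = years; linear in between, flat outside
    ax <- as.numeric(names(anchors))
    stats::approx(ax, anchors, xout = years, rule = 2)$y
  }

  growth_schedule <- list(
    PUBLIC  = round(interp(c(`1990` = 20, `2015` = 60))),
    PRIVATE = round(interp(c(`1990` = 4, `2015` = 30))),
    CSO     = round(interp(c(`1990` = 6, `2005` = 60, `2011` = 160,
                             `2015` = 190))),
    PPP     = round(interp(c(`1990` = 0, `1999` = 0, `2000` = 2,
                             `2015` = 15)))
  )
  growth_schedule <- lapply(growth_schedule, function(v) {
    setNames(cummax(v), yr_chr)
  })

  annual_total <- exp(seq(log(7e9), log(36e9), length.out = n))
  annual_total[c(1, n)] <- c(7e9, 36e9)
  names(annual_total) <- yr_chr

  share_matrix <- function(public, others) {
    # `public` is exact; remaining categories are scaled to fill 1 - public
    m <- cbind(PUBLIC = public,
               PRIVATE = others$PRIVATE, CSO = others$CSO, PPP = others$PPP)
    rest <- 1 - m[, "PUBLIC"]
    raw <- rowSums(m[, c("PRIVATE", "CSO", "PPP"), drop = FALSE])
    for (cat in c("PRIVATE", "CSO", "PPP")) {
      m[, cat] <- m[, cat] / raw * rest
    }
    rownames(m) <- yr_chr
    m
  }

  source_share_schedule <- share_matrix(
    public = interp(c(`1990` = 0.945, `2015` = 0.813)),
    others = list(
      PRIVATE = interp(c(`1990` = 0.030, `2015` = 0.060)),
      CSO     = interp(c(`1990` = 0.025, `2015` = 0.097)),
      PPP     = interp(c(`1990` = 0, `1999` = 0, `2000` = 0.005,
                         `2015` = 0.030))
    )
  )
  channel_share_schedule <- share_matrix(
    public = interp(c(`1990` = 0.924, `2015` = 0.499)),
    others = list(
      PRIVATE = interp(c(`1990` = 0.006, `2015` = 0.051)),
      CSO     = interp(c(`1990` = 0.070, `2015` = 0.300)),
      PPP     = interp(c(`1990` = 0, `1999` = 0, `2000` = 0.010,
                         `2015` = 0.150))
    )
  )

  dah_generator_config(
    years = years,
    n_recipients = 40,
    growth_schedule = growth_schedule,
    annual_total = annual_total,
    source_share_schedule = source_share_schedule,
    channel_share_schedule = channel_share_schedule,
    single_area_prob = 0.33,
    n_health_areas = 22,
    unspecified_rate = 0.02,
    hybrid_recipient_donor_rate = 0.1,
    seed = seed
  )
}

# deterministic fake ISO3 codes: AAA, AAB, AAC, ...
make_iso3_codes <- function(n) {
  stopifnot(n <= 26^3)
  i <- seq_len(n) - 1L
  paste0(LETTERS[i %/% 676 + 1], LETTERS[(i %/% 26) %% 26 + 1],
         LETTERS[i %% 26 + 1])
}

# Deterministic actor roster from the growth schedule. Actor i of a category
# activates in the first year whose scheduled count reaches i and is never
# retired; roles (source / channel / both) cycle within each category so that
# every category fields both sides of the flow. The only RNG use is the
# cause-specific flag and dedicated area of channel-capable CSOs.
build_actor_roster <- function(config) {
  years <- config$years
  yr_chr <- as.character(years)
  rows <- list()

  for (cat in dah_categories) {
    counts <- config$growth_schedule[[cat]][yr_chr]
    n_final <- counts[[length(counts)]]
    if (n_final == 0) next
    idx <- seq_len(n_final)
    first_year <- vapply(idx, function(i) {
      years[match(TRUE, counts >= i)]
    }, integer(1))
    role <- rep(c("source", "channel", "both"), length.out = n_final)
    subgroup <- switch(
      cat,
      PUBLIC  = ifelse(role == "source", "national_government", "multilateral"),
      PRIVATE = rep(c("individual", "sme_corporation"), length.out = n_final),
      CSO     = rep(c("ngo", "public_charity_npo", "family_foundation",
                      "corporate_foundation"), length.out = n_final),
      PPP     = rep(c("global_health_network", "global_health_initiative"),
                    length.out = n_final)
    )
    rows[[cat]] <- tibble::tibble(
      actor_id = sprintf("%s_%03d", tolower(cat), idx),
      name = sprintf("%s actor %03d", cat, idx),
      category = cat,
      subgroup = subgroup,
      is_oecd_dac = cat == "PUBLIC" & subgroup == "national_government" &
        idx <= 29,
      iso3 = NA_character_,
      role = role,
      first_year = first_year
    )
  }

  iso3 <- make_iso3_codes(config$n_recipients)
  n_hybrid <- floor(config$hybrid_recipient_donor_rate * config$n_recipients)
  rows$recipients <- tibble::tibble(
    actor_id = iso3,
    name = sprintf("Country %s", iso3),
    category = "PUBLIC",
    subgroup = "national_government",
    is_oecd_dac = FALSE,
    iso3 = iso3,
    role = c(rep("recipient_source", n_hybrid),
             rep("recipient", config$n_recipients - n_hybrid)),
    first_year = years[1]
  )

  roster <- dplyr::bind_rows(rows)
  # cause-specific status is a fixed actor attribute: a quota of
  # round(p * n) channel-capable CSOs (identity randomized) is dedicated to
  # a single randomly drawn health area, so the realized rate matches the
  # configured probability by construction
  cso_channel <- which(roster$category == "CSO" &
                         roster$role %in% c("channel", "both"))
  n_single <- round(config$single_area_prob * length(cso_channel))
  flagged <- if (length(cso_channel) > 0 && n_single > 0) {
    sample(cso_channel, n_single)
  } else {
    integer(0)
  }
  roster$single_area <- seq_len(nrow(roster)) %in% flagged
  roster$dedicated_area <- ifelse(
    roster$single_area,
    sample(config$health_areas, nrow(roster), replace = TRUE),
    NA_character_
  )
  roster
}

# Iterative proportional fitting of record amounts so that the per-category
# amount marginals on the source side and the channel side match the
# scheduled shares exactly (every cell with a positive marginal pair is
# guaranteed a record, so the fit always converges).
ras_rescale <- function(amount, src_cat, ch_cat, src_target, ch_target,
                        total, tol = 1e-13, max_iter = 500) {
  for (iter in seq_len(max_iter)) {
    row_sum <- vapply(names(src_target), function(cat) {
      sum(amount[src_cat == cat])
    }, numeric(1))
    fac <- ifelse(row_sum > 0, src_target / row_sum, 1)
    amount <- amount * fac[src_cat]

    col_sum <- vapply(names(ch_target), function(cat) {
      sum(amount[ch_cat == cat])
    }, numeric(1))
    fac <- ifelse(col_sum > 0, ch_target / col_sum, 1)
    amount <- amount * fac[ch_cat]

    row_sum <- vapply(names(src_target), function(cat) {
      sum(amount[src_cat == cat])
    }, numeric(1))
    dev <- abs(row_sum - src_target) / max(total, 1)
    if (max(dev) < tol) break
  }
  amount * (total / sum(amount))
}

# weighted single draw; degenerate pools short-circuit for speed
pick_one <- function(pool, w) {
  if (length(pool) == 1L) return(pool)
  pool[sample.int(length(pool), 1L, prob = w)]
}

generate_year_flows <- function(config, roster, year) {
  yr_chr <- as.character(year)
  active <- roster[roster$first_year <= year, ]
  orgs <- active[is.na(active$iso3), ]
  recipients <- active$actor_id[!is.na(active$iso3)]

  src_pool <- lapply(setNames(dah_categories, dah_categories), function(cat) {
    c(orgs$actor_id[orgs$category == cat & orgs$role %in% c("source", "both")],
      if (cat == "PUBLIC")
        active$actor_id[active$role == "recipient_source"])
  })
  ch_pool <- lapply(setNames(dah_categories, dah_categories), function(cat) {
    orgs$actor_id[orgs$category == cat & orgs$role %in% c("channel", "both")]
  })

  effective_shares <- function(schedule, pool, field) {
    if (is.null(schedule)) {
      s <- vapply(pool, length, numeric(1))
    } else {
      s <- schedule[yr_chr, dah_categories]
      empty <- vapply(pool, length, integer(1)) == 0
      bad <- !empty & s == 0
      if (any(bad)) {
        abort(sprintf(
          "`%s`: category %s has active actors in %d but a zero share; every active category needs a positive share.",
          field, paste(dah_categories[bad], collapse = ", "), year
        ))
      }
      s[empty] <- 0
    }
    if (sum(s) <= 0) {
      abort(sprintf("`%s`: no active category has a positive share in %d.",
                    field, year))
    }
    s / sum(s)
  }
  src_share <- effective_shares(config$source_share_schedule, src_pool,
                                "source_share_schedule")
  ch_share <- effective_shares(config$channel_share_schedule, ch_pool,
                               "channel_share_schedule")

  all_src <- unlist(src_pool, use.names = FALSE)
  all_ch <- unlist(ch_pool, use.names = FALSE)

  # coverage block: every role-capable actor and every recipient appears at
  # least once, plus one record per active (source cat x channel cat) cell so
  # the amount-marginal fit has full support
  # each channel-capable actor is covered twice so every multi-cause channel
  # can demonstrably carry at least two health areas
  n_cov <- max(length(all_src), 2 * length(all_ch), length(recipients))
  cov_src <- rep(sample(all_src), length.out = n_cov)
  cov_ch <- rep(c(sample(all_ch), sample(all_ch)), length.out = n_cov)
  cov_rec <- rep(sample(recipients), length.out = n_cov)
  cells <- expand.grid(src = dah_categories, ch = dah_categories,
                       stringsAsFactors = FALSE)
  cells <- cells[src_share[cells$src] > 0 & ch_share[cells$ch] > 0, ]
  cell_src <- vapply(cells$src, function(cat) pick_one(src_pool[[cat]], NULL),
                     character(1))
  cell_ch <- vapply(cells$ch, function(cat) pick_one(ch_pool[[cat]], NULL),
                    character(1))
  cell_rec <- sample(recipients, nrow(cells), replace = TRUE)

  mand_src <- c(cov_src, cell_src)
  mand_ch <- c(cov_ch, cell_ch)
  mand_rec <- c(cov_rec, cell_rec)
  n_mand <- length(mand_src)

  n_target <- if (!is.null(config$records_per_year)) {
    config$records_per_year[[yr_chr]]
  } else {
    round(5 * nrow(orgs) + 2 * length(recipients))
  }
  n_rand <- max(0L, as.integer(n_target) - n_mand)

  # random block: category drawn from the share schedule, actor within the
  # category by preferential attachment on accumulated strength
  cat_lookup <- setNames(active$category, active$actor_id)
  rand_src_cat <- sample(dah_categories, n_rand, replace = TRUE,
                         prob = src_share)
  rand_ch_cat <- sample(dah_categories, n_rand, replace = TRUE,
                        prob = ch_share)
  amt_raw <- rlnorm(n_mand + n_rand, meanlog = 0, sdlog = 1.2)

  out_str <- setNames(numeric(length(all_src)), all_src)
  in_str <- setNames(numeric(length(all_ch)), all_ch)
  mand_amt <- amt_raw[seq_len(n_mand)]
  for (cat in dah_categories) {
    sel <- mand_src %in% src_pool[[cat]]
    add <- tapply(mand_amt[sel], mand_src[sel], sum)
    out_str[names(add)] <- out_str[names(add)] + add
  }
  add <- tapply(mand_amt, mand_ch, sum)
  in_str[names(add)] <- in_str[names(add)] + add

  rand_src <- character(n_rand)
  rand_ch <- character(n_rand)
  if (n_rand > 0) {
    for (k in seq_len(n_rand)) {
      sp <- src_pool[[rand_src_cat[k]]]
      cp <- ch_pool[[rand_ch_cat[k]]]
      s <- pick_one(sp, 1 + out_str[sp])
      ch <- pick_one(cp, 1 + in_str[cp])
      a <- amt_raw[n_mand + k]
      out_str[[s]] <- out_str[[s]] + a
      in_str[[ch]] <- in_str[[ch]] + a
      rand_src[k] <- s
      rand_ch[k] <- ch
    }
  }
  rand_rec <- sample(recipients, n_rand, replace = TRUE)

  source_id <- c(mand_src, rand_src)
  channel_id <- c(mand_ch, rand_ch)
  recipient_id <- c(mand_rec, rand_rec)

  # health area: cause-specific CSOs always disburse their dedicated area
  ded <- setNames(roster$dedicated_area, roster$actor_id)[channel_id]
  health_area <- ifelse(is.na(ded),
                        sample(config$health_areas, length(channel_id),
                               replace = TRUE),
                        ded)

  total_y <- config$annual_total[[yr_chr]]
  src_cat <- cat_lookup[source_id]
  ch_cat <- cat_lookup[channel_id]
  amount <- ras_rescale(
    amt_raw, src_cat, ch_cat,
    src_target = src_share * total_y,
    ch_target = ch_share * total_y,
    total = total_y
  )

  tibble::tibble(
    year = year,
    source_id = unname(source_id),
    channel_id = unname(channel_id),
    recipient_id = unname(recipient_id),
    health_area = unname(health_area),
    amount_usd = unname(amount),
    .coverage = c(rep(TRUE, n_mand), rep(FALSE, n_rand))
  )
}

#' Generate a synthetic DAH flow table
#'
#' Draws, for every year of the configuration, a table of
#' source -> channel -> recipient disbursement records reproducing the
#' configured structural features: actor activation follows the growth
#' schedule deterministically (so per-year active-actor counts are exact);
#' per-year category shares of source and channel amounts match the share
#' schedules (amounts are proportionally refitted to the scheduled
#' marginals); each year's amounts sum exactly to the scheduled annual
#' total; channel choice within a category follows preferential attachment
#' on accumulated in-strength, producing heavy-tailed flow concentration;
#' and a configured fraction of non-coverage records has its source or
#' recipient relabelled to [UNSPECIFIED].
#'
#' The generator is a pure function of the configuration (which includes the
#' seed): the same configuration yields byte-identical output, and the
#' caller's RNG state is left untouched.
#'
#' @param config A [dah_generator_config()].
#' @return An object of class `dah_simulation`: a list with `flows` (tibble
#'   with columns `year, source_id, channel_id, recipient_id, health_area,
#'   amount_usd`), `registry` (actor registry tibble, including per-actor
#'   role, activation year and cause-specific flags), and `config`.
#' @examples
#' cfg <- dah_generator_config(years = 1995:1997, n_recipients = 3,
#'                             initial_actors = c(PUBLIC = 4, PRIVATE = 2,
#'                                                CSO = 3, PPP = 0),
#'                             seed = 42L)
#' sim <- generate_dah(cfg)
#' head(sim$flows)
#' @export
generate_dah <- function(config) {
  validate_generator_config(config)
  withr::with_seed(config$seed, {
    roster <- build_actor_roster(config)
    flows <- dplyr::bind_rows(lapply(config$years, function(y) {
      generate_year_flows(config, roster, y)
    }))

    # a channel that is not cause-specific must carry at least two distinct
    # health areas over the window; diversify the rare all-one-area draws
    multi <- roster$actor_id[!roster$single_area &
                               roster$role %in% c("channel", "both")]
    for (id in multi) {
      idx <- which(flows$channel_id == id)
      if (length(idx) >= 2 &&
          length(unique(flows$health_area[idx])) == 1) {
        current <- flows$health_area[idx[1]]
        flows$health_area[idx[length(idx)]] <-
          setdiff(config$health_areas, current)[1]
      }
    }

    # endpoint relabelling exercises the unspecified-record filter; coverage
    # records are exempt so realized active-actor counts stay exact
    eligible <- which(!flows$.coverage)
    n_unspec <- min(length(eligible),
                    round(config$unspecified_rate * nrow(flows)))
    if (n_unspec > 0) {
      hit <- sample(eligible, n_unspec)
      as_source <- runif(n_unspec) < 0.5
      flows$source_id[hit[as_source]] <- UNSPECIFIED
      flows$recipient_id[hit[!as_source]] <- UNSPECIFIED
    }
    flows$.coverage <- NULL

    registry <- roster[, c(registry_columns, "role", "first_year",
                           "single_area", "dedicated_area")]
    structure(list(flows = flows, registry = registry, config = config),
              class = "dah_simulation")
  })
}

#' @export
print.dah_simulation <- function(x, ...) {
  cat(sprintf(
    "<dah_simulation> %d flow records, %d actors, years %d-%d, seed %d\n",
    nrow(x$flows), nrow(x$registry), min(x$config$years),
    max(x$config$years), x$config$seed
  ))
  invisible(x)
}

#' @export
print.dah_generator_config <- function(x, ...) {
  cat(sprintf(
    "<dah_generator_config> years %d-%d, %d recipients, seed %d\n",
    min(x$years), max(x$years), x$n_recipients, x$seed
  ))
  invisible(x)
}

#' Serialize a generator configuration to YAML
#'
#' @param config A [dah_generator_config()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_config_yaml <- function(config, path) {
  validate_generator_config(config)
  as_list <- function(m) {
    if (is.null(m)) return(NULL)
    stats::setNames(lapply(rownames(m), function(r) as.list(m[r, ])),
                    rownames(m))
  }
  out <- list(
    years = range(config$years),
    n_recipients = config$n_recipients,
    growth_schedule = lapply(config$growth_schedule, as.list),
    annual_total = as.list(config$annual_total),
    source_share_schedule = as_list(config$source_share_schedule),
    channel_share_schedule = as_list(config$channel_share_schedule),
    single_area_prob = config$single_area_prob,
    n_health_areas = config$n_health_areas,
    health_areas = config$health_areas,
    unspecified_rate = config$unspecified_rate,
    hybrid_recipient_donor_rate = config$hybrid_recipient_donor_rate,
    seed = config$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
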