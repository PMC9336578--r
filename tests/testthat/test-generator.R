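test_that("configuration validation names the offending field", {
  expect_error(dah_generator_config(single_area_prob = 1.5),
               "single_area_prob")
  expect_error(dah_generator_config(unspecified_rate = -0.1),
               "unspecified_rate")
  expect_error(dah_generator_config(n_recipients = 0), "n_recipients")
  cfg <- small_config()
  cfg$annual_total["1991"] <- -1
  expect_error(validate_generator_config(cfg), "annual_total")
  cfg <- small_config()
  cfg$growth_schedule$CSO["1992"] <- 0  # decreasing: actors never retire
  expect_error(validate_generator_config(cfg), "growth_schedule")
  bad_shares <- matrix(0.3, 3, 4,
                       dimnames = list(1990:1992, dah_categories))
  expect_error(
    dah_generator_config(years = 1990:1992,
                         source_share_schedule = bad_shares),
    "source_share_schedule"
  )
})

test_that("generated records respect the schema contracts", {
  sim <- generate_dah(small_config())
  flows <- sim$flows
  expect_true(all(flows$year %in% 1990:1992))
  expect_true(all(flows$amount_usd > 0))
  expect_named(flows, c("year", "source_id", "channel_id", "recipient_id",
                        "health_area", "amount_usd"))
  # actor identifiers are stable: every id resolves in the registry
  ids <- unique(c(flows$source_id, flows$channel_id, flows$recipient_id))
  expect_true(all(setdiff(ids, UNSPECIFIED) %in% sim$registry$actor_id))
})

test_that("generation is a pure function of configuration and seed", {
  a <- generate_dah(small_config(seed = 11L))
  b <- generate_dah(small_config(seed = 11L))
  expect_identical(a$flows, b$flows)
  expect_identical(a$registry, b$registry)
  c <- generate_dah(small_config(seed = 12L))
  expect_false(identical(a$flows, c$flows))
  # caller RNG state untouched
  set.seed(99); before <- .Random.seed
  generate_dah(small_config())
  expect_identical(before, .Random.seed)
})

test_that("degenerate single_area_prob makes every CSO channel single-area", {
  cfg <- dah_generator_config(
    years = 1995:1999, n_recipients = 3,
    initial_actors = c(PUBLIC = 4, PRIVATE = 2, CSO = 6, PPP = 0),
    single_area_prob = 1, unspecified_rate = 0, seed = 5L
  )
  sim <- generate_dah(cfg)
  cso_ids <- sim$registry$actor_id[sim$registry$category == "CSO"]
  ch <- sim$flows[sim$flows$channel_id %in% cso_ids, ]
  areas <- tapply(ch$health_area, ch$channel_id,
                  function(a) length(unique(a)))
  expect_true(all(areas == 1))
})

test_that("annual amounts hit the scheduled totals and shares", {
  fx <- default_sim()
  cfg <- fx$sim$config
  # totals computed on the raw table (relabelling does not change amounts)
  tot <- annual_totals(fx$sim$flows)
  expect_equal(tot$total_usd, unname(cfg$annual_total[as.character(tot$year)]),
               tolerance = 1e-9)
  # realized category shares track the schedule; the small drift comes only
  # from dropping the relabelled records
  for (role in c("source", "channel")) {
    sched <- cfg[[paste0(role, "_share_schedule")]]
    pd <- proportional_distribution(fx$flows, fx$registry, role)
    for (yr in c(1990, 2002, 2015)) {
      for (cat in dah_categories) {
        realized <- pd$share[pd$year == yr & pd$category == cat]
        realized <- if (length(realized) == 0) 0 else realized
        expect_lt(abs(realized - sched[as.character(yr), cat]), 0.03)
      }
    }
  }
})

test_that("active actor counts follow the growth schedule exactly", {
  fx <- default_sim()
  cfg <- fx$sim$config
  orgs <- fx$registry[is.na(fx$registry$iso3), ]
  for (yr in c(1990, 2000, 2008, 2015)) {
    sub <- fx$flows[fx$flows$year == yr, ]
    active_ids <- unique(c(sub$source_id, sub$channel_id))
    m <- match(active_ids, orgs$actor_id)
    counts <- table(orgs$category[m[!is.na(m)]])
    for (cat in dah_categories) {
      expected <- cfg$growth_schedule[[cat]][[as.character(yr)]]
      got <- if (cat %in% names(counts)) counts[[cat]] else 0
      expect_identical(as.integer(got), as.integer(expected))
    }
  }
  # recipients all present every year
  recips <- fx$registry$actor_id[!is.na(fx$registry$iso3)]
  for (yr in c(1990, 2015)) {
    seen <- unique(fx$flows$recipient_id[fx$flows$year == yr])
    expect_true(all(recips %in% seen))
  }
})

test_that("the calibrated 1990-2015 configuration encodes its anchors", {
  cfg <- default_config_mdg_era()
  expect_true(validate_generator_config(cfg))
  expect_equal(cfg$source_share_schedule["1990", "PUBLIC"], 0.945)
  expect_equal(cfg$source_share_schedule["2015", "PUBLIC"], 0.813)
  expect_equal(cfg$channel_share_schedule["1990", "PUBLIC"], 0.924)
  expect_equal(cfg$channel_share_schedule["2015", "PUBLIC"], 0.499)
  expect_equal(unname(cfg$annual_total[c("1990", "2015")]), c(7e9, 36e9))
  # monotone interpolation between anchors
  expect_true(all(diff(cfg$source_share_schedule[, "PUBLIC"]) < 0))
  expect_true(all(diff(cfg$channel_share_schedule[, "PUBLIC"]) < 0))
  # PPPs enter the landscape from 2000
  expect_true(all(cfg$growth_schedule$PPP[as.character(1990:1999)] == 0))
  expect_gt(cfg$growth_schedule$PPP[["2000"]], 0)
})

test_that("the default landscape grows about five-fold with a CSO surge", {
  fx <- default_sim()
  per_year <- vapply(1990:2015, function(yr) {
    sub <- fx$flows[fx$flows$year == yr, ]
    length(unique(c(sub$source_id, sub$channel_id, sub$recipient_id)))
  }, numeric(1))
  expect_true(all(diff(per_year) >= 0))
  ratio <- per_year[26] / per_year[1]
  expect_gte(ratio, 4)
  expect_lte(ratio, 6)
  # CSO growth 2005-2011 outpaces the other categories
  cso <- fx$sim$config$growth_schedule$CSO
  surge <- cso[["2011"]] - cso[["2005"]]
  for (cat in c("PUBLIC", "PRIVATE", "PPP")) {
    other <- fx$sim$config$growth_schedule[[cat]]
    expect_gt(surge, other[["2011"]] - other[["2005"]])
  }
})

test_that("unspecified endpoints are injected at the configured rate", {
  fx <- default_sim()
  flows <- fx$sim$flows
  n_unspec <- sum(flows$source_id == UNSPECIFIED |
                    flows$recipient_id == UNSPECIFIED)
  expect_equal(n_unspec / nrow(flows), 0.02, tolerance = 0.25)
  cfg0 <- small_config(unspecified_rate = 0)
  expect_false(any(generate_dah(cfg0)$flows$source_id == UNSPECIFIED))
})

test_that("configuration round-trips through YAML", {
  cfg <- small_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config_yaml(cfg, path)
  raw <- yaml::read_yaml(path)
  expect_equal(raw$seed, cfg$seed)
  expect_equal(raw$years, c(1990, 1992))
  expect_equal(unlist(raw$growth_schedule$PUBLIC),
               cfg$growth_schedule$PUBLIC)
})
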