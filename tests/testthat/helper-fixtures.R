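# Shared fixtures. The calibrated default simulation takes a couple of
# seconds, so it is generated once per test run and reused.

.fixtures <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- generate_dah(default_config_mdg_era())
    .fixtures$flows <- suppressMessages(drop_unspecified(.fixtures$sim$flows))
  }
  list(sim = .fixtures$sim, flows = .fixtures$flows,
       registry = .fixtures$sim$registry)
}

small_config <- function(seed = 7L, years = 1990:1992, ...) {
  dah_generator_config(
    years = years,
    n_recipients = 2,
    initial_actors = c(PUBLIC = 3, PRIVATE = 0, CSO = 2, PPP = 0),
    seed = seed,
    ...
  )
}

# hand-built cleaned flow table used across modules
tiny_flows <- function() {
  tibble::tibble(
    year = c(2000L, 2000L, 2000L, 2001L),
    source_id = c("A", "A", "B", "A"),
    channel_id = c("B", "B", "C", "C"),
    recipient_id = c("R1", "R2", "R1", "R2"),
    health_area = c("malaria", "hiv_aids", "malaria", "malaria"),
    amount_usd = c(5, 3, 2, 7)
  )
}

tiny_registry <- function() {
  tibble::tibble(
    actor_id = c("A", "B", "C", "R1", "R2"),
    name = c("A", "B", "C", "R1", "R2"),
    category = c("PUBLIC", "CSO", "PPP", "PUBLIC", "PUBLIC"),
    subgroup = c("national_government", "ngo", "global_health_initiative",
                 "national_government", "national_government"),
    is_oecd_dac = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    iso3 = c(NA, NA, NA, "RAA", "RAB")
  )
}

random_flow_table <- function(n = 200, years = 2000:2002) {
  tibble::tibble(
    year = sample(years, n, replace = TRUE),
    source_id = sample(sprintf("src_%02d", 1:8), n, replace = TRUE),
    channel_id = sample(sprintf("ch_%02d", 1:6), n, replace = TRUE),
    recipient_id = sample(sprintf("%s", c("AAA", "AAB", "AAC")), n,
                          replace = TRUE),
    health_area = sample(dah_health_areas[1:5], n, replace = TRUE),
    amount_usd = rlnorm(n, 10, 1)
  )
}
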