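#' Actor typology vocabulary
#'
#' The four top-level categories of global health actors and the subgroups
#' each category may carry. Public entities are national governments and the
#' multilateral organizations they constitute; private entities are
#' individuals and enterprises; civil society organizations (CSOs) span NGOs,
#' public charities/NPOs and philanthropic foundations; public-private
#' partnerships (PPPs) are institutionalized polylateral collaborations such
#' as Global Health Initiatives.
#'
#' @format `dah_categories` is a character vector of the four category codes.
#' @name typology
NULL

#' @rdname typology
#' @export
dah_categories <- c("PUBLIC", "PRIVATE", "CSO", "PPP")

#' @rdname typology
#' @export
dah_subgroups <- list(
  PUBLIC  = c("national_government", "multilateral"),
  PRIVATE = c("individual", "sme_corporation"),
  CSO     = c("ngo", "public_charity_npo", "family_foundation",
              "corporate_foundation"),
  PPP     = c("global_health_network", "global_health_initiative")
)

#' Sentinel for unspecified flow endpoints
#'
#' Flow records whose source, channel or recipient could not be attributed
#' carry this literal; [drop_unspecified()] removes them before analysis.
#' @export
UNSPECIFIED <- "UNSPECIFIED"

#' Default health-area labels
#'
#' Twenty-two health areas over which disbursements are disaggregated.
#' Labels are generic stand-ins with the cardinality of the real tracking
#' data's split.
#' @export
dah_health_areas <- c(
  "hiv_aids", "malaria", "tuberculosis", "maternal_health",
  "newborn_child_health", "nutrition", "vaccines", "reproductive_health",
  "ncd", "mental_health", "injuries", "health_systems",
  "water_sanitation", "neglected_tropical_diseases", "polio", "surgery",
  "tobacco_control", "substance_use", "environmental_health",
  "pandemic_preparedness", "other_infectious_diseases", "unallocated"
)

# columns of the canonical flow-table CSV dialect
flow_table_columns <- c("year", "source_id", "channel_id", "recipient_id",
                        "health_area", "amount_usd")

registry_columns <- c("actor_id", "name", "category", "subgroup",
                      "is_oecd_dac", "iso3")
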