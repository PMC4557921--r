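# Administrative geography: 36 states plus the Federal Capital Territory,
# grouped into the six geopolitical zones that form the upper level of the
# random-effects hierarchy.

#' Nigerian states and geopolitical zones
#'
#' Returns the 37 subnational units (36 states plus the Federal Capital
#' Territory) with their geopolitical zone. The zone is the grouping factor
#' for zone-level random intercepts and slopes in the stage-1 model.
#'
#' @return a tibble with columns `state` and `zone` (37 rows, 6 zones).
#' @export
nigeria_states <- function() {
  zones <- list(
    "North Central" = c("Benue", "Kogi", "Kwara", "Nasarawa", "Niger",
                        "Plateau", "FCT"),
    "North East"    = c("Adamawa", "Bauchi", "Borno", "Gombe", "Taraba",
                        "Yobe"),
    "North West"    = c("Jigawa", "Kaduna", "Kano", "Katsina", "Kebbi",
                        "Sokoto", "Zamfara"),
    "South East"    = c("Abia", "Anambra", "Ebonyi", "Enugu", "Imo"),
    "South South"   = c("Akwa Ibom", "Bayelsa", "Cross River", "Delta",
                        "Edo", "Rivers"),
    "South West"    = c("Ekiti", "Lagos", "Ogun", "Ondo", "Osun", "Oyo")
  )
  tibble::tibble(
    state = unlist(zones, use.names = FALSE),
    zone = rep(names(zones), lengths(zones))
  )
}

# state -> zone lookup as a named character vector
state_zone_map <- function(states_table = nigeria_states()) {
  setNames(states_table$zone, states_table$state)
}
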