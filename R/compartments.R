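# Compartment registry and controlled vocabularies for the urban N network.

#' Nitrogen species labels recognized on flux records
#'
#' @format Character vector of species tags: bulk nitrogen (`total_N`),
#'   gaseous reactive species (`NOx`, `NH3`, `N2O`), inert dinitrogen (`N2`),
#'   organic and dissolved inorganic N (`organic_N`, `NO3_NH4`), and nitrogen
#'   bound in traded or manufactured goods (`product_N`).
#' @export
n_species <- c("total_N", "NOx", "NH3", "N2O", "N2",
               "organic_N", "NO3_NH4", "product_N")

#' Reliability grades, from best to worst data quality
#' @export
reliability_grades <- c("high", "moderate", "low")

#' Canonical compartment registry
#'
#' The urban system is resolved into twelve within-boundary subsystems,
#' organised into four process groups: production (farmland, urban green,
#' livestock, forest, aquaculture, industry), consumption (human), treatment
#' (sewage and garbage disposal) and environment (atmosphere, surface water,
#' ground water). Four external compartments (world trade, ocean, the
#' surrounding atmosphere, and the notional fixation source feeding new
#' reactive N into circulation) carry boundary-crossing flows and have
#' `within_boundary = FALSE`.
#'
#' @return A data frame with columns `id`, `name`, `group`, `within_boundary`.
#' @examples
#' reg <- compartment_registry()
#' table(reg$group)
#' @export
compartment_registry <- function() {
  within <- data.frame(
    id = c("farmland", "urban_green", "livestock", "forest", "aquaculture",
           "industry", "human", "sewage_disposal", "garbage_disposal",
           "atmosphere", "surface_water", "ground_water"),
    name = c("Farmland", "Urban green", "Livestock", "Forest", "Aquaculture",
             "Industry", "Human", "Sewage disposal", "Garbage disposal",
             "Atmosphere", "Surface water", "Ground water"),
    group = c(rep("production", 6L), "consumption", "treatment", "treatment",
              rep("environment", 3L)),
    within_boundary = TRUE,
    stringsAsFactors = FALSE
  )
  external <- data.frame(
    id = c("world_trade", "ocean", "surrounding_atmosphere", "fixation_source"),
    name = c("World trade", "Ocean", "Surrounding atmosphere",
             "Fixation source"),
    group = "external",
    within_boundary = FALSE,
    stringsAsFactors = FALSE
  )
  rbind(within, external)
}

# Subsystems whose stock changes count as terrestrial accumulation in the
# fate partition (atmosphere, surface water and the treatment subsystems are
# transit compartments, not terrestrial stores).
terrestrial_compartments <- function() {
  c("farmland", "livestock", "forest", "aquaculture", "human",
    "ground_water", "urban_green")
}

process_groups <- function() c("production", "consumption", "treatment",
                               "environment")
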