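# Worked-example fixture: the published 1995/2015 nitrogen budget of
# Guangzhou, encoded from the printed aggregate fluxes. Only values printed
# in the source are stored (each record carries its citation string); the
# full 12x12 inter-compartment matrix was never published, so the fixture
# networks hold boundary flows plus the handful of internal fluxes the text
# reports, and per-compartment accumulations travel as a recorded table
# rather than being derivable from the flux set.

gz_flux_table <- function() {
  r <- function(source, target, year, value, species, grade, label,
                citation) {
    data.frame(source = source, target = target, year = year, value = value,
               species = species, grade = grade, label = label,
               citation = citation, stringsAsFactors = FALSE)
  }
  rbind(
    # --- 2015 boundary inputs (uncertainty table, means) ---
    r("fixation_source", "farmland", 2015, 15.4, "total_N", "moderate",
      "bnf", "2015 budget table: BNF mean 15.4 (12.6, 18.3)"),
    r("fixation_source", "industry", 2015, 85.2, "product_N", "moderate",
      "hbnf", "2015 budget table: HBNF mean 85.2 (75.6, 95.3)"),
    r("fixation_source", "industry", 2015, 89.0, "total_N", "moderate",
      "fossil_fuel_fixation",
      "2015 budget table: fossil fuel mean 89.0 (66.7, 113.0)"),
    r("world_trade", "industry", 2015, 111.9, "product_N", "moderate",
      "import", "2015 budget table: import mean 111.9 (88.3, 135.2)"),
    # --- 2015 boundary outputs ---
    r("atmosphere", "surrounding_atmosphere", 2015, 70.7, "N2", "low",
      "denitrification_n2", "2015 budget table: N2 mean 70.7 (52.8, 87.4)"),
    r("atmosphere", "surrounding_atmosphere", 2015, 100.8, "total_N",
      "moderate", "atmospheric_transfer",
      "2015 budget table: atmospheric transfer 100.8 (76.5, 123.9)"),
    r("surface_water", "ocean", 2015, 22.8, "NO3_NH4", "moderate",
      "surface_water_transfer",
      "2015 budget table: surface water transfer 22.8 (11.1, 34.6)"),
    r("industry", "world_trade", 2015, 47.0, "product_N", "low",
      "net_domestic_trade",
      "2015 budget table: net domestic trade 47.0 (23.2, 70.3)"),
    r("industry", "world_trade", 2015, 3.7, "product_N", "high",
      "export", "2015 budget table: export 3.7 (3.0, 4.4)"),
    # --- 2015 internal fluxes printed in the text ---
    r("industry", "atmosphere", 2015, 83.6, "NOx", "moderate",
      "nox_fossil_industry",
      "2015 industrial NOx emissions to atmosphere, 83.6"),
    r("human", "atmosphere", 2015, 8.7, "NOx", "moderate",
      "nox_domestic_straw",
      paste("derived by difference: 2015 total NOx 92.3 minus industrial",
            "83.6 (domestic combustion and straw burning)")),
    r("sewage_disposal", "surface_water", 2015, 36.6, "NO3_NH4", "moderate",
      "domestic_wastewater",
      "2015 domestic wastewater N to surface water, 36.6"),
    r("industry", "human", 2015, 76.6, "product_N", "moderate",
      "food_intake",
      paste("2015 food N input to the human subsystem, 76.6 (aggregate over",
            "supply routes)")),
    r("industry", "farmland", 2015, 51.5, "product_N", "moderate",
      "fertilizer_and_feed",
      paste("2015 fertilizer and ammoniated feed N, 51.5 (aggregate; target",
            "nominal for the crop/livestock split)")),
    r("human", "garbage_disposal", 2015, 18.8, "product_N", "moderate",
      "garbage_treatment_load", "2015 garbage treatment N load, 18.8"),
    r("sewage_disposal", "atmosphere", 2015, 2.0, "N2O", "low",
      "n2o_emissions_total",
      paste("2015 total N2O emissions, 2.0 (aggregate; sewage treatment",
            "contributed 30% of the total)")),
    # --- 1995 fluxes printed in the text ---
    r("fixation_source", "industry", 1995, 56.8, "product_N", "moderate",
      "hbnf", "1995 HBNF, 56.8"),
    r("fixation_source", "industry", 1995, 26.0, "total_N", "moderate",
      "fossil_fuel_fixation", "1995 fossil fuel fixation, 26.0"),
    r("industry", "farmland", 1995, 52.3, "product_N", "moderate",
      "fertilizer_n", "1995 fertilizer N from HBNF, 52.3 (92% of HBNF)"),
    r("industry", "atmosphere", 1995, 34.2, "NOx", "moderate",
      "nox_emissions_total",
      "1995 total NOx emissions, 34.2 (73.7% industrial fossil fuel)"),
    r("sewage_disposal", "surface_water", 1995, 4.9, "NO3_NH4", "moderate",
      "domestic_wastewater", "1995 domestic wastewater N, 4.9"),
    r("surface_water", "ocean", 1995, 8.1, "NO3_NH4", "moderate",
      "surface_water_transfer", "1995 N transfer to the ocean, 8.1"),
    r("sewage_disposal", "atmosphere", 1995, 1.4, "N2O", "low",
      "n2o_emissions_total", "1995 total N2O emissions, 1.4"),
    r("human", "garbage_disposal", 1995, 3.3, "product_N", "moderate",
      "garbage_treatment_load", "1995 garbage treatment N load, 3.3")
  )
}

gz_accumulations <- function() {
  data.frame(
    compartment = c("farmland", "livestock", "forest", "aquaculture",
                    "human", "urban_green", "ground_water"),
    year = 2015L,
    value = c(11.3, 1.0, 8.0, 1.9, 20.3, 2.6, 11.4),
    citation = paste0("2015 budget table, accumulations: ",
                      c("farmland 11.3 (2.1, 22.5)",
                        "livestock 1.0 (0.8, 1.3)",
                        "forest 8.0 (5.3, 10.6)",
                        "aquaculture 1.9 (0.1, 4.1)",
                        "human 20.3 (10.5, 29.4)",
                        "urban green 2.6 (1.7, 3.5)",
                        "ground water 11.4 (8.9, 16.8)")),
    stringsAsFactors = FALSE
  )
}

gz_table1 <- function() {
  data.frame(
    quantity = c("bnf", "hbnf", "fossil_fuel", "import", "n2",
                 "atmospheric_transfer", "surface_water_transfer",
                 "net_domestic_trade", "export", "farmland", "livestock",
                 "forest", "aquaculture", "human", "urban_green",
                 "ground_water"),
    role = c(rep("input", 4), rep("output", 5), rep("accumulation", 7)),
    mean = c(15.4, 85.2, 89.0, 111.9, 70.7, 100.8, 22.8, 47.0, 3.7,
             11.3, 1.0, 8.0, 1.9, 20.3, 2.6, 11.4),
    p5 = c(12.6, 75.6, 66.7, 88.3, 52.8, 76.5, 11.1, 23.2, 3.0,
           2.1, 0.8, 5.3, 0.1, 10.5, 1.7, 8.9),
    p95 = c(18.3, 95.3, 113.0, 135.2, 87.4, 123.9, 34.6, 70.3, 4.4,
            22.5, 1.3, 10.6, 4.1, 29.4, 3.5, 16.8),
    citation = "2015 uncertainty table (10,000-trial Monte Carlo summary)",
    stringsAsFactors = FALSE
  )
}

gz_totals <- function() {
  data.frame(
    quantity = rep(c("inputs", "outputs", "accumulation"), times = 2),
    year = rep(c(1995L, 2015L), each = 3),
    value = c(142.5, 99.2, 44.7, 301.5, 245.0, 56.5),
    note = c("", "",
             paste("printed accumulation 44.7 does not close against printed",
                   "totals (142.5 - 99.2 = 43.3); attributed to rounding of",
                   "aggregated sub-fluxes, excluded from closure checks"),
             "", "", "closes exactly: 301.5 - 245.0 = 56.5"),
    citation = "results text: system totals 1995 and 2015",
    stringsAsFactors = FALSE
  )
}

gz_drivers <- function() {
  data.frame(
    factor = c("P", "A", "T1", "T2"),
    growth_rate = c(0.02352, 0.00456, -0.03527, 0.00364),
    coefficient = c(0.957, 2.620, 0.243, 5.617),
    stars = c("***", "**", "*", "***"),
    effect_coefficient_printed = c(1.022, 1.012, 0.991, 1.021),
    contribution_rate_printed = c(34.10, 18.06, 13.25, 30.51),
    citation = "driver-decomposition table (growth %, OLS coefficient, EC)",
    stringsAsFactors = FALSE
  )
}

gz_constants <- function() {
  data.frame(
    name = c("anthropogenic_creation_1995", "anthropogenic_creation_2015",
             "impact_growth_rate", "r_squared",
             "recycling_livestock_1995", "recycling_livestock_2015",
             "recycling_human_1995", "recycling_human_2015",
             "human_absorption_1995", "human_absorption_2015",
             "synthetic_accumulation_human_1995",
             "synthetic_accumulation_human_2015",
             "industrial_flux_1995", "industrial_flux_2015",
             "food_production_inputs_1995", "food_production_inputs_2015",
             "nox_industrial_share_1995", "nox_industrial_share_2015",
             "area_km2"),
    value = c(90.9, 180.0, 0.04904, 0.940, 0.48, 0.42, 0.70, 0.11,
              0.044, 0.026, 3.1, 18.0, 125.2, 184.9, 100.1, 167.8,
              0.737, 0.906, 7434),
    citation = c("anthropogenic Nr creation 90.9 (1995)",
                 "anthropogenic Nr creation 180.0 (2015)",
                 "impact annual growth rate 4.904%",
                 "OLS R-square 0.940",
                 "livestock excreta recycling 48% (1995)",
                 "livestock excreta recycling 42% (2015)",
                 "human excreta recycling 70% (1995)",
                 "human excreta recycling 11% (2015)",
                 "human absorption ratio 4.4% (1995)",
                 "human absorption ratio 2.6% (2015)",
                 "synthetic-product accumulation in humans 3.1 (1995)",
                 "synthetic-product accumulation in humans 18.0 (2015)",
                 "industrial subsystem Nr flux 125.2 (1995)",
                 "industrial subsystem Nr flux 184.9 (2015)",
                 "food-production N inputs 100.1 (1995)",
                 "food-production N inputs 167.8 (2015)",
                 "industrial share of NOx 73.7% (1995)",
                 "industrial share of NOx 90.6% (2015)",
                 "city area 7434 km2"),
    stringsAsFactors = FALSE
  )
}

#' Published city nitrogen budget fixture (Guangzhou, 1995 and 2015)
#'
#' Encodes the printed aggregate fluxes of a published megacity nitrogen
#' budget: 2015 boundary inputs (biological fixation 15.4, Haber-Bosch 85.2,
#' fossil-fuel fixation 89.0, import 111.9 Gg N), outputs (denitrified N2
#' 70.7, atmospheric transfer 100.8, surface-water transfer 22.8, net
#' domestic trade 47.0, export 3.7), recorded per-compartment accumulations
#' (summing to 56.5), the 1995 totals, the full 2015 uncertainty table
#' (means with 5th/95th percentiles), the printed driver-decomposition
#' inputs, and assorted printed indicator constants. Every record carries a
#' citation string describing where the number is printed.
#'
#' The 2015 budget closes exactly (301.5 - 245.0 = 56.5). The printed 1995
#' accumulation (44.7) does not close against the printed totals (43.3);
#' the mismatch is stored with a paper-rounding annotation and must not be
#' "fixed".
#'
#' @return A `guangzhou_fixture` list: `network` (an `n_network` over both
#'   years, with the recorded accumulation table attached), `accumulations`,
#'   `table1`, `totals`, `drivers`, `constants`, `area_km2`.
#' @examples
#' gz <- guangzhou_fixture()
#' system_balance(gz$network, 2015)
#' @export
guangzhou_fixture <- function() {
  fluxes <- gz_flux_table()
  acc <- gz_accumulations()
  structure(list(
    network = build_network(fluxes, accumulations = acc),
    accumulations = acc,
    table1 = gz_table1(),
    totals = gz_totals(),
    drivers = gz_drivers(),
    constants = gz_constants(),
    area_km2 = 7434
  ), class = "guangzhou_fixture")
}

#' @export
print.guangzhou_fixture <- function(x, ...) {
  cat("<guangzhou_fixture> published city N budget, 1995 and 2015\n")
  print(x$network)
  invisible(x)
}

#' Look up a fixture constant
#'
#' @param fixture A [guangzhou_fixture()].
#' @param name Constant name (see `fixture$constants$name`).
#' @return The stored value, with its citation attached as attribute
#'   `"citation"`.
#' @export
fixture_constant <- function(fixture, name) {
  i <- match(name, fixture$constants$name)
  if (is.na(i)) stop("unknown fixture constant '", name, "'", call. = FALSE)
  structure(fixture$constants$value[i],
            citation = fixture$constants$citation[i])
}
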