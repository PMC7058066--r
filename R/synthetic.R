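# Synthetic city scenarios: a 21-year activity/parameter/flux-definition
# bundle with the statistical structure the budget analysis assumes —
# exponential trends times lognormal noise, rising population, energy and
# imports, shrinking farmland and fertilizer use, diet drifting toward
# animal protein. Magnitudes are of the order of a Chinese megacity; the
# scenario is structural, not a reconstruction of any real city's data.

# item -> (subsystem, unit, grade) lookup for generated activities
.activity_meta <- data.frame(
  item = c("population", "coal_consumption", "oil_consumption",
           "ammonia_production", "import_food", "chemical_fertilizer",
           "farmland_area", "livestock_heads"),
  subsystem = c("human", "industry", "industry", "industry", "industry",
                "farmland", "farmland", "livestock"),
  unit = c("capita", "Mt", "Mt", "kt", "kt", "kt", "ha", "head"),
  grade = c("high", "high", "high", "moderate", "moderate", "high",
            "high", "moderate"),
  stringsAsFactors = FALSE
)

default_parameters <- function() {
  data.frame(
    name = c("NOx_EF_coal", "NOx_EF_oil", "N_content_ammonia",
             "N_content_import_food", "N_content_fertilizer",
             "BNF_rate_farmland", "harvest_N_rate", "feed_N_rate",
             "excretion_rate_human", "excretion_rate_livestock",
             "meat_N_rate", "NH3_EF_fertilizer", "N2O_EF_sewage",
             "denitrification_factor", "atm_transfer_factor",
             "wastewater_N_rate", "garbage_N_rate"),
    value = c(4, 6, 0.82, 0.03, 0.30, 15, 100, 90, 4.4, 8, 2, 0.10,
              0.05, 2.0, 2.6, 2.4, 6),
    unit = c("kg/t", "kg/t", "frac", "frac", "frac", "kg/ha", "kg/ha",
             "kg/ha", "kg/capita", "kg/head", "kg/head", "frac",
             "kg/capita", "kg/t", "kg/t", "kg/capita", "kg/capita"),
    grade = c("moderate", "moderate", "high", "moderate", "high",
              "low", "moderate", "low", "high", "low", "moderate",
              "low", "low", "low", "moderate", "moderate", "moderate"),
    stringsAsFactors = FALSE
  )
}

default_flux_defs <- function() {
  fd <- flux_definition
  list(
    # new reactive N entering the system
    fd("bnf", "fixation_source", "farmland", "total_N",
       list(list(activity = "farmland_area", parameter = "BNF_rate_farmland"))),
    fd("hbnf", "fixation_source", "industry", "product_N",
       list(list(activity = "ammonia_production",
                 parameter = "N_content_ammonia"))),
    fd("fossil_fuel_fixation", "fixation_source", "industry", "total_N",
       list(list(activity = "coal_consumption", parameter = "NOx_EF_coal"),
            list(activity = "oil_consumption", parameter = "NOx_EF_oil"))),
    fd("import", "world_trade", "industry", "product_N",
       list(list(activity = "import_food",
                 parameter = "N_content_import_food"))),
    # internal circulation
    fd("fertilizer", "industry", "farmland", "product_N",
       list(list(activity = "chemical_fertilizer",
                 parameter = "N_content_fertilizer"))),
    fd("crop_harvest", "farmland", "human", "organic_N",
       list(list(activity = "farmland_area", parameter = "harvest_N_rate"))),
    fd("feed", "farmland", "livestock", "organic_N",
       list(list(activity = "farmland_area", parameter = "feed_N_rate"))),
    fd("livestock_products", "livestock", "human", "organic_N",
       list(list(activity = "livestock_heads", parameter = "meat_N_rate"))),
    fd("manure_return", "livestock", "farmland", "organic_N",
       list(list(activity = "livestock_heads",
                 parameter = "excretion_rate_livestock",
                 multiplier = 0.42))),
    fd("human_excreta_sewage", "human", "sewage_disposal", "organic_N",
       list(list(activity = "population",
                 parameter = "excretion_rate_human", multiplier = 0.89))),
    fd("human_excreta_return", "human", "farmland", "organic_N",
       list(list(activity = "population",
                 parameter = "excretion_rate_human", multiplier = 0.11))),
    fd("food_intake", "industry", "human", "product_N",
       list(list(activity = "import_food",
                 parameter = "N_content_import_food", multiplier = 0.85))),
    fd("synthetic_products", "industry", "human", "product_N",
       list(list(activity = "ammonia_production",
                 parameter = "N_content_ammonia", multiplier = 0.40))),
    fd("garbage_treatment_load", "human", "garbage_disposal", "product_N",
       list(list(activity = "population", parameter = "garbage_N_rate"))),
    fd("domestic_wastewater", "sewage_disposal", "surface_water", "NO3_NH4",
       list(list(activity = "population",
                 parameter = "wastewater_N_rate"))),
    fd("nox_emission", "industry", "atmosphere", "NOx",
       list(list(activity = "coal_consumption", parameter = "NOx_EF_coal"),
            list(activity = "oil_consumption", parameter = "NOx_EF_oil"))),
    fd("nh3_volatilization", "farmland", "atmosphere", "NH3",
       list(list(activity = "chemical_fertilizer",
                 parameter = "N_content_fertilizer", multiplier = 0.10))),
    fd("n2o_sewage", "sewage_disposal", "atmosphere", "N2O",
       list(list(activity = "population", parameter = "N2O_EF_sewage"))),
    # boundary outputs
    fd("denitrification_n2", "atmosphere", "surrounding_atmosphere", "N2",
       list(list(activity = "coal_consumption",
                 parameter = "denitrification_factor"),
            list(activity = "oil_consumption",
                 parameter = "denitrification_factor"))),
    fd("atmospheric_transfer", "atmosphere", "surrounding_atmosphere",
       "total_N",
       list(list(activity = "coal_consumption",
                 parameter = "atm_transfer_factor"),
            list(activity = "oil_consumption",
                 parameter = "atm_transfer_factor"))),
    fd("surface_water_transfer", "surface_water", "ocean", "NO3_NH4",
       list(list(activity = "population", parameter = "wastewater_N_rate",
                 multiplier = 0.55))),
    fd("net_domestic_trade", "industry", "world_trade", "product_N",
       list(list(activity = "ammonia_production",
                 parameter = "N_content_ammonia", multiplier = 0.25))),
    fd("export", "industry", "world_trade", "product_N",
       list(list(activity = "ammonia_production",
                 parameter = "N_content_ammonia", multiplier = 0.05)))
  )
}

#' Configuration of the synthetic-city generator
#'
#' Defaults describe a megacity over 1995-2015: population near eight
#' million growing 2.35\% per year, coal and oil use rising, ammonia output
#' and imports rising, fertilizer use and farmland area shrinking, the
#' animal-source share of dietary N drifting up 0.456\% per year, energy
#' intensity falling 3.53\% per year and the industrial level rising
#' 0.364\% per year. Activity levels follow exponential trends times
#' lognormal noise.
#'
#' @param start_year First budget year.
#' @param n_years Number of annual snapshots.
#' @param seed Integer seed for the noise realisation.
#' @param noise_cv Lognormal noise CV applied around every activity and
#'   driver trend (0 gives exact exponentials).
#' @param area_km2 City area.
#' @param growth,level0 Named overrides for per-item annual growth rates
#'   (fractions, > -1) and initial levels.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(start_year = 1995L, n_years = 21L, seed = 42L,
                            noise_cv = 0.03, area_km2 = 7434,
                            growth = NULL, level0 = NULL) {
  g <- c(population = 0.0235, coal_consumption = 0.03,
         oil_consumption = 0.05, ammonia_production = 0.021,
         import_food = 0.04, chemical_fertilizer = -0.008,
         farmland_area = -0.01, livestock_heads = -0.012,
         diet_share = 0.00456, energy_intensity = -0.0353,
         industrial_level = 0.00364)
  l <- c(population = 8e6, coal_consumption = 15, oil_consumption = 5,
         ammonia_production = 100, import_food = 1500,
         chemical_fertilizer = 180, farmland_area = 150000,
         livestock_heads = 2.5e6, diet_share = 0.29,
         energy_intensity = 1.8, industrial_level = 0.18)
  if (!is.null(growth)) g[names(growth)] <- growth
  if (!is.null(level0)) l[names(level0)] <- level0
  if (any(g <= -1)) stop("growth rates must exceed -1", call. = FALSE)
  if (noise_cv < 0) stop("noise CV must be nonnegative", call. = FALSE)
  if (n_years < 1) stop("need at least one year", call. = FALSE)
  structure(list(start_year = as.integer(start_year),
                 n_years = as.integer(n_years), seed = as.integer(seed),
                 noise_cv = noise_cv, area_km2 = area_km2,
                 growth = g, level0 = l),
            class = "scenario_config")
}

# lognormal noise with unit mean and the requested CV
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Generate a synthetic city scenario
#'
#' Activities and driver series follow `level0 * (1 + growth)^t` times
#' lognormal noise; the trend component is deterministic, so distinct seeds
#' share trends and differ only in the noise realisation. Because every
#' flux is evaluated from the same activity tables, the yearly networks
#' satisfy per-compartment mass balance by construction (accumulations
#' absorb the input-output residuals).
#'
#' @param config A [scenario_config()].
#' @return A `city_scenario`: compartment registry, activity and parameter
#'   tables, flux definitions, STIRPAT driver series (with the impact `I`
#'   computed as the scenario's anthropogenic N creation: Haber-Bosch +
#'   fossil-fuel fixation + agricultural biological fixation), area and
#'   metadata.
#' @export
generate_city <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  years <- config$start_year + seq_len(config$n_years) - 1L
  t <- seq_len(config$n_years) - 1L

  series <- function(item) {
    config$level0[[item]] * (1 + config$growth[[item]])^t *
      lnoise(config$n_years, config$noise_cv)
  }

  act_rows <- lapply(.activity_meta$item, function(item) {
    meta <- .activity_meta[.activity_meta$item == item, ]
    data.frame(year = years, subsystem = meta$subsystem, item = item,
               amount = series(item), unit = meta$unit, grade = meta$grade,
               stringsAsFactors = FALSE)
  })
  activities <- do.call(rbind, act_rows)

  drivers <- data.frame(year = years,
                        P = activities$amount[activities$item == "population"],
                        A = series("diet_share"),
                        T1 = series("energy_intensity"),
                        T2 = series("industrial_level"))

  scenario <- structure(list(name = "synthetic_city",
                             seed = config$seed,
                             compartments = compartment_registry(),
                             activities = activities,
                             parameters = default_parameters(),
                             flux_defs = default_flux_defs(),
                             drivers = drivers,
                             area_km2 = config$area_km2,
                             config = config),
                        class = "city_scenario")

  fl <- evaluate_scenario(scenario)
  creation <- fl[fl$label %in% c("hbnf", "fossil_fuel_fixation", "bnf"), ]
  scenario$drivers$I <- as.numeric(
    tapply(creation$value, creation$year, sum)[as.character(years)])
  scenario
}

#' @export
print.city_scenario <- function(x, ...) {
  yrs <- range(x$activities$year)
  cat("<city_scenario> '", x$name, "' ", yrs[1], "-", yrs[2], ": ",
      length(unique(x$activities$item)), " activity items, ",
      nrow(x$parameters), " parameters, ", length(x$flux_defs),
      " flux definitions\n", sep = "")
  invisible(x)
}

#' Restrict a scenario to a subset of years
#'
#' Convenience for Monte Carlo quantity functions that only need one year.
#'
#' @param scenario A `city_scenario`.
#' @param years Years to keep.
#' @export
scenario_subset_years <- function(scenario, years) {
  stopifnot(inherits(scenario, "city_scenario"))
  scenario$activities <- scenario$activities[
    scenario$activities$year %in% years, , drop = FALSE]
  scenario$drivers <- scenario$drivers[
    scenario$drivers$year %in% years, , drop = FALSE]
  scenario
}

#' Simulate data from the ln-linear driver model
#'
#' Draws log-normal predictor series (independent across observations) and
#' computes the impact exactly from the ln-linear relation plus optional
#' Gaussian noise on the log scale — the construction oracle for
#' coefficient-recovery studies.
#'
#' @param n Number of observations.
#' @param coefficients Named vector `c(a =, b =, c =, d1 =, d2 =)`:
#'   intercept and the four elasticities.
#' @param sigma Standard deviation of the log-scale error term (0 gives a
#'   noiseless, exactly recoverable dataset).
#' @param seed Integer seed.
#' @return Data frame with `year`, `I`, `P`, `A`, `T1`, `T2`.
#' @export
simulate_stirpat_data <- function(n = 21,
                                  coefficients = c(a = 1, b = 0.957,
                                                   c = 2.620, d1 = 0.243,
                                                   d2 = 5.617),
                                  sigma = 0, seed = 1L) {
  set.seed(as.integer(seed))
  lnP <- stats::rnorm(n, log(8e6), 0.10)
  lnA <- stats::rnorm(n, log(0.30), 0.08)
  lnT1 <- stats::rnorm(n, log(1.5), 0.12)
  lnT2 <- stats::rnorm(n, log(0.20), 0.05)
  lnI <- coefficients[["a"]] + coefficients[["b"]] * lnP +
    coefficients[["c"]] * lnA + coefficients[["d1"]] * lnT1 +
    coefficients[["d2"]] * lnT2 + stats::rnorm(n, 0, sigma)
  data.frame(year = seq_len(n), I = exp(lnI), P = exp(lnP), A = exp(lnA),
             T1 = exp(lnT1), T2 = exp(lnT2))
}

#' Write / read a scenario as a directory of plain-text files
#'
#' `activities.csv`, `parameters.csv`, `drivers.csv`, `flux_defs.yaml` and
#' `meta.yaml`. Numbers are written with 17 significant digits so the
#' write-read round trip reproduces the scenario exactly and a rewrite is
#' byte-identical.
#'
#' @param scenario A `city_scenario`.
#' @param dir Directory path (created if absent).
#' @return `write_scenario` returns `dir` invisibly; `read_scenario`
#'   returns the reconstructed `city_scenario`.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "city_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) sprintf("%.17g", col)
      else col
    })
    df
  }
  utils::write.csv(fmt(scenario$activities),
                   file.path(dir, "activities.csv"), row.names = FALSE)
  utils::write.csv(fmt(scenario$parameters),
                   file.path(dir, "parameters.csv"), row.names = FALSE)
  utils::write.csv(fmt(scenario$drivers), file.path(dir, "drivers.csv"),
                   row.names = FALSE)
  defs <- lapply(scenario$flux_defs, function(d) {
    list(label = d$label, source = d$source, target = d$target,
         species = d$species,
         terms = lapply(d$terms, function(tm) {
           list(activity = tm$activity, parameter = tm$parameter,
                multiplier = tm$multiplier)
         }))
  })
  yaml::write_yaml(defs, file.path(dir, "flux_defs.yaml"),
                   precision = 17L)
  yaml::write_yaml(list(name = scenario$name, seed = scenario$seed,
                        area_km2 = scenario$area_km2),
                   file.path(dir, "meta.yaml"), precision = 17L)
  invisible(dir)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(dir) {
  need <- c("activities.csv", "parameters.csv", "drivers.csv",
            "flux_defs.yaml", "meta.yaml")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("scenario directory lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  activities <- utils::read.csv(file.path(dir, "activities.csv"),
                                stringsAsFactors = FALSE)
  registry <- compartment_registry()
  bad <- which(!activities$subsystem %in% registry$id)
  if (length(bad)) {
    stop("activities.csv line ", bad[1] + 1L, ": unknown subsystem '",
         activities$subsystem[bad[1]], "'", call. = FALSE)
  }
  parameters <- utils::read.csv(file.path(dir, "parameters.csv"),
                                stringsAsFactors = FALSE)
  drivers <- utils::read.csv(file.path(dir, "drivers.csv"),
                             stringsAsFactors = FALSE)
  defs_raw <- yaml::read_yaml(file.path(dir, "flux_defs.yaml"))
  flux_defs <- lapply(defs_raw, function(d) {
    flux_definition(d$label, d$source, d$target, d$species, d$terms)
  })
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  structure(list(name = meta$name, seed = meta$seed,
                 compartments = registry, activities = activities,
                 parameters = parameters, flux_defs = flux_defs,
                 drivers = drivers, area_km2 = meta$area_km2,
                 config = NULL),
            class = "city_scenario")
}
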