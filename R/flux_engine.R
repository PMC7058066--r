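# Declarative flux engine: flux value = sum over terms of
# activity amount x parameter x optional scalar, converted to Gg N / y.
#
# The per-flux equations of city budgets are sums of products of this form
# (fuel consumption x emission factor, product mass x N content, population
# x excretion rate), so a sum-of-products grammar expresses them all.

# grams per unit for mass units; strict failure on anything unknown
.mass_g <- c(g = 1, kg = 1e3, t = 1e6, kt = 1e9, Gg = 1e9, Mt = 1e12)

# dimensionless carrier units an activity may be counted in
.carrier_units <- c("head", "capita", "ha", "km2", "GWh", "m3", "item")

is_mass_unit <- function(u) u %in% names(.mass_g)

# Convert one activity x parameter product to Gg N.
# Parameter units: "frac" (N mass fraction of a mass-valued activity) or
# "<massN>/<denominator>" where the denominator must either equal the
# activity unit exactly (carrier units) or share the mass family with it.
term_to_gg <- function(amount, a_unit, value, p_unit, term_id = "") {
  fail <- function(msg) {
    stop("unit error in term ", term_id, ": ", msg, call. = FALSE)
  }
  p_unit <- gsub("_per_", "/", p_unit, fixed = TRUE)
  if (p_unit %in% c("frac", "fraction")) {
    if (!is_mass_unit(a_unit)) {
      fail(paste0("fractional N content requires a mass-valued activity, got '",
                  a_unit, "'"))
    }
    return(amount * .mass_g[[a_unit]] * value / 1e9)
  }
  parts <- strsplit(p_unit, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L) fail(paste0("cannot parse parameter unit '",
                                       p_unit, "'"))
  num <- parts[1]; den <- parts[2]
  if (!is_mass_unit(num)) fail(paste0("parameter numerator '", num,
                                      "' is not a mass unit"))
  if (den == a_unit) {
    grams <- amount * value * .mass_g[[num]]
  } else if (is_mass_unit(den) && is_mass_unit(a_unit)) {
    grams <- amount * .mass_g[[a_unit]] / .mass_g[[den]] * value *
      .mass_g[[num]]
  } else {
    fail(paste0("denominator '", den, "' does not match activity unit '",
                a_unit, "'"))
  }
  grams / 1e9
}

#' Define a flux as a sum of activity-by-parameter terms
#'
#' @param label Flux name (unique within a scenario).
#' @param source,target Compartment ids.
#' @param species Species tag, see [n_species].
#' @param terms List of terms, each a list with `activity` (activity item
#'   key), `parameter` (parameter name) and optional `multiplier`
#'   (dimensionless scalar, default 1).
#' @return A `flux_definition` object.
#' @export
flux_definition <- function(label, source, target, species = "total_N",
                            terms = list()) {
  stopifnot(is.character(label), is.character(source), is.character(target))
  if (!species %in% n_species) {
    stop("unknown species '", species, "' in definition '", label, "'",
         call. = FALSE)
  }
  terms <- lapply(terms, function(tm) {
    if (is.null(tm$activity) || is.null(tm$parameter)) {
      stop("each term needs 'activity' and 'parameter' (definition '",
           label, "')", call. = FALSE)
    }
    list(activity = tm$activity, parameter = tm$parameter,
         multiplier = if (is.null(tm$multiplier)) 1 else
           as.numeric(tm$multiplier))
  })
  structure(list(label = label, source = source, target = target,
                 species = species, terms = terms),
            class = "flux_definition")
}

worst_grade <- function(grades) {
  if (!length(grades)) return("high")
  ord <- match(grades, reliability_grades)
  if (anyNA(ord)) stop("unknown reliability grade: ",
                       paste(unique(grades[is.na(ord)]), collapse = ", "),
                       call. = FALSE)
  reliability_grades[max(ord)]
}

# value + propagated grade of one definition, without building a record
eval_defn <- function(defn, activities, parameters, year) {
  value <- 0
  grades <- character()
  for (tm in defn$terms) {
    arow <- which(activities$year == year & activities$item == tm$activity)
    if (length(arow) == 0L) {
      stop("definition '", defn$label, "': activity '", tm$activity,
           "' not found for year ", year, call. = FALSE)
    }
    if (length(arow) > 1L) {
      stop("definition '", defn$label, "': activity '", tm$activity,
           "' is ambiguous in year ", year,
           " (recorded under several subsystems)", call. = FALSE)
    }
    prow <- which(parameters$name == tm$parameter)
    if (length(prow) != 1L) {
      stop("definition '", defn$label, "': parameter '", tm$parameter,
           "' not found (or duplicated)", call. = FALSE)
    }
    gg <- term_to_gg(activities$amount[arow], activities$unit[arow],
                     parameters$value[prow], parameters$unit[prow],
                     term_id = paste0("'", tm$activity, "' x '",
                                      tm$parameter, "' in '", defn$label,
                                      "'"))
    value <- value + gg * tm$multiplier
    grades <- c(grades, activities$grade[arow], parameters$grade[prow])
  }
  if (value < 0) {
    stop("definition '", defn$label, "' evaluated to a negative flux",
         call. = FALSE)
  }
  list(value = value, grade = worst_grade(grades))
}

#' Evaluate one flux definition for one year
#'
#' Each term resolves an activity amount (by `(year, item)`) and a parameter
#' value; the products are converted to Gg N per year through the declared
#' unit table and summed. The flux inherits the worst (lowest) reliability
#' grade among its contributing activities and parameters.
#'
#' @param defn A [flux_definition()].
#' @param activities Activity table: `year`, `subsystem`, `item`, `amount`,
#'   `unit`, `grade`.
#' @param parameters Parameter table: `name`, `value`, `unit`, `grade`.
#' @param year Integer year.
#' @return One-row flux record data frame (see [build_network()]).
#' @examples
#' acts <- data.frame(year = 2015, subsystem = "industry",
#'                    item = "coal", amount = 10, unit = "Mt",
#'                    grade = "high")
#' pars <- data.frame(name = "NOx_EF_coal", value = 4, unit = "kg/t",
#'                    grade = "moderate")
#' defn <- flux_definition("nox", "industry", "atmosphere", "NOx",
#'   terms = list(list(activity = "coal", parameter = "NOx_EF_coal")))
#' evaluate_flux(defn, acts, pars, 2015)$value  # 40 Gg N / y
#' @export
evaluate_flux <- function(defn, activities, parameters, year) {
  stopifnot(inherits(defn, "flux_definition"))
  ev <- eval_defn(defn, activities, parameters, year)
  data.frame(source = defn$source, target = defn$target,
             year = as.integer(year), value = ev$value,
             species = defn$species, grade = ev$grade, label = defn$label,
             citation = NA_character_, stringsAsFactors = FALSE)
}

#' Evaluate a scenario's fluxes for one year, values only
#'
#' Lightweight path for Monte Carlo loops: returns the per-definition flux
#' values without assembling record tables.
#'
#' @inheritParams evaluate_scenario
#' @param year Single year.
#' @return Named numeric vector (by definition label), Gg N per year.
#' @export
flux_values <- function(scenario, year) {
  stopifnot(inherits(scenario, "city_scenario"))
  stats::setNames(
    vapply(scenario$flux_defs, function(defn) {
      eval_defn(defn, scenario$activities, scenario$parameters, year)$value
    }, numeric(1)),
    vapply(scenario$flux_defs, `[[`, "", "label"))
}

#' Scalar quantity functions for uncertainty propagation
#'
#' Builds a `quantity_fn` for [propagate()] that evaluates one
#' compartment's balance component (or, with `compartment = NULL`, the
#' system boundary balance) in a given year, using the lightweight
#' [flux_values()] path.
#'
#' @param compartment Compartment id, or `NULL` for the system boundary.
#' @param year Integer year.
#' @param component `"accumulation"`, `"inputs"` or `"outputs"`.
#' @return Function mapping a `city_scenario` to a number.
#' @export
quantity_balance <- function(compartment, year,
                             component = c("accumulation", "inputs",
                                           "outputs")) {
  component <- match.arg(component)
  force(compartment); force(year)
  function(scenario) {
    v <- flux_values(scenario, year)
    src <- vapply(scenario$flux_defs, `[[`, "", "source")
    tgt <- vapply(scenario$flux_defs, `[[`, "", "target")
    if (is.null(compartment)) {
      wb <- scenario$compartments$id[scenario$compartments$within_boundary]
      ins <- sum(v[!(src %in% wb) & tgt %in% wb])
      outs <- sum(v[src %in% wb & !(tgt %in% wb)])
    } else {
      ins <- sum(v[tgt == compartment])
      outs <- sum(v[src == compartment])
    }
    switch(component, inputs = ins, outputs = outs,
           accumulation = ins - outs)
  }
}

#' Evaluate every flux definition of a scenario across years
#'
#' @param scenario A `city_scenario` (see [generate_city()]).
#' @param years Years to evaluate; defaults to all years with activity data.
#' @return Flux record data frame with one row per (definition, year);
#'   deterministic given the scenario.
#' @export
evaluate_scenario <- function(scenario, years = NULL) {
  stopifnot(inherits(scenario, "city_scenario"))
  if (is.null(years)) years <- sort(unique(scenario$activities$year))
  rows <- vector("list", length(scenario$flux_defs) * length(years))
  k <- 0L
  for (yr in years) {
    for (defn in scenario$flux_defs) {
      k <- k + 1L
      rows[[k]] <- tryCatch(
        evaluate_flux(defn, scenario$activities, scenario$parameters, yr),
        error = function(e) {
          stop("while evaluating '", defn$label, "' for year ", yr, ": ",
               conditionMessage(e), call. = FALSE)
        })
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Build the flux network of a scenario
#'
#' @inheritParams evaluate_scenario
#' @return An `n_network` over the evaluated fluxes.
#' @export
scenario_network <- function(scenario, years = NULL) {
  build_network(evaluate_scenario(scenario, years = years))
}

#' Area-normalised input intensity
#'
#' Converts a city-total flux (Gg N per year) over an area (km2) to
#' kg N per hectare per year.
#'
#' @param flux_gg Flux in Gg N per year.
#' @param area_km2 Area in square kilometres; must be positive.
#' @return Intensity in kg N ha^-1 y^-1.
#' @examples
#' input_intensity(89.0, 7434)  # ~119.7 kg N / ha / y
#' @export
input_intensity <- function(flux_gg, area_km2) {
  if (!is.numeric(area_km2) || any(area_km2 <= 0)) {
    stop("area must be positive", call. = FALSE)
  }
  flux_gg * 1e6 / (area_km2 * 100)
}
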