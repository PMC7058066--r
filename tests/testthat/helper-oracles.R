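# Shared fixtures and independent brute-force oracles.

# naive double loop over an explicit edge list; deliberately independent of
# the package's vectorised balance computation
brute_balance <- function(fluxes, compartment, year) {
  ins <- 0
  outs <- 0
  for (i in seq_len(nrow(fluxes))) {
    row <- fluxes[i, ]
    if (row$year != year) next
    if (identical(row$target, compartment)) ins <- ins + row$value
    if (identical(row$source, compartment)) outs <- outs + row$value
  }
  list(inputs = ins, outputs = outs, accumulation = ins - outs)
}

# random small flux table over the full registry (internal + boundary edges)
random_flux_table <- function(n_fluxes = 6, years = 2010:2012) {
  reg <- compartment_registry()
  ids <- reg$id
  pick <- function(x, n = 1) x[sample.int(length(x), n, replace = TRUE)]
  src <- pick(ids, n_fluxes)
  tgt <- vapply(src, function(s) pick(setdiff(ids, s)), "")
  data.frame(
    source = src, target = unname(tgt),
    year = pick(years, n_fluxes),
    value = round(stats::runif(n_fluxes, 0, 50), 3),
    species = sample(n_species, n_fluxes, replace = TRUE),
    grade = sample(reliability_grades, n_fluxes, replace = TRUE),
    label = paste0("f", seq_len(n_fluxes)),
    stringsAsFactors = FALSE
  )
}

# one-activity, one-parameter scenario: flux = amount * frac, in Gg when the
# activity is counted in kt
toy_scenario <- function(amount = 100, value = 1, a_grade = "high",
                         p_grade = "high", year = 2015L) {
  structure(list(
    name = "toy", seed = 1L,
    compartments = compartment_registry(),
    activities = data.frame(year = year, subsystem = "industry",
                            item = "x", amount = amount, unit = "kt",
                            grade = a_grade, stringsAsFactors = FALSE),
    parameters = data.frame(name = "p", value = value, unit = "frac",
                            grade = p_grade, stringsAsFactors = FALSE),
    flux_defs = list(flux_definition(
      "xp", "fixation_source", "industry", "total_N",
      terms = list(list(activity = "x", parameter = "p")))),
    drivers = NULL, area_km2 = 100, config = NULL
  ), class = "city_scenario")
}
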