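make_defn <- function(terms, label = "f", source = "fixation_source",
                      target = "industry") {
  flux_definition(label, source, target, "total_N", terms = terms)
}

test_that("evaluate_flux reproduces hand-computed unit arithmetic", {
  acts <- data.frame(year = 2015L, subsystem = "industry",
                     item = c("coal", "oil"), amount = c(10, 5),
                     unit = "Mt", grade = c("high", "moderate"),
                     stringsAsFactors = FALSE)
  pars <- data.frame(name = c("ef_coal", "ef_oil"), value = c(4, 2),
                     unit = "kg/t", grade = "moderate",
                     stringsAsFactors = FALSE)
  defn <- make_defn(list(list(activity = "coal", parameter = "ef_coal"),
                         list(activity = "oil", parameter = "ef_oil")))
  # hand oracle: 10e6 t * 4 kg/t + 5e6 t * 2 kg/t = 5.0e7 kg = 50 Gg N
  rec <- evaluate_flux(defn, acts, pars, 2015)
  expect_equal(rec$value, 50)
  expect_equal(rec$grade, "moderate")

  # empty term list evaluates to zero
  expect_equal(evaluate_flux(make_defn(list()), acts, pars, 2015)$value, 0)
})

test_that("unit handling is strict and conversions are exact", {
  acts <- data.frame(year = 2015L, subsystem = "human",
                     item = c("pop", "mass"), amount = c(1e6, 2),
                     unit = c("capita", "kt"), grade = "high",
                     stringsAsFactors = FALSE)
  pars <- data.frame(name = c("rate", "frac", "badrate"),
                     value = c(4.4, 0.5, 1), unit = c("kg/capita", "frac",
                                                      "kg/head"),
                     grade = "high", stringsAsFactors = FALSE)
  # 1e6 capita * 4.4 kg/capita = 4.4e6 kg = 4.4e9 g = 4.4 Gg
  d1 <- make_defn(list(list(activity = "pop", parameter = "rate")))
  expect_equal(evaluate_flux(d1, acts, pars, 2015)$value, 4.4)
  # mass fraction of a kt activity: 2 kt * 0.5 = 1 kt N = 1 Gg
  d2 <- make_defn(list(list(activity = "mass", parameter = "frac")))
  expect_equal(evaluate_flux(d2, acts, pars, 2015)$value, 1)
  # carrier-unit mismatch names the term
  d3 <- make_defn(list(list(activity = "pop", parameter = "badrate")))
  expect_error(evaluate_flux(d3, acts, pars, 2015), "unit error.*pop")
  # fraction of a non-mass activity is rejected
  d4 <- make_defn(list(list(activity = "pop", parameter = "frac")))
  expect_error(evaluate_flux(d4, acts, pars, 2015), "unit error")
  # unresolved references are configuration errors
  d5 <- make_defn(list(list(activity = "nope", parameter = "rate")))
  expect_error(evaluate_flux(d5, acts, pars, 2015), "not found")
  d6 <- make_defn(list(list(activity = "pop", parameter = "nope")))
  expect_error(evaluate_flux(d6, acts, pars, 2015), "not found")
})

test_that("evaluated fluxes are linear in activities and term-order
           invariant, and inherit the worst grade", {
  set.seed(31)
  for (rep in 1:20) {
    n_terms <- sample(1:4, 1)
    acts <- data.frame(year = 2015L, subsystem = "industry",
                       item = paste0("a", 1:n_terms),
                       amount = stats::runif(n_terms, 1, 100),
                       unit = "kt",
                       grade = sample(reliability_grades, n_terms,
                                      replace = TRUE),
                       stringsAsFactors = FALSE)
    pars <- data.frame(name = paste0("p", 1:n_terms),
                       value = stats::runif(n_terms, 0.01, 1),
                       unit = "frac",
                       grade = sample(reliability_grades, n_terms,
                                      replace = TRUE),
                       stringsAsFactors = FALSE)
    terms <- lapply(1:n_terms, function(i) {
      list(activity = paste0("a", i), parameter = paste0("p", i),
           multiplier = stats::runif(1, 0.1, 2))
    })
    defn <- make_defn(terms)
    v1 <- evaluate_flux(defn, acts, pars, 2015)
    # doubling every activity doubles the flux
    acts2 <- acts
    acts2$amount <- acts2$amount * 2
    expect_equal(evaluate_flux(defn, acts2, pars, 2015)$value,
                 2 * v1$value)
    # term permutation leaves the value unchanged
    perm <- make_defn(terms[sample(n_terms)])
    expect_equal(evaluate_flux(perm, acts, pars, 2015)$value, v1$value)
    # worst grade among contributing terms wins
    worst_idx <- max(match(c(acts$grade, pars$grade), reliability_grades))
    expect_equal(v1$grade, reliability_grades[worst_idx])
  }
})

test_that("scenario evaluation yields one record per definition and year", {
  sc <- toy_scenario()
  sc$activities <- do.call(rbind, lapply(2013:2015, function(yr) {
    a <- toy_scenario()$activities
    a$year <- yr
    a
  }))
  fl <- evaluate_scenario(sc)
  expect_equal(nrow(fl), 3)  # 1 definition x 3 years
  expect_equal(fl$value, rep(100, 3))  # 100 kt x N fraction 1 = 100 Gg
  expect_s3_class(scenario_network(sc), "n_network")
})

test_that("area-normalised input intensity matches published arithmetic", {
  expect_equal(round(input_intensity(89.0, 7434), 1), 119.7)
  expect_equal(round(input_intensity(85.2, 7434), 1), 114.6)
  expect_equal(input_intensity(0, 7434), 0)
  expect_error(input_intensity(10, 0), "positive")
  expect_error(input_intensity(10, -5), "positive")
})
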