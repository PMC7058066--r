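test_that("registry holds the twelve subsystems in their process groups", {
  reg <- compartment_registry()
  wb <- reg[reg$within_boundary, ]
  expect_equal(nrow(wb), 12)
  expect_setequal(wb$id[wb$group == "production"],
                  c("farmland", "urban_green", "livestock", "forest",
                    "aquaculture", "industry"))
  expect_equal(wb$id[wb$group == "consumption"], "human")
  expect_setequal(wb$id[wb$group == "treatment"],
                  c("sewage_disposal", "garbage_disposal"))
  expect_setequal(wb$id[wb$group == "environment"],
                  c("atmosphere", "surface_water", "ground_water"))
  expect_false(any(reg$within_boundary[reg$group == "external"]))
})

test_that("build_network validates records and rejects duplicates", {
  empty <- build_network(NULL)
  expect_s3_class(empty, "n_network")
  expect_equal(nrow(empty$fluxes), 0)

  expect_error(build_network(data.frame(
    source = "farmland", target = "mars", year = 2015, value = 1,
    label = "a")), "unknown compartment.*mars")

  dup <- data.frame(source = "farmland", target = "livestock",
                    year = 2015, value = c(1, 2), label = "same")
  expect_error(build_network(dup), "duplicate")

  expect_error(build_network(data.frame(
    source = "farmland", target = "livestock", year = 2015, value = -1,
    label = "neg")), "nonnegative")
})

test_that("balance matches a brute-force edge-list oracle", {
  set.seed(101)
  for (rep in 1:25) {
    fl <- random_flux_table(n_fluxes = sample(2:6, 1))
    net <- build_network(fl)
    comp <- sample(compartment_registry()$id, 1)
    yrs <- unique(fl$year)
    yr <- yrs[sample.int(length(yrs), 1)]
    got <- suppressWarnings(balance(net, comp, yr))
    want <- brute_balance(fl, comp, yr)
    expect_equal(got, want)
  }
})

test_that("balance warns and returns zeros for an untouched compartment", {
  net <- build_network(data.frame(source = "farmland", target = "livestock",
                                  year = 2015, value = 3, label = "a"))
  expect_warning(b <- balance(net, "forest", 2015), "no incident fluxes")
  expect_equal(b, list(inputs = 0, outputs = 0, accumulation = 0))
  expect_error(balance(net, "farmland", 1999), "not present")
})

test_that("balance is additive under flux splitting", {
  set.seed(9)
  fl <- random_flux_table(n_fluxes = 5, years = 2015)
  net0 <- build_network(fl)
  split <- fl
  split$value[3] <- fl$value[3] / 2
  extra <- fl[3, ]
  extra$value <- fl$value[3] / 2
  extra$label <- "split_copy"
  net1 <- build_network(rbind(split, extra))
  for (comp in unique(c(fl$source, fl$target))) {
    expect_equal(suppressWarnings(balance(net1, comp, 2015)),
                 suppressWarnings(balance(net0, comp, 2015)))
  }
})

test_that("accumulations conserve mass on random networks", {
  set.seed(2024)
  reg <- compartment_registry()
  wb <- reg$id[reg$within_boundary]
  for (rep in 1:200) {
    fl <- random_flux_table(n_fluxes = sample(3:12, 1))
    net <- build_network(fl)
    for (yr in unique(fl$year)) {
      led <- balance_ledger(net, years = yr)
      sys <- system_balance(net, yr)
      expect_equal(sum(led$accumulation), sys$accumulation,
                   tolerance = 1e-12)
      expect_equal(led$accumulation, led$inputs - led$outputs)
    }
  }
})

test_that("group aggregation cancels intra-group flows and matches a
           partition-sum oracle", {
  net <- build_network(data.frame(source = "farmland", target = "livestock",
                                  year = 2015, value = 7, label = "intra"))
  ga <- group_aggregate(net, 2015)
  prod <- ga[ga$group == "production", ]
  expect_equal(prod$inputs, 0)
  expect_equal(prod$outputs, 0)
  expect_equal(prod$accumulation, 0)

  set.seed(77)
  fl <- random_flux_table(n_fluxes = 12, years = 2015)
  net <- build_network(fl)
  ga <- group_aggregate(net, 2015)
  reg <- compartment_registry()
  led <- balance_ledger(net, years = 2015)
  for (g in ga$group) {
    members <- reg$id[reg$group == g]
    expect_equal(ga$accumulation[ga$group == g],
                 sum(led$accumulation[led$compartment %in% members]))
  }
  expect_equal(sum(ga$accumulation), system_balance(net, 2015)$accumulation,
               tolerance = 1e-12)
})

test_that("flux CSV round trip is lossless", {
  set.seed(5)
  fl <- random_flux_table(n_fluxes = 8)
  fl$value[1] <- pi  # non-terminating decimal must survive
  net <- build_network(fl)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fluxes(net, path)
  back <- read_fluxes(path)
  expect_equal(back[, c("source", "target", "year", "value", "species",
                        "grade", "label")],
               net$fluxes[, c("source", "target", "year", "value",
                              "species", "grade", "label")])
  # canonical rewrite is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_fluxes(build_network(back), path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("sankey export carries nodes with groups and valued links", {
  net <- build_network(data.frame(
    source = c("fixation_source", "farmland"),
    target = c("farmland", "atmosphere"),
    year = 2015, value = c(10, 4), species = c("total_N", "NH3"),
    label = c("in", "vol")))
  js <- jsonlite::fromJSON(sankey_json(net, 2015))
  expect_setequal(js$nodes$id, c("fixation_source", "farmland",
                                 "atmosphere"))
  expect_equal(sort(js$links$value), c(4, 10))
  expect_true(all(c("source", "target", "value", "species") %in%
                    names(js$links)))
})
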