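# Derived indicators of the N budget: shares, fate fractions, nitrogen use
# efficiency, excreta recycling, environmental load series, and life-cycle
# commodity-chain traces.

#' Round half away from zero
#'
#' Budget tables conventionally round 0.5 up (away from zero), unlike R's
#' banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_away <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Percentage share of a part in a whole
#'
#' @param part,whole Nonnegative numerator and positive denominator, same
#'   units.
#' @param decimals Decimal places reported (half-away-from-zero).
#' @return Rounded percentage; the unrounded value is attached as attribute
#'   `"raw"`.
#' @examples
#' share_of(111.9, 301.5)      # 37.1
#' share_of(52.3, 56.8, 0)     # 92
#' @export
share_of <- function(part, whole, decimals = 1) {
  if (any(whole <= 0)) stop("whole must be positive", call. = FALSE)
  if (any(part < 0)) stop("part must be nonnegative", call. = FALSE)
  raw <- 100 * part / whole
  structure(round_half_away(raw, decimals), raw = raw)
}

#' Partition total new reactive-N creation
#'
#' Total creation is biological fixation plus industrial (Haber-Bosch)
#' fixation plus fixation during fossil-fuel combustion. The anthropogenic
#' total excludes natural biological fixation but keeps its agricultural
#' component.
#'
#' @param bnf Total biological N fixation (Gg N / y).
#' @param hbnf Haber-Bosch fixation (Gg N / y).
#' @param fossil_fixation Fixation during fossil-fuel combustion (Gg N / y).
#' @param abnf Agricultural component of `bnf`; `NA` if unknown.
#' @return List with the components, `total_creation` and
#'   `anthropogenic_total` (`NA` when `abnf` is unknown).
#' @export
creation_partition <- function(bnf, hbnf, fossil_fixation, abnf = NA_real_) {
  stopifnot(bnf >= 0, hbnf >= 0, fossil_fixation >= 0)
  if (!is.na(abnf) && abnf > bnf) {
    stop("agricultural BNF cannot exceed total BNF", call. = FALSE)
  }
  list(bnf = bnf, hbnf = hbnf, fossil_fixation = fossil_fixation,
       abnf = abnf,
       total_creation = bnf + hbnf + fossil_fixation,
       anthropogenic_total = hbnf + fossil_fixation +
         (if (is.na(abnf)) NA_real_ else abnf))
}

#' Fate partition of annual reactive-N input
#'
#' Classifies where one year's N input ends up, each channel as a percentage
#' of total system input: denitrified to inert N2, transferred to the
#' surrounding atmosphere as reactive species, transferred to the ocean via
#' surface water, exported through trade, accumulated in terrestrial
#' subsystems, plus a residual that closes the partition to 100.
#'
#' Channels are read off the boundary flows: N2-tagged outputs
#' (denitrification), other outputs to the surrounding atmosphere, outputs
#' to the ocean, and outputs to world trade. Terrestrial accumulation sums
#' the stock changes of the farmland, livestock, forest, aquaculture, human,
#' ground-water and urban-green subsystems, taken from the network's
#' recorded accumulation table when present and from the flux ledger
#' otherwise.
#'
#' @param network An `n_network`.
#' @param year Integer year.
#' @param decimals Decimal places for the rounded percentages.
#' @return `fate_fractions` object: `rounded` and `raw` named vectors over
#'   `denitrified_n2`, `atmospheric_transfer`, `surface_water_transfer`,
#'   `trade_output`, `terrestrial_accumulation`, `residual`; plus
#'   `total_input` (Gg N / y) and `year`.
#' @export
fate_fractions <- function(network, year, decimals = 1) {
  stopifnot(inherits(network, "n_network"))
  fl <- network$fluxes[network$fluxes$year == year, , drop = FALSE]
  comp <- network$compartments
  wb <- comp$id[comp$within_boundary]
  sysb <- system_balance(network, year)
  if (sysb$inputs <= 0) {
    stop("total N input is zero in ", year,
         "; fate fractions undefined", call. = FALSE)
  }
  out_bound <- fl[fl$source %in% wb & !(fl$target %in% wb), , drop = FALSE]
  denit <- sum(out_bound$value[out_bound$species == "N2"])
  atm <- sum(out_bound$value[out_bound$target == "surrounding_atmosphere" &
                               out_bound$species != "N2"])
  sw <- sum(out_bound$value[out_bound$target == "ocean"])
  trade <- sum(out_bound$value[out_bound$target == "world_trade"])
  acc <- network$accumulations
  if (!is.null(acc)) {
    acc <- acc[acc$year == year &
                 acc$compartment %in% terrestrial_compartments(), ,
               drop = FALSE]
    terr <- sum(acc$value)
  } else {
    led <- balance_ledger(network, years = year)
    terr <- sum(led$accumulation[led$compartment %in%
                                   terrestrial_compartments()])
  }
  raw <- 100 * c(denitrified_n2 = denit, atmospheric_transfer = atm,
                 surface_water_transfer = sw, trade_output = trade,
                 terrestrial_accumulation = terr) / sysb$inputs
  raw <- c(raw, residual = 100 - sum(raw))
  structure(list(rounded = round_half_away(raw, decimals), raw = raw,
                 total_input = sysb$inputs, year = year),
            class = "fate_fractions")
}

#' @export
print.fate_fractions <- function(x, ...) {
  cat("<fate_fractions> year", x$year, " total input",
      round(x$total_input, 1), "Gg N\n")
  print(x$rounded)
  invisible(x)
}

#' Nitrogen use efficiency of a production subsystem
#'
#' Harvested (crop) N divided by total N inputs to the subsystem. Values
#' above 1 are physically possible only when the soil N stock is being
#' mined; they are returned but flagged with a warning.
#'
#' @param harvest_n Harvested N (Gg N / y).
#' @param inputs_n Total N inputs (Gg N / y), positive.
#' @return Fraction (not percent).
#' @export
nue <- function(harvest_n, inputs_n) {
  if (inputs_n <= 0) stop("inputs must be positive", call. = FALSE)
  if (harvest_n < 0) stop("harvest must be nonnegative", call. = FALSE)
  out <- harvest_n / inputs_n
  if (out > 1) {
    warning("NUE exceeds 1: harvest draws down the soil N stock",
            call. = FALSE)
  }
  out
}

#' Excreta recycling ratio
#'
#' Fraction of livestock or human excreta N returned to farmland.
#'
#' @param excreta_to_farmland Returned excreta N (Gg N / y).
#' @param excreta_total Total excreta N (Gg N / y), positive.
#' @return Fraction between 0 and 1.
#' @export
recycling_ratio <- function(excreta_to_farmland, excreta_total) {
  if (excreta_total <= 0) stop("total excreta must be positive",
                               call. = FALSE)
  if (excreta_to_farmland < 0) stop("returned excreta must be nonnegative",
                                    call. = FALSE)
  if (excreta_to_farmland > excreta_total * (1 + 1e-9)) {
    stop("returned excreta exceeds the total produced", call. = FALSE)
  }
  min(excreta_to_farmland / excreta_total, 1)
}

#' Environmental load time series by source subsystem
#'
#' Per-year, per-source totals of one emission channel: `"NOx"`, `"NH3"` and
#' `"N2O"` select species-tagged fluxes into the atmosphere; the
#' `"surface_water"` channel selects all reactive-N discharge into surface
#' water.
#'
#' @param network An `n_network`.
#' @param channel One of `"NOx"`, `"NH3"`, `"N2O"`, `"surface_water"`.
#' @return Data frame `year`, `source`, `value` (Gg N / y); zero rows when
#'   the network holds no such fluxes.
#' @export
environmental_load_series <- function(network, channel) {
  stopifnot(inherits(network, "n_network"))
  channels <- c("NOx", "NH3", "N2O", "surface_water")
  if (!channel %in% channels) {
    stop("unknown channel '", channel, "'; expected one of ",
         paste(channels, collapse = ", "), call. = FALSE)
  }
  fl <- network$fluxes
  sel <- if (channel == "surface_water") {
    fl$target == "surface_water"
  } else {
    fl$species == channel & fl$target == "atmosphere"
  }
  fl <- fl[sel, , drop = FALSE]
  if (!nrow(fl)) {
    return(data.frame(year = integer(), source = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(value ~ year + source, data = fl, FUN = sum)
  agg <- agg[order(agg$year, agg$source), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Built-in commodity-chain configurations for life-cycle tracing
#'
#' Stage maps over the flux labels used by the packaged city fixture and the
#' synthetic-city generator: the industrial chain follows new N from
#' Haber-Bosch fixation, fossil-fuel fixation and imports through
#' agricultural use, trade and waste; the food chain follows N from
#' agricultural inputs through human intake to wastewater and riverine
#' export.
#'
#' @param chain `"industrial"` or `"food"`.
#' @return Chain configuration list (`name`, `stages`), each stage naming
#'   the flux labels it sums.
#' @export
chain_config <- function(chain = c("industrial", "food")) {
  chain <- match.arg(chain)
  if (chain == "industrial") {
    list(name = "industrial", stages = list(
      list(stage = "hbnf_input", labels = "hbnf"),
      list(stage = "fossil_fuel_input", labels = "fossil_fuel_fixation"),
      list(stage = "import_input", labels = "import"),
      list(stage = "agricultural_use",
           labels = c("fertilizer_and_feed", "fertilizer_n", "fertilizer")),
      list(stage = "trade_output", labels = c("net_domestic_trade",
                                              "export")),
      list(stage = "waste_to_garbage", labels = "garbage_treatment_load")
    ))
  } else {
    list(name = "food", stages = list(
      list(stage = "agricultural_inputs",
           labels = c("bnf", "fertilizer_and_feed", "fertilizer_n",
                      "fertilizer")),
      list(stage = "human_intake", labels = c("food_intake", "crop_harvest",
                                              "livestock_products")),
      list(stage = "wastewater_discharge", labels = "domestic_wastewater"),
      list(stage = "river_export", labels = "surface_water_transfer")
    ))
  }
}

#' Trace a commodity chain through the network
#'
#' Sums the labelled fluxes of each configured stage for one year, giving
#' the ordered stage-flux table of a life-cycle trace.
#'
#' @param network An `n_network`.
#' @param chain `"industrial"`, `"food"`, or a custom configuration shaped
#'   like [chain_config()].
#' @param year Integer year.
#' @return Data frame `stage`, `value` (Gg N / y), `n_fluxes`.
#' @export
trace_life_cycle <- function(network, chain, year) {
  stopifnot(inherits(network, "n_network"))
  cfg <- if (is.character(chain)) chain_config(chain) else chain
  if (is.null(cfg$stages)) {
    stop("chain configuration needs a 'stages' list", call. = FALSE)
  }
  all_labels <- unique(network$fluxes$label)
  fl <- network$fluxes[network$fluxes$year == year, , drop = FALSE]
  rows <- lapply(cfg$stages, function(st) {
    if (!any(st$labels %in% all_labels)) {
      stop("chain stage '", st$stage, "' references no flux present in the ",
           "network (labels: ", paste(st$labels, collapse = ", "), ")",
           call. = FALSE)
    }
    hit <- fl[fl$label %in% st$labels, , drop = FALSE]
    data.frame(stage = st$stage, value = sum(hit$value),
               n_fluxes = nrow(hit), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
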