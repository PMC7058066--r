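# Directed N-flux network and the mass-balance ledger.
#
# Fluxes are stored as nonnegative magnitudes on directed edges; reverse
# flows are separate records. The canonical unit is Gg N per year throughout;
# unit conversion happens in the flux engine at the I/O boundary.

flux_columns <- c("source", "target", "year", "value", "species", "grade",
                  "label")

normalize_fluxes <- function(fluxes) {
  if (is.null(fluxes) || nrow(as.data.frame(fluxes)) == 0L) {
    out <- data.frame(source = character(), target = character(),
                      year = integer(), value = numeric(),
                      species = character(), grade = character(),
                      label = character(), citation = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  fluxes <- as.data.frame(fluxes, stringsAsFactors = FALSE)
  if (!"species" %in% names(fluxes)) fluxes$species <- "total_N"
  if (!"grade" %in% names(fluxes)) fluxes$grade <- "moderate"
  if (!"label" %in% names(fluxes)) {
    fluxes$label <- paste(fluxes$source, fluxes$target, fluxes$species,
                          sep = "_")
  }
  if (!"citation" %in% names(fluxes)) fluxes$citation <- NA_character_
  missing <- setdiff(c("source", "target", "year", "value"), names(fluxes))
  if (length(missing)) {
    stop("flux table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fluxes$year <- as.integer(fluxes$year)
  fluxes$value <- as.numeric(fluxes$value)
  rownames(fluxes) <- NULL
  fluxes[, c(flux_columns, "citation")]
}

#' Build a directed nitrogen flux network
#'
#' Validates a flux table against the compartment registry and wraps it in a
#' queryable network object. Direction is carried solely by
#' `(source, target)`; values are nonnegative magnitudes in Gg N per year and
#' `(source, target, year, label)` must be unique.
#'
#' @param fluxes Data frame with columns `source`, `target`, `year`, `value`
#'   and optionally `species`, `grade`, `label`, `citation`.
#' @param accumulations Optional data frame of recorded per-compartment stock
#'   changes (`compartment`, `year`, `value`, optionally `citation`), used
#'   when per-compartment accumulation is known from an external budget
#'   rather than derivable from a complete flux set.
#' @param compartments Compartment registry; defaults to
#'   [compartment_registry()].
#' @return An object of class `n_network`.
#' @examples
#' net <- build_network(data.frame(
#'   source = "fixation_source", target = "farmland",
#'   year = 2015, value = 15.4, label = "bnf"))
#' balance(net, "farmland", 2015)
#' @export
build_network <- function(fluxes, accumulations = NULL,
                          compartments = compartment_registry()) {
  fluxes <- normalize_fluxes(fluxes)
  if (nrow(fluxes)) {
    unknown <- !(fluxes$source %in% compartments$id) |
      !(fluxes$target %in% compartments$id)
    if (any(unknown)) {
      bad <- fluxes[unknown, , drop = FALSE]
      stop("unknown compartment id in flux record(s): ",
           paste(sprintf("[%s -> %s, year %d, label '%s']", bad$source,
                         bad$target, bad$year, bad$label),
                 collapse = "; "), call. = FALSE)
    }
    if (any(!is.finite(fluxes$value)) || any(fluxes$value < 0)) {
      stop("flux values must be finite and nonnegative", call. = FALSE)
    }
    bad_sp <- setdiff(unique(fluxes$species), n_species)
    if (length(bad_sp)) {
      stop("unknown species label(s): ", paste(bad_sp, collapse = ", "),
           call. = FALSE)
    }
    key <- paste(fluxes$source, fluxes$target, fluxes$year, fluxes$label,
                 sep = "\r")
    if (anyDuplicated(key)) {
      dup <- fluxes[duplicated(key), , drop = FALSE]
      stop("duplicate flux record(s) for (source, target, year, label): ",
           paste(sprintf("[%s -> %s, %d, '%s']", dup$source, dup$target,
                         dup$year, dup$label), collapse = "; "),
           call. = FALSE)
    }
  }
  if (!is.null(accumulations)) {
    accumulations <- as.data.frame(accumulations, stringsAsFactors = FALSE)
    stopifnot(all(c("compartment", "year", "value") %in% names(accumulations)))
    if (!all(accumulations$compartment %in% compartments$id)) {
      stop("recorded accumulation names unknown compartment(s)",
           call. = FALSE)
    }
    accumulations$year <- as.integer(accumulations$year)
  }
  structure(list(fluxes = fluxes, compartments = compartments,
                 accumulations = accumulations),
            class = "n_network")
}

#' @export
print.n_network <- function(x, ...) {
  cat("<n_network>", nrow(x$fluxes), "flux records,",
      sum(x$compartments$within_boundary), "within-boundary compartments\n")
  if (nrow(x$fluxes)) {
    yrs <- range(x$fluxes$year)
    cat("  years:", yrs[1], "-", yrs[2],
        " total flux:", round(sum(x$fluxes$value), 2), "Gg N\n")
  }
  invisible(x)
}

#' Years present in a network
#' @param network An `n_network`.
#' @export
network_years <- function(network) sort(unique(network$fluxes$year))

#' Mass balance of one compartment in one year
#'
#' Sums flux magnitudes into and out of a compartment; accumulation is
#' inputs minus outputs, the per-compartment statement of conservation of
#' mass for an annual budget.
#'
#' @param network An `n_network`.
#' @param compartment Compartment id.
#' @param year Integer year; must be present in the network.
#' @return List with `inputs`, `outputs`, `accumulation` (Gg N per year).
#' @export
balance <- function(network, compartment, year) {
  stopifnot(inherits(network, "n_network"))
  if (!compartment %in% network$compartments$id) {
    stop("unknown compartment id: ", compartment, call. = FALSE)
  }
  if (!year %in% network$fluxes$year) {
    stop("year ", year, " not present in network", call. = FALSE)
  }
  fl <- network$fluxes[network$fluxes$year == year, , drop = FALSE]
  ins <- sum(fl$value[fl$target == compartment])
  outs <- sum(fl$value[fl$source == compartment])
  if (ins == 0 && outs == 0 &&
      !any(fl$source == compartment | fl$target == compartment)) {
    warning("compartment '", compartment, "' has no incident fluxes in ",
            year, "; returning zeros", call. = FALSE)
  }
  list(inputs = ins, outputs = outs, accumulation = ins - outs)
}

#' System-level boundary balance
#'
#' System input and output count only boundary-crossing flows (external to
#' within-boundary and vice versa); flows internal to the system, and flows
#' between external compartments, do not enter the totals. The system
#' accumulation is input minus output and equals the sum of within-boundary
#' compartment accumulations for any flux-complete network.
#'
#' @inheritParams balance
#' @return List with `inputs`, `outputs`, `accumulation` (Gg N per year).
#' @export
system_balance <- function(network, year) {
  stopifnot(inherits(network, "n_network"))
  fl <- network$fluxes[network$fluxes$year == year, , drop = FALSE]
  wb <- network$compartments$id[network$compartments$within_boundary]
  ins <- sum(fl$value[!(fl$source %in% wb) & fl$target %in% wb])
  outs <- sum(fl$value[fl$source %in% wb & !(fl$target %in% wb)])
  list(inputs = ins, outputs = outs, accumulation = ins - outs)
}

#' Per-compartment balance ledger
#'
#' @param network An `n_network`.
#' @param years Years to tabulate; defaults to all years in the network.
#' @return Data frame with one row per within-boundary compartment and year:
#'   `compartment`, `year`, `inputs`, `outputs`, `accumulation`.
#' @export
balance_ledger <- function(network, years = network_years(network)) {
  stopifnot(inherits(network, "n_network"))
  wb <- network$compartments$id[network$compartments$within_boundary]
  grid <- expand.grid(compartment = wb, year = years,
                      stringsAsFactors = FALSE)
  fl <- network$fluxes
  grid$inputs <- mapply(function(cp, yr) {
    sum(fl$value[fl$target == cp & fl$year == yr])
  }, grid$compartment, grid$year)
  grid$outputs <- mapply(function(cp, yr) {
    sum(fl$value[fl$source == cp & fl$year == yr])
  }, grid$compartment, grid$year)
  grid$accumulation <- grid$inputs - grid$outputs
  grid
}

#' Aggregate the balance to the four process groups
#'
#' Group input counts flows entering the group from outside it (other groups
#' or external compartments); flows internal to a group cancel, so the group
#' accumulation equals the sum of its members' accumulations.
#'
#' @inheritParams balance
#' @param accumulation `"flux"` derives accumulation from the flux balance;
#'   `"recorded"` uses the network's recorded accumulation table (for
#'   networks that carry only the boundary flows of a published budget).
#' @return Data frame with `group`, `inputs`, `outputs`, `accumulation`.
#' @export
group_aggregate <- function(network, year,
                            accumulation = c("flux", "recorded")) {
  stopifnot(inherits(network, "n_network"))
  accumulation <- match.arg(accumulation)
  fl <- network$fluxes[network$fluxes$year == year, , drop = FALSE]
  comp <- network$compartments
  out <- data.frame(group = process_groups(), inputs = 0, outputs = 0,
                    accumulation = 0, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    members <- comp$id[comp$group == out$group[i]]
    out$inputs[i] <- sum(fl$value[fl$target %in% members &
                                    !(fl$source %in% members)])
    out$outputs[i] <- sum(fl$value[fl$source %in% members &
                                     !(fl$target %in% members)])
  }
  if (accumulation == "flux") {
    led <- balance_ledger(network, years = year)
    led$group <- comp$group[match(led$compartment, comp$id)]
    agg <- tapply(led$accumulation, led$group, sum)
    out$accumulation <- as.numeric(agg[out$group])
    out$accumulation[is.na(out$accumulation)] <- 0
  } else {
    acc <- network$accumulations
    if (is.null(acc)) {
      stop("network carries no recorded accumulation table", call. = FALSE)
    }
    acc <- acc[acc$year == year, , drop = FALSE]
    acc$group <- comp$group[match(acc$compartment, comp$id)]
    agg <- tapply(acc$value, acc$group, sum)
    out$accumulation <- as.numeric(agg[out$group])
    out$accumulation[is.na(out$accumulation)] <- 0
  }
  out
}

#' Write / read a flux table as CSV
#'
#' Columns `source,target,year,value_GgN,species,grade,label`; UTF-8, header
#' required, '.' decimal separator. The round trip
#' `read_fluxes(write_fluxes(net))` is lossless.
#'
#' @param network An `n_network` (or a flux data frame).
#' @param path File path.
#' @return `write_fluxes` returns `path` invisibly; `read_fluxes` returns a
#'   flux data frame suitable for [build_network()].
#' @export
write_fluxes <- function(network, path) {
  fl <- if (inherits(network, "n_network")) network$fluxes else
    normalize_fluxes(network)
  out <- fl[, flux_columns]
  names(out)[names(out) == "value"] <- "value_GgN"
  out$value_GgN <- sprintf("%.17g", out$value_GgN)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_fluxes
#' @export
read_fluxes <- function(path) {
  fl <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("source", "target", "year", "value_GgN")
  missing <- setdiff(need, names(fl))
  if (length(missing)) {
    stop("flux CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  names(fl)[names(fl) == "value_GgN"] <- "value"
  normalize_fluxes(fl)
}

#' Export a network as Sankey-ready JSON
#'
#' Nodes carry `id` and `group`; links carry `source`, `target`, `value`,
#' `species` — the structure plotting tools expect for flow diagrams.
#'
#' @inheritParams balance
#' @param path Optional path; if given the JSON is written there.
#' @return JSON string (invisibly if `path` is given).
#' @export
sankey_json <- function(network, year = NULL, path = NULL) {
  stopifnot(inherits(network, "n_network"))
  fl <- network$fluxes
  if (!is.null(year)) fl <- fl[fl$year %in% year, , drop = FALSE]
  used <- union(fl$source, fl$target)
  comp <- network$compartments
  nodes <- comp[comp$id %in% used, c("id", "group")]
  links <- fl[, c("source", "target", "value", "species")]
  js <- jsonlite::toJSON(list(nodes = nodes, links = links),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
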