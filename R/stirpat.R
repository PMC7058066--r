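# Extended STIRPAT driver decomposition: ln-linear OLS of anthropogenic
# reactive-N creation (I) on population (P), diet choice (A, animal-source
# share of food N intake), energy intensity (T1, energy per unit GDP) and
# industrial level (T2, share of Nr creation through anthropogenic
# ammonification):
#
#   ln I = a + b ln P + c ln A + d1 ln T1 + d2 ln T2 + e
#
# Each driver's annual (geometric) growth rate and fitted elasticity combine
# into an effect coefficient (1 + r)^coef, and effect coefficients into
# R^2-scaled contribution rates.

stirpat_terms <- c("P", "A", "T1", "T2")

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Geometric (compound) annual growth rate of a series
#'
#' @param values Positive series values.
#' @param years Optional calendar years; when given, the rate compounds over
#'   `years[n] - years[1]` steps, otherwise over `length(values) - 1`.
#' @return Fraction per year: `(last/first)^(1/steps) - 1`.
#' @examples
#' annual_growth_rate(c(100, 200))              # 1.0
#' annual_growth_rate(100 * 1.02352^(0:20))     # 0.02352
#' @export
annual_growth_rate <- function(values, years = NULL) {
  n <- length(values)
  stopifnot(n >= 2)
  first <- values[1]; last <- values[n]
  if (!is.finite(first) || !is.finite(last) || first <= 0 || last <= 0) {
    stop("series endpoints must be positive", call. = FALSE)
  }
  steps <- if (is.null(years)) n - 1 else years[n] - years[1]
  if (steps <= 0) stop("years must span a positive interval", call. = FALSE)
  (last / first)^(1 / steps) - 1
}

#' Fit the extended STIRPAT model by OLS
#'
#' Ordinary least squares on natural-log-transformed variables. All series
#' must be strictly positive and at least six time points are required for
#' the four-predictor fit.
#'
#' @param dataset Data frame with columns `I`, `P`, `A`, `T1`, `T2` (a
#'   `year` column, if present, is carried along but not used in the fit).
#' @return `stirpat_fit` object: coefficient table (`estimate`, `se`, `t`,
#'   `p`, `stars`), `r_squared`, `adj_r_squared`, `vif`, and the underlying
#'   `lm` model.
#' @export
fit_stirpat <- function(dataset) {
  dataset <- as.data.frame(dataset)
  need <- c("I", stirpat_terms)
  missing <- setdiff(need, names(dataset))
  if (length(missing)) {
    stop("dataset lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (v in need) {
    if (any(!is.finite(dataset[[v]])) || any(dataset[[v]] <= 0)) {
      stop("series '", v, "' must be strictly positive (logs must exist)",
           call. = FALSE)
    }
  }
  if (nrow(dataset) < 6) {
    stop("need at least 6 time points for a 4-predictor fit", call. = FALSE)
  }
  d <- data.frame(lnI = log(dataset$I), lnP = log(dataset$P),
                  lnA = log(dataset$A), lnT1 = log(dataset$T1),
                  lnT2 = log(dataset$T2))
  model <- stats::lm(lnI ~ lnP + lnA + lnT1 + lnT2, data = d)
  cf <- stats::coef(model)
  if (anyNA(cf)) {
    aliased <- names(cf)[is.na(cf)]
    stop("perfect collinearity among predictors: ",
         paste(sub("^ln", "", aliased), collapse = ", "),
         " aliased in the fit", call. = FALSE)
  }
  sm <- summary(model)
  tab <- as.data.frame(sm$coefficients)
  names(tab) <- c("estimate", "se", "t", "p")
  tab$stars <- p_stars(tab$p)
  rownames(tab) <- c("intercept", stirpat_terms)
  vif <- car::vif(model)
  names(vif) <- sub("^ln", "", names(vif))
  structure(list(coefficients = tab, r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared, sigma = sm$sigma,
                 vif = vif, model = model, n = nrow(d)),
            class = "stirpat_fit")
}

#' @export
print.stirpat_fit <- function(x, ...) {
  cat("<stirpat_fit> ln I ~ ln P + ln A + ln T1 + ln T2   n =", x$n, "\n")
  printed <- x$coefficients
  printed[, 1:4] <- round(printed[, 1:4], 4)
  print(printed)
  cat(sprintf("R-squared = %.3f (adjusted %.3f)\n", x$r_squared,
              x$adj_r_squared))
  invisible(x)
}

#' Effect coefficient of a driver
#'
#' Multiplicative annual effect of a driver on the impact:
#' `(1 + r)^coefficient`, where `r` is the driver's annual growth rate and
#' the exponent its fitted elasticity.
#'
#' @param r Annual growth rate (fraction per year); `1 + r` must be
#'   positive.
#' @param coefficient Regression coefficient (elasticity).
#' @return Effect coefficient (full precision; round to 3 decimals for
#'   reporting).
#' @examples
#' effect_coefficient(0.02352, 0.957)   # ~1.022
#' effect_coefficient(-0.03527, 0.243)  # ~0.991
#' @export
effect_coefficient <- function(r, coefficient) {
  if (any(1 + r <= 0)) stop("1 + growth rate must be positive",
                            call. = FALSE)
  (1 + r)^coefficient
}

#' Contribution rates of drivers
#'
#' Each driver's share of the explained impact change:
#' `100 * |EC - 1| / sum(|EC - 1|) * R^2`. The rates sum to `100 * R^2` by
#' construction and are invariant to driver ordering.
#'
#' @param ec Named vector of effect coefficients.
#' @param r_squared Model R-squared used for scaling.
#' @return Named percentage vector.
#' @export
contribution_rates <- function(ec, r_squared) {
  stopifnot(r_squared >= 0, r_squared <= 1)
  dev <- abs(ec - 1)
  if (all(dev == 0)) {
    stop("all effect coefficients equal 1; contribution rates degenerate",
         call. = FALSE)
  }
  100 * dev / sum(dev) * r_squared
}

#' Screen candidate drivers by correlation and collinearity
#'
#' Pearson correlation matrix of the (log) candidate series, plus variance
#' inflation factors. Reporting only — which factors to keep is a modelling
#' decision, not automated here.
#'
#' @param candidates Data frame of candidate series (a `year` column is
#'   ignored); at least two candidates.
#' @param use_log Correlate log-transformed series (default), matching the
#'   ln-linear model the screen informs.
#' @return List with `correlation` (symmetric matrix, unit diagonal) and
#'   `vif` (named vector; `NA` with fewer than 3 candidates).
#' @export
screen_factors <- function(candidates, use_log = TRUE) {
  candidates <- as.data.frame(candidates)
  candidates <- candidates[, setdiff(names(candidates), "year"),
                           drop = FALSE]
  if (ncol(candidates) < 2) stop("need at least two candidate series",
                                 call. = FALSE)
  x <- as.matrix(candidates)
  if (use_log) {
    if (any(x <= 0)) stop("log screening requires positive series",
                          call. = FALSE)
    x <- log(x)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant series (undefined correlation): ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  cm <- suppressWarnings(stats::cor(x, method = "pearson"))
  vif <- rep(NA_real_, ncol(x))
  names(vif) <- colnames(x)
  ok <- sds > 0
  if (sum(ok) >= 2) {
    sub <- cm[ok, ok, drop = FALSE]
    inv <- tryCatch(solve(sub), error = function(e) NULL)
    if (!is.null(inv)) vif[ok] <- diag(inv)
  }
  list(correlation = cm, vif = vif)
}

#' Full driver-decomposition table
#'
#' Fits the model and assembles the reporting table: per driver, the annual
#' growth rate (%), regression coefficient with significance stars, effect
#' coefficient, contribution rate (%), t value and VIF.
#'
#' @param dataset As in [fit_stirpat()]; a `year` column, when present,
#'   defines the growth-rate window.
#' @return `driver_decomposition` object: the table (`table`), the fit
#'   (`fit`) and the growth rates (`growth`).
#' @export
driver_decomposition <- function(dataset) {
  dataset <- as.data.frame(dataset)
  fit <- fit_stirpat(dataset)
  years <- if ("year" %in% names(dataset)) dataset$year else NULL
  growth <- vapply(stirpat_terms, function(v) {
    annual_growth_rate(dataset[[v]], years)
  }, numeric(1))
  coefs <- fit$coefficients[stirpat_terms, ]
  ec <- effect_coefficient(growth, coefs$estimate)
  contrib <- contribution_rates(ec, fit$r_squared)
  tab <- data.frame(
    factor = c("Population (P)", "Diet choice (A)",
               "Energy intensity (T1)", "Industrial level (T2)"),
    growth_rate_pct = 100 * growth,
    coefficient = coefs$estimate,
    stars = coefs$stars,
    effect_coefficient = ec,
    contribution_rate_pct = contrib,
    t_value = coefs$t,
    vif = fit$vif[stirpat_terms],
    stringsAsFactors = FALSE)
  rownames(tab) <- stirpat_terms
  structure(list(table = tab, fit = fit, growth = growth,
                 impact_growth_rate = annual_growth_rate(dataset$I, years)),
            class = "driver_decomposition")
}

#' @export
print.driver_decomposition <- function(x, ...) {
  cat("<driver_decomposition>  impact annual growth rate:",
      sprintf("%.3f%%", 100 * x$impact_growth_rate), "\n")
  tab <- x$table
  tab$growth_rate_pct <- round(tab$growth_rate_pct, 3)
  tab$coefficient <- round(tab$coefficient, 3)
  tab$effect_coefficient <- round(tab$effect_coefficient, 3)
  tab$contribution_rate_pct <- round(tab$contribution_rate_pct, 2)
  tab$t_value <- round(tab$t_value, 2)
  tab$vif <- round(tab$vif, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("R-squared = %.3f\n", x$fit$r_squared))
  invisible(x)
}
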