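#' Summarise annualised GDP growth by income group
#'
#' Annualises each country's GDP-per-capita run (see [annualized_rate()])
#' and returns the mean and sample SD (n-1 denominator) of the per-country
#' rates within each income group. Groups absent from the input are
#' omitted with a warning.
#'
#' @param projections A `che_gdp_proj` data frame.
#' @param method Annualisation method passed to [annualized_rate()].
#' @return A `che_growth` data frame with columns `income_group`,
#'   `mean_rate`, `sd_rate`, `n_countries`.
#' @export
summarize_growth <- function(projections, method = c("endpoint", "ols_log")) {
  method <- match.arg(method)
  stopifnot(inherits(projections, "che_gdp_proj"))
  split_by_country <- split(projections, projections$country_id)
  rates <- data.frame(
    country_id = names(split_by_country),
    income_group = vapply(split_by_country,
                          function(d) as.character(d$income_group[1]), ""),
    rate = vapply(split_by_country,
                  function(d) annualized_rate(d$gdp_c, d$year, method), 0)
  )
  present <- income_groups()[income_groups() %in% rates$income_group]
  absent <- setdiff(income_groups(), present)
  if (length(absent) > 0) {
    warning("no GDP projections for group(s): ",
            paste(absent, collapse = ", "), " (omitted)", call. = FALSE)
  }
  out <- do.call(rbind, lapply(present, function(g) {
    r <- rates$rate[rates$income_group == g]
    data.frame(income_group = g, mean_rate = mean(r),
               sd_rate = if (length(r) > 1) stats::sd(r) else 0,
               n_countries = length(r))
  }))
  out$income_group <- as_income_group(out$income_group)
  rownames(out) <- NULL
  structure(out, class = c("che_growth", "data.frame"))
}

growth_lookup <- function(growth, group) {
  i <- match(as.character(group), as.character(growth$income_group))
  list(mean_rate = growth$mean_rate[i], sd_rate = growth$sd_rate[i])
}

#' Project a country's GDP per capita to the horizon year
#'
#' Compounds the base-year GDP per capita at its income group's mean
#' annualised growth rate over `horizon_year - base_year` years. The rate
#' is per group, not per country: all countries of a group share it.
#'
#' @param forecast One-row subset of a `che_forecasts` (or a list with
#'   `gdp_c_base`, `base_year`, `horizon_year`, `income_group`).
#' @param growth A `che_growth` row set from [summarize_growth()].
#' @return Projected GDP per capita at the horizon year.
#' @export
project_gdp_2040 <- function(forecast, growth) {
  g <- growth_lookup(growth, forecast$income_group)
  if (any(is.na(g$mean_rate))) {
    stop("no growth summary for group ",
         paste(unique(as.character(forecast$income_group)), collapse = ", "),
         call. = FALSE)
  }
  compound(forecast$gdp_c_base, g$mean_rate,
           forecast$horizon_year - forecast$base_year)
}

#' Deterministic point projection of CHE to the horizon year
#'
#' For each forecast country: project GDP forward with the group growth
#' rate, evaluate the fitted model at the forecast covariate means, and
#' aggregate per income group by the unweighted arithmetic mean of the
#' country predictions (countries, not populations, are the units).
#'
#' @param model A `che_model`.
#' @param forecasts A `che_forecasts`.
#' @param growth A `che_growth` from [summarize_growth()]; countries whose
#'   group lacks a growth summary are excluded with a warning.
#' @param use_blup If `TRUE`, each country's estimated random intercept
#'   (BLUP) is added to its linear predictor when available; default
#'   `FALSE` gives population-level predictions.
#' @return A `che_projection`: list with `country` (data frame
#'   `country_id`, `income_group`, `gdp_2040`, `che_2040`) and `group`
#'   (data frame `income_group`, `che_point`).
#' @export
project_group_che <- function(model, forecasts, growth, use_blup = FALSE) {
  stopifnot(inherits(model, "che_model"), inherits(forecasts, "che_forecasts"),
            inherits(growth, "che_growth"))
  fs <- forecasts[order(forecasts$country_id), , drop = FALSE]
  known <- as.character(fs$income_group) %in% as.character(growth$income_group)
  if (any(!known)) {
    warning("excluding countries with no group growth summary: ",
            paste(fs$country_id[!known], collapse = ", "), call. = FALSE)
    fs <- fs[known, , drop = FALSE]
  }
  gdp_2040 <- project_gdp_2040(fs, growth)
  effect <- if (use_blup) {
    e <- model$country_effects[fs$country_id]
    e[is.na(e)] <- 0
    unname(e)
  } else 0
  che_2040 <- predict_che(model, fs$oop_exp_mean, fs$hex_gdp_mean, gdp_2040,
                          country_effect = effect)
  country <- data.frame(country_id = fs$country_id,
                        income_group = fs$income_group,
                        gdp_2040 = gdp_2040, che_2040 = unname(che_2040))
  present <- income_groups()[income_groups() %in% as.character(country$income_group)]
  group <- do.call(rbind, lapply(present, function(g) {
    data.frame(income_group = g,
               che_point = mean(country$che_2040[as.character(country$income_group) == g]))
  }))
  group$income_group <- as_income_group(group$income_group)
  structure(list(country = country, group = group), class = "che_projection")
}

#' @export
print.che_projection <- function(x, ...) {
  cat("CHE point projection for", nrow(x$country), "countries:\n")
  print(transform(x$group, che_pct = 100 * che_point), row.names = FALSE)
  invisible(x)
}

#' Annualised decline between base-year and horizon-year group CHE
#'
#' Thin wrapper over [annualized_decline()] with the conventional 27-year
#' (2013 to 2040) horizon as default.
#'
#' @param group_2013,group_2040 Group CHE incidences in (0, 1).
#' @param n_years Horizon length in years.
#' @return Per-year fractional decline rate.
#' @export
compute_decline <- function(group_2013, group_2040, n_years = 27) {
  annualized_decline(group_2013, group_2040, n_years)
}

#' Base-year covariates and group CHE baselines from the panel
#'
#' `baseline_covariates()` extracts, per country, the covariate row at the
#' base year (by default the latest panel year), used both for per-trial
#' Monte Carlo baselines and for fitted baseline levels.
#' `baseline_group_che()` summarises base-year group CHE either as the
#' arithmetic mean of *observed* CHE values at the base year, or as the
#' mean of model-*fitted* values (BLUP included) at the base-year
#' covariates; the two are labelled explicitly since they answer slightly
#' different questions (data average vs model-implied level).
#'
#' @param panel A `che_panel`.
#' @param base_year Base year; default `max(panel$year)`.
#' @return `baseline_covariates()`: data frame `country_id`,
#'   `income_group`, `oop_exp`, `hex_gdp`, `gdp_c`, `che` (possibly NA).
#' @export
baseline_covariates <- function(panel, base_year = max(panel$year)) {
  stopifnot(inherits(panel, "che_panel"))
  rows <- panel[panel$year == base_year, , drop = FALSE]
  if (nrow(rows) == 0) stop("no panel rows at base year ", base_year, call. = FALSE)
  rows[c("country_id", "income_group", "oop_exp", "hex_gdp", "gdp_c", "che")]
}

#' @rdname baseline_covariates
#' @param model A `che_model` (needed for `type = "fitted"`).
#' @param type `"fitted"` (model predictions with BLUPs at base-year
#'   covariates) or `"observed"` (mean of observed base-year CHE).
#' @return `baseline_group_che()`: named numeric vector of group CHE at the
#'   base year.
#' @export
baseline_group_che <- function(panel, model = NULL,
                               type = c("fitted", "observed"),
                               base_year = max(panel$year)) {
  type <- match.arg(type)
  bc <- baseline_covariates(panel, base_year)
  if (type == "fitted") {
    stopifnot(inherits(model, "che_model"))
    eff <- model$country_effects[bc$country_id]
    eff[is.na(eff)] <- 0
    vals <- predict_che(model, bc$oop_exp, bc$hex_gdp, bc$gdp_c,
                        country_effect = unname(eff))
  } else {
    vals <- bc$che
  }
  keep <- !is.na(vals)
  groups <- as.character(bc$income_group)[keep]
  vals <- vals[keep]
  present <- income_groups()[income_groups() %in% groups]
  stats::setNames(vapply(present, function(g) mean(vals[groups == g]), 0),
                  present)
}
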